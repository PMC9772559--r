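#' Sloan neutral-model predicted occurrence frequency
#'
#' Under the neutral community model, the long-run proportion of a taxon
#' with metacommunity relative abundance p follows a
#' Beta(N m p, N m (1 - p)) distribution; the predicted occurrence
#' frequency is the probability of exceeding the detection limit d:
#' \eqn{1 - \mathrm{BetaCDF}(d;\; Nmp,\; Nm(1-p))}.
#'
#' @param p metacommunity mean relative abundance(s), in (0, 1).
#' @param m migration rate, > 0.
#' @param n community size (reads per sample), >= 1.
#' @param d detection limit as a relative abundance, in (0, 1).
#' @return predicted occurrence frequency in `[0, 1]`; vectorised over `p`.
#' @export
ncm_predict <- function(p, m, n, d) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0,1)")
  if (m <= 0) stop("m must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (d <= 0 || d >= 1) stop("d must be in (0,1)")
  stats::pbeta(d, n * m * p, n * m * (1 - p), lower.tail = FALSE)
}

# Wilson score interval for a proportion
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model to an abundance table
#'
#' Estimates the migration rate m by least squares between observed taxon
#' occurrence frequencies and [ncm_predict()] at the taxa's mean relative
#' abundances, with N the mean reads per sample and detection limit
#' d = ln(2)/N — the relative abundance at which a multinomial sample of
#' depth N detects a taxon with probability one half, so that predicted
#' frequencies are the exact dual of count-based detection (a taxon counts
#' as present when it receives at least one read). R-squared is computed about the mean
#' observed frequency, and each taxon is classified as above / within /
#' below the 95% Wilson band around its prediction.
#'
#' @param table an [abundance_table()].
#' @param d detection limit; defaults to `log(2)/N`.
#' @return list of class `ncm_fit`: `m`, `nm` (N*m), `n` (community size),
#'   `d`, `r2`, and `taxa` (data.frame with `p`, `observed`, `predicted`,
#'   `lower`, `upper`, `partition`).
#' @export
ncm_fit <- function(table, d = NULL) {
  counts <- table$counts
  n_samp <- nrow(counts)
  n_reads <- mean(rowSums(counts))
  if (is.null(d)) d <- log(2) / n_reads
  p <- colMeans(sweep(counts, 1, rowSums(counts), "/"))
  f <- colMeans(counts > 0)
  keep <- p > 0 & p < 1
  p <- p[keep]; f <- f[keep]
  if (sum(f > 0 & f < 1) < 10)
    stop("need >= 10 taxa with intermediate occurrence to fit the model")
  sse_of <- function(m) sum((f - ncm_predict(p, m, n_reads, d))^2)
  grid <- 10^seq(-4, 1, length.out = 60)
  sse_grid <- vapply(grid, sse_of, numeric(1))
  i <- which.min(sse_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse_of, lower = lo, upper = hi)
  m <- opt$minimum
  pred <- ncm_predict(p, m, n_reads, d)
  r2 <- 1 - opt$objective / sum((f - mean(f))^2)
  band <- wilson_interval(pred, n_samp)
  partition <- ifelse(f > band[, "upper"], "above",
               ifelse(f < band[, "lower"], "below", "within"))
  structure(list(
    m = m, nm = n_reads * m, n = n_reads, d = d, r2 = r2,
    taxa = data.frame(taxon = names(p), p = p, observed = f, predicted = pred,
                      lower = band[, "lower"], upper = band[, "upper"],
                      partition = partition,
                      stringsAsFactors = FALSE, row.names = NULL)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM: m = %.4g, Nm = %.4g, R2 = %.3f (%d taxa)\n",
              x$m, x$nm, x$r2, nrow(x$taxa)))
  print(table(x$taxa$partition))
  invisible(x)
}

# One null realisation of a group table: each sample keeps its observed
# richness and total count; taxa are drawn without replacement with
# probability proportional to regional occurrence frequency, then reads are
# filled proportionally to regional relative abundance (each drawn taxon
# keeps at least one read so realised richness matches).
null_draw <- function(counts) {
  occ <- colMeans(counts > 0)
  reg <- colSums(counts) / sum(counts)
  pool <- which(occ > 0)
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(nrow(counts))) {
    s <- sum(counts[j, ] > 0)
    n <- sum(counts[j, ])
    sel <- if (s >= length(pool)) pool else
      sample(pool, s, prob = occ[pool])
    fill <- stats::rmultinom(1, n - length(sel), prob = reg[sel])[, 1]
    out[j, sel] <- 1 + fill
  }
  out
}

#' Null-model expected pairwise dissimilarity
#'
#' Monte-Carlo expectation of Bray-Curtis dissimilarity between the samples
#' of one group under a proportional-proportional randomisation that
#' preserves each sample's richness and total reads: taxa are reassigned
#' with probability proportional to their regional occurrence frequency and
#' reads filled proportionally to regional relative abundance.
#'
#' @param table an [abundance_table()] holding one group's samples (>= 3).
#' @param n_null number of null draws (default 1000).
#' @param seed integer seed.
#' @return symmetric matrix of expected dissimilarities E_ij.
#' @export
null_expected_dissimilarity <- function(table, n_null = 1000, seed = 1) {
  counts <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (nrow(counts) < 3) stop("need >= 3 samples in the group")
  if (n_null < 2) stop("need at least 2 null draws")
  if (n_null < 10) warning("fewer than 10 null draws; E_ij will be noisy")
  set.seed(seed)
  acc <- matrix(0, nrow(counts), nrow(counts))
  for (b in seq_len(n_null))
    acc <- acc + as.matrix(vegan::vegdist(null_draw(counts), method = "bray"))
  e <- acc / n_null
  dimnames(e) <- list(rownames(counts), rownames(counts))
  e
}

#' Modified stochasticity ratio (MST)
#'
#' Compares each observed pairwise Bray-Curtis dissimilarity D to its null
#' expectation E: when D >= E, \eqn{MST = (d_{max} - D)/(d_{max} - E)};
#' otherwise \eqn{MST = D/E}; values are clamped to `[0, 1]`. MST equals 1
#' when the observation matches the null expectation and falls toward 0 as
#' communities are more similar or more different than chance. The group
#' mean above 0.5 is read as stochastic assembly; below 0.5 as
#' deterministic.
#'
#' @param table an [abundance_table()] holding one group's samples.
#' @param n_null null draws for the expectation (default 1000).
#' @param seed integer seed.
#' @param d_max maximal dissimilarity of the metric (1 for Bray-Curtis).
#' @return list of class `mst_result`: `pairwise` (data.frame of sample
#'   pairs with D, E, MST), `mean`, `classification`, `n_null`, `seed`.
#' @export
mst <- function(table, n_null = 1000, seed = 1, d_max = 1) {
  counts <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  d_obs <- as.matrix(vegan::vegdist(counts, method = "bray"))
  e <- null_expected_dissimilarity(counts, n_null = n_null, seed = seed)
  pairs <- which(upper.tri(d_obs), arr.ind = TRUE)
  vals <- apply(pairs, 1, function(ij) {
    d <- d_obs[ij[1], ij[2]]; ee <- e[ij[1], ij[2]]
    if (ee >= d_max) {
      warning("null expectation at d_max; pair skipped")
      return(NA_real_)
    }
    v <- if (d >= ee) (d_max - d) / (d_max - ee) else d / ee
    min(max(v, 0), 1)
  })
  pw <- data.frame(sample_a = rownames(d_obs)[pairs[, 1]],
                   sample_b = rownames(d_obs)[pairs[, 2]],
                   d = d_obs[pairs], e = e[pairs], mst = vals,
                   stringsAsFactors = FALSE)
  mn <- mean(vals, na.rm = TRUE)
  structure(list(pairwise = pw, mean = mn,
                 classification = if (mn > 0.5) "stochastic" else "deterministic",
                 n_null = n_null, seed = seed),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("MST: mean %.3f over %d pairs -> %s (null draws %d)\n",
              x$mean, nrow(x$pairwise), x$classification, x$n_null))
  invisible(x)
}
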