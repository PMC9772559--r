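#' Lognormal metacommunity relative abundances
#'
#' Rank-abundance structure typical of soil communities: lognormal
#' abundances normalised to proportions, yielding both abundant (> 1%) and
#' rare (< 1%) taxa at realistic evenness.
#'
#' @param n_taxa number of taxa.
#' @param sdlog lognormal shape (default 2; larger = steeper curve).
#' @param seed integer seed.
#' @param prefix taxon-id prefix.
#' @return named numeric vector of proportions summing to 1.
#' @export
lognormal_metacommunity <- function(n_taxa, sdlog = 2, seed = 1,
                                    prefix = "OTU") {
  set.seed(seed)
  w <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)
  stats::setNames(w / sum(w), sprintf("%s%04d", prefix, seq_len(n_taxa)))
}

#' Simulate samples under the Sloan neutral community model
#'
#' The sampling dual of [ncm_predict()]: per sample, each taxon's local
#' proportion is drawn from Beta(N m p_i, N m (1 - p_i)), proportions are
#' renormalised, and N reads are drawn multinomially.
#'
#' @param p metacommunity proportions (must sum to 1).
#' @param m migration rate, > 0.
#' @param n reads per sample.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param prefix sample-id prefix.
#' @return an [abundance_table()].
#' @export
simulate_neutral <- function(p, m, n, n_samples, seed = 1, prefix = "S") {
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  if (m <= 0) stop("m must be > 0")
  set.seed(seed)
  counts <- t(vapply(seq_len(n_samples), function(j) {
    x <- stats::rbeta(length(p), n * m * p, n * m * (1 - p))
    if (sum(x) == 0) x <- p
    stats::rmultinom(1, n, x / sum(x))[, 1]
  }, numeric(length(p))))
  dimnames(counts) <- list(sprintf("%s%02d", prefix, seq_len(n_samples)),
                           names(p))
  abundance_table(counts)
}

#' Simulate samples under deterministic environmental filtering
#'
#' Expected abundances are the metacommunity proportions reweighted by a
#' Gaussian fitness kernel \eqn{\exp(-strength (g - o_i)^2)} centred on each
#' taxon's niche optimum \eqn{o_i} at the sample's gradient position g, with
#' lognormal replicate noise and multinomial read sampling. `strength = 0`
#' reduces to noisy sampling of p with no group signal.
#'
#' @param p metacommunity proportions.
#' @param gradient environmental position of this group of samples.
#' @param optima per-taxon niche optima (same length as p).
#' @param strength filtering strength, >= 0.
#' @param n reads per sample.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param noise_sdlog lognormal replicate-noise sd on the log scale
#'   (default 0.3).
#' @param prefix sample-id prefix.
#' @return an [abundance_table()].
#' @export
simulate_filtered <- function(p, gradient, optima, strength, n, n_samples,
                              seed = 1, noise_sdlog = 0.3, prefix = "S") {
  if (strength < 0) stop("strength must be >= 0")
  if (length(optima) != length(p)) stop("optima must match p in length")
  set.seed(seed)
  w <- p * exp(-strength * (gradient - optima)^2)
  w <- w / sum(w)
  counts <- t(vapply(seq_len(n_samples), function(j) {
    e <- w * stats::rlnorm(length(w), 0, noise_sdlog)
    stats::rmultinom(1, n, e / sum(e))[, 1]
  }, numeric(length(p))))
  dimnames(counts) <- list(sprintf("%s%02d", prefix, seq_len(n_samples)),
                           names(p))
  abundance_table(counts)
}

# logistic colour-development curve starting at 0 OD at t = 0
logistic_od <- function(t, a, r, t0) {
  a * (stats::plogis(r * (t - t0)) - stats::plogis(-r * t0))
}

#' Simulate a raw Biolog plate reading
#'
#' Each substrate develops colour along a logistic curve
#' \eqn{OD(t) = A[\sigma(r(t - t_0)) - \sigma(-r t_0)]} (zero at inoculation)
#' whose rate r is scaled by the treatment multiplier; raw wells add a
#' shared baseline, a slow linear drift and Gaussian noise, and control
#' wells carry baseline + drift + noise only. ECO substrates occupy
#' triplicate wells sharing one true curve.
#'
#' @param kind `"ECO"` or `"FF"`.
#' @param rate_multiplier treatment scaling of development rates (1 =
#'   uncontaminated; 0 silences all colour development).
#' @param times reading times in hours (default 0 to 168 by 24).
#' @param noise_sd Gaussian OD noise sd (default 0.02).
#' @param seed integer seed.
#' @param path optional CSV output path (format of [read_plate()]).
#' @return list: `plate` (a `raw_plate`), `truth` (data.frame of per-substrate
#'   A, r, t0), and `path` when written.
#' @export
simulate_plate <- function(kind = c("ECO", "FF"), rate_multiplier = 1,
                           times = seq(0, 168, by = 24), noise_sd = 0.02,
                           seed = 1, path = NULL) {
  kind <- match.arg(kind)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be ascending")
  sc <- substrate_scheme(kind)
  set.seed(seed)
  subs <- unique(sc$substrate[sc$group != "control"])
  truth <- data.frame(
    substrate = subs,
    a = stats::runif(length(subs), 0.6, 1.6),
    r = rate_multiplier * stats::runif(length(subs), 0.03, 0.08),
    t0 = stats::runif(length(subs), 60, 110),
    stringsAsFactors = FALSE)
  baseline <- 0.08
  drift <- 2e-4  # OD per hour, shared by all wells, removed by correction
  od <- matrix(0, nrow(sc), length(times),
               dimnames = list(sc$well, times))
  for (i in seq_len(nrow(sc))) {
    dev <- if (sc$group[i] == "control") 0 else {
      tr <- truth[truth$substrate == sc$substrate[i], ]
      logistic_od(times, tr$a, tr$r, tr$t0)
    }
    od[i, ] <- baseline + drift * times + dev +
      stats::rnorm(length(times), 0, noise_sd)
  }
  od[od < 0] <- 0
  plate <- structure(list(kind = kind, od = od, times = times),
                     class = "raw_plate")
  if (!is.null(path)) {
    utils::write.table(
      data.frame(well = rownames(od), od, check.names = FALSE),
      path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  list(plate = plate, truth = truth, path = path)
}

#' Default experiment design
#'
#' The microcosm layout the generators emulate: four treatment groups — an
#' uncontaminated control (CK) and low / moderate / high risk levels
#' targeting RI = 100, 200 and 400 via Pb and Cd additions — with 5, 5, 6
#' and 6 replicates; bacterial total abundance and plate activity declining
#' with risk while fungal abundance rises; per-group assembly regimes
#' (neutral with migration rate m, or environmentally filtered); logistic
#' plate kinetics; and the bundled 72-gene C/N/P/S panel read against a CT
#' detection limit of 31.
#'
#' @param n_bacteria,n_fungi taxon richness of the two metacommunities.
#' @param reads reads per sample.
#' @return nested list of design parameters accepted by
#'   [simulate_experiment()].
#' @export
experiment_design <- function(n_bacteria = 300, n_fungi = 120, reads = 2000) {
  groups <- c("CK", "L", "M", "H")
  list(
    groups = groups,
    replicates = c(CK = 5L, L = 5L, M = 6L, H = 6L),
    ri_targets = c(L = 100, M = 200, H = 400),
    metals = data.frame(
      metal = c("Pb", "Cd"),
      background = c(20, 0.2),        # mg/kg, typical uncontaminated topsoil
      toxicity_factor = c(5, 30),     # conventional Hakanson factors
      stringsAsFactors = FALSE),
    allocation = c(Pb = 0.5, Cd = 0.5),
    n_bacteria = n_bacteria, n_fungi = n_fungi, reads = reads,
    # total-abundance multipliers (true qPCR copy scaling) per group
    bacterial_multiplier = c(CK = 1, L = 0.8, M = 0.6, H = 0.4),
    fungal_multiplier = c(CK = 1, L = 1.3, M = 1.6, H = 2.0),
    # assembly regime per group and domain: list(type, m or strength)
    assembly = list(
      bacteria = list(CK = list(type = "neutral", m = 0.3),
                      L = list(type = "filtered", strength = 25),
                      M = list(type = "filtered", strength = 15),
                      H = list(type = "neutral", m = 0.15)),
      fungi = list(CK = list(type = "filtered", strength = 20),
                   L = list(type = "neutral", m = 0.2),
                   M = list(type = "neutral", m = 0.25),
                   H = list(type = "neutral", m = 0.3))),
    filter_noise_sdlog = 0.05,
    # Biolog development-rate multipliers per group
    eco_rate = c(CK = 1, L = 0.8, M = 0.65, H = 0.5),
    ff_rate = c(CK = 1, L = 1, M = 0.95, H = 0.7),
    plate_noise_sd = 0.02,
    gene_base_meanlog = log(50), gene_base_sdlog = 1.5,
    gene_noise_sdlog = 0.4,
    detection_ct = 31
  )
}

#' Simulate a full study dataset with known ground truth
#'
#' Writes every input the pipeline consumes into a directory: bacterial and
#' fungal OTU tables, sample metadata, coalescent trees, per-sample Biolog
#' ECO/FF plate files, a functional-gene CT table with per-gene
#' amplification efficiencies, and a metals table whose additions are solved
#' with [solve_additions()] to hit the designed RI targets — plus a
#' `ground_truth.json` recording every generating parameter.
#'
#' @param design from [experiment_design()].
#' @param seed master seed; all stage seeds are forked from it.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the written `paths` and the `truth` list.
#' @export
simulate_experiment <- function(design = experiment_design(), seed = 1,
                                dir = tempfile("ecorisknet_sim_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "plates"), showWarnings = FALSE)
  groups <- design$groups
  reps <- design$replicates
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", g, seq_len(reps[[g]]))), use.names = FALSE)
  md <- data.frame(
    sample_id = samples,
    level = rep(groups, reps[groups]),
    replicate = unlist(lapply(reps[groups], seq_len), use.names = FALSE))
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)

  # --- metals designed to hit the RI targets ---------------------------------
  base <- design$metals
  base$concentration <- base$background   # CK soil sits at background
  rows <- list(cbind(group = "CK", base))
  for (g in names(design$ri_targets)) {
    added <- solve_additions(design$ri_targets[[g]], base, design$allocation)
    spec <- base
    spec$concentration <- base$concentration + added[base$metal]
    rows[[g]] <- cbind(group = g, spec)
  }
  metals <- do.call(rbind, rows)
  utils::write.csv(metals, file.path(dir, "metals.csv"), row.names = FALSE,
                   quote = FALSE)

  # --- community tables per domain -------------------------------------------
  truth <- list(seed = seed, design = design[c("replicates", "ri_targets",
                  "bacterial_multiplier", "fungal_multiplier", "eco_rate",
                  "ff_rate")])
  for (dom in c("bacteria", "fungi")) {
    n_taxa <- if (dom == "bacteria") design$n_bacteria else design$n_fungi
    prefix <- if (dom == "bacteria") "bOTU" else "fOTU"
    p <- lognormal_metacommunity(n_taxa, seed = fork_seed(seed, paste0("meta_", dom)),
                                 prefix = prefix)
    set.seed(fork_seed(seed, paste0("optima_", dom)))
    optima <- stats::setNames(stats::runif(n_taxa), names(p))
    grad <- stats::setNames(seq(0, 1, length.out = length(groups)), groups)
    tabs <- lapply(groups, function(g) {
      reg <- design$assembly[[dom]][[g]]
      s <- fork_seed(seed, paste(dom, g, sep = "_"))
      if (reg$type == "neutral")
        simulate_neutral(p, reg$m, design$reads, reps[[g]], seed = s,
                         prefix = g)
      else
        simulate_filtered(p, grad[[g]], optima, reg$strength, design$reads,
                          reps[[g]], seed = s,
                          noise_sdlog = design$filter_noise_sdlog, prefix = g)
    })
    counts <- do.call(rbind, lapply(tabs, function(t) t$counts))
    tab <- abundance_table(counts)
    write_abundance_table(tab, file.path(dir, paste0("otu_", dom, ".tsv")))
    set.seed(fork_seed(seed, paste0("tree_", dom)))
    tree <- ape::rcoal(n_taxa, tip.label = sample(names(p)))
    ape::write.tree(tree, file.path(dir, paste0("tree_", dom, ".nwk")))
    truth[[paste0("metacommunity_", dom)]] <- as.list(p)
    truth[[paste0("assembly_", dom)]] <- design$assembly[[dom]]
  }

  # --- Biolog plates per sample ----------------------------------------------
  for (i in seq_len(nrow(md))) {
    g <- md$level[i]
    for (kind in c("ECO", "FF")) {
      mult <- if (kind == "ECO") design$eco_rate[[g]] else design$ff_rate[[g]]
      simulate_plate(kind, mult, noise_sd = design$plate_noise_sd,
                     seed = fork_seed(seed, paste("plate", kind, md$sample_id[i])),
                     path = file.path(dir, "plates",
                                      paste0(md$sample_id[i], "_", kind, ".csv")))
    }
  }

  # --- functional-gene CT table ----------------------------------------------
  catalog <- gene_catalog()
  set.seed(fork_seed(seed, "genes"))
  base_copies <- stats::rlnorm(nrow(catalog), design$gene_base_meanlog,
                               design$gene_base_sdlog)
  eff <- round(stats::rnorm(nrow(catalog), 2.0, 0.12), 3)
  copies <- matrix(0, nrow(catalog), nrow(md),
                   dimnames = list(catalog$gene, md$sample_id))
  for (i in seq_len(nrow(md))) {
    mult <- design$bacterial_multiplier[[md$level[i]]]
    copies[, i] <- base_copies * mult *
      stats::rlnorm(nrow(catalog), 0, design$gene_noise_sdlog)
  }
  ct <- design$detection_ct - (10 / 3) * log10(copies)
  ct[copies < 1] <- NA  # below one relative copy: non-detected
  ct <- round(ct, 3)
  ctdf <- data.frame(gene = catalog$gene, ct, check.names = FALSE)
  utils::write.csv(ctdf, file.path(dir, "genes_ct.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(data.frame(gene = catalog$gene, efficiency = eff),
                   file.path(dir, "gene_efficiency.csv"), row.names = FALSE,
                   quote = FALSE)
  truth$gene_base_copies <- as.list(stats::setNames(base_copies, catalog$gene))

  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, metadata = md, truth = truth))
}
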