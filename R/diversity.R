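#' Abundance-based coverage estimator (ACE) of richness
#'
#' Chao & Lee's estimator from the abundance structure of rare taxa
#' (counts <= `rare_cutoff`, conventionally 10):
#' \deqn{ACE = S_{abund} + S_{rare}/C_{ACE} + (F_1/C_{ACE})\gamma^2}
#' with sample coverage \eqn{C_{ACE} = 1 - F_1/N_{rare}} and \eqn{\gamma^2}
#' the rare-taxon coefficient of variation, floored at 0. When every rare
#' taxon is a singleton the coverage is 0 and the function falls back to
#' Chao1 with a warning.
#'
#' @param counts per-taxon counts of one sample.
#' @param rare_cutoff taxa with counts above this are "abundant" (default 10).
#' @return estimated richness (>= observed richness).
#' @export
ace_index <- function(counts, rare_cutoff = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all-zero sample: ACE undefined")
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_cutoff)  # f[i] = number of taxa with count i
  f1 <- f[1]
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("zero ACE coverage (all rare taxa singletons); falling back to Chao1")
    f2 <- f[2]
    return(length(counts) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rare_cutoff)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over taxa with positive counts.
#'
#' @param counts per-taxon counts of one sample.
#' @return H in nats.
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all-zero sample: Shannon undefined")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree spanning the root and
#' all present taxa (rooted convention: the path to the root is included).
#'
#' @param present_taxa character vector of tip labels present in the sample.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(present_taxa, tree) {
  present_taxa <- unique(present_taxa)
  miss <- setdiff(present_taxa, tree$tip.label)
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "))
  if (length(present_taxa) == 0) return(0)
  root <- ape::Ntip(tree) + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  used <- logical(max(tree$edge))
  for (tip in match(present_taxa, tree$tip.label)) {
    node <- tip
    while (node != root && !used[node]) {
      used[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(elen[used])
}

#' Partition taxa into abundant and rare
#'
#' Taxa with mean relative abundance across all samples above 1% (by
#' default) are "abundant"; all others, including the exact boundary, are
#' "rare".
#'
#' @param table an [abundance_table()].
#' @param cutoff relative-abundance boundary (default 0.01).
#' @return list with character vectors `abundant` and `rare` and the vector
#'   of mean relative abundances.
#' @export
split_abundant_rare <- function(table, cutoff = 0.01) {
  mra <- colMeans(relative_abundance(table))
  list(abundant = names(mra)[mra > cutoff],
       rare = names(mra)[mra <= cutoff],
       mean_relative_abundance = mra)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)} on counts.
#'
#' @param table an [abundance_table()] or a samples x taxa numeric matrix.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering and eigendecomposition; axes are ordered by
#' descending eigenvalue and negative eigenvalues are reported, not dropped.
#' Explained-variance fractions are computed over the positive eigenvalues.
#'
#' @param d square symmetric distance matrix.
#' @param k number of axes to keep (default all).
#' @return list of class `ordination_result`: `coordinates` (samples x axes),
#'   `eigenvalues`, `explained` (fractions over positive eigenvalues) and the
#'   input `distance` matrix.
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  if (is.null(k)) k <- n - 1
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-8]
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 explained = if (length(pos)) pos[seq_len(min(ncol(coords), length(pos)))] / sum(pos) else numeric(0),
                 distance = d),
            class = "ordination_result")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix via [vegan::adonis2()], with
#' the permutation stream fixed by `seed`. The p-value has resolution
#' 1/(n_perm + 1).
#'
#' @param d distance matrix (samples x samples) or `dist`.
#' @param groups factor of group labels, one per sample.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class `permanova_result`: `f` (pseudo-F), `r2`, `p`,
#'   `n_perm`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = df, permutations = n_perm)
  structure(list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1],
                 n_perm = n_perm, seed = seed),
            class = "permanova_result")
}

#' Group comparison with one-way ANOVA and a compact letter display
#'
#' Per-group mean and sd, the one-way ANOVA p-value, and letters assigned so
#' that groups sharing a letter are not significantly different at `alpha`
#' under Holm-adjusted pairwise t tests.
#'
#' @param values numeric response, one per sample.
#' @param groups factor of group labels.
#' @param alpha significance level for the letter display (default 0.05).
#' @return data.frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `letters`; the ANOVA p-value is attached as attribute `anova_p`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0 | is.na(within_var)))
    stop("zero within-group variance in all groups; ANOVA undefined")
  p_anova <- stats::anova(stats::aov(values ~ groups))$`Pr(>F)`[1]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "holm")$p.value
  lv <- levels(groups)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in rownames(pw)) for (j in colnames(pw)) {
    if (!is.na(pw[i, j]) && pw[i, j] < alpha) sig[i, j] <- sig[j, i] <- TRUE
  }
  letters_by_group <- cld_letters(sig, order(-tapply(values, groups, mean)))
  out <- data.frame(group = lv,
                    n = as.integer(table(groups)),
                    mean = as.numeric(tapply(values, groups, mean)),
                    sd = as.numeric(tapply(values, groups, stats::sd)),
                    letters = letters_by_group[lv],
                    stringsAsFactors = FALSE)
  attr(out, "anova_p") <- p_anova
  out
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix (TRUE = significantly different); `ord` orders groups (highest mean
# first) so the leading letter lands on the largest group.
cld_letters <- function(sig, ord) {
  lv <- rownames(sig)[ord]
  sets <- list(lv)  # start: one letter covering everything
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    a <- lv[i]; b <- lv[j]
    if (!sig[a, b]) next
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      if (all(c(a, b) %in% s)) {
        sets[[k]] <- setdiff(s, a)
        sets <- c(sets, list(setdiff(s, b)))
      }
    }
    # absorb sets contained in another
    keep <- !vapply(seq_along(sets), function(k)
      any(vapply(seq_along(sets), function(l)
        l != k && all(sets[[k]] %in% sets[[l]]), logical(1))), logical(1))
    sets <- unique(sets[keep])
  }
  lab <- stats::setNames(rep("", length(lv)), lv)
  for (k in seq_along(sets))
    for (g in sets[[k]]) lab[g] <- paste0(lab[g], letters[k])
  vapply(lab, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
         character(1))
}

#' Alpha diversity of every sample of a table
#'
#' @param table an [abundance_table()].
#' @param tree optional rooted tree for Faith PD; tips must cover the
#'   table's taxa present in each sample.
#' @param rare_cutoff ACE rare-abundance cutoff (default 10).
#' @return data.frame with one row per sample: `sample_id`, `observed`,
#'   `ace`, `shannon`, and `pd` when a tree is supplied.
#' @export
alpha_diversity <- function(table, tree = NULL, rare_cutoff = 10) {
  m <- table$counts
  out <- data.frame(
    sample_id = rownames(m),
    observed = rowSums(m > 0),
    ace = apply(m, 1, ace_index, rare_cutoff = rare_cutoff),
    shannon = apply(m, 1, shannon_index),
    stringsAsFactors = FALSE)
  if (!is.null(tree))
    out$pd <- apply(m, 1, function(x) faith_pd(colnames(m)[x > 0], tree))
  rownames(out) <- NULL
  out
}
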