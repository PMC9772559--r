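#' Filter taxa by mean relative abundance for network construction
#'
#' Retains taxa whose mean relative abundance across samples is strictly
#' above the cutoff (default 0.01%).
#'
#' @param table an [abundance_table()].
#' @param min_mean_relative_abundance strict lower bound (default 1e-4).
#' @return a reduced [abundance_table()].
#' @export
filter_taxa <- function(table, min_mean_relative_abundance = 1e-4) {
  mra <- colMeans(relative_abundance(table))
  keep <- mra > min_mean_relative_abundance
  if (!any(keep))
    stop("no taxa above the abundance cutoff; lower min_mean_relative_abundance")
  abundance_table(table$counts[, keep, drop = FALSE],
                  if (is.null(table$taxonomy)) NULL else
                    table$taxonomy[intersect(names(table$taxonomy),
                                             colnames(table$counts)[keep])])
}

# log10 relative abundances with half-minimum replacement of zeros;
# used before Pearson correlation (abundances are heavy-tailed).
log_relative_abundance <- function(m) {
  rel <- sweep(m, 1, rowSums(m), "/")
  minpos <- min(rel[rel > 0])
  rel[rel == 0] <- minpos / 2
  log10(rel)
}

#' Pearson correlation matrix over taxa
#'
#' Correlations are computed on log10 relative abundances, replacing zeros
#' with half the smallest positive relative abundance. Taxa with zero
#' variance across samples are dropped with a warning.
#'
#' @param table an [abundance_table()] (typically after [filter_taxa()]).
#' @return symmetric taxa x taxa correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  m <- table$counts
  if (nrow(m) < 4) stop("need at least 4 samples for correlations")
  x <- log_relative_abundance(m)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance taxa: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  stats::cor(x)
}

# Unfold an eigenvalue spectrum to uniform mean spacing and return the
# nearest-neighbour spacing distribution (mean-normalised).
nnsd_spacings <- function(ev) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]  # degenerate eigenvalues carry no spacing info
  n <- length(ev)
  if (n < 20) return(NULL)
  cdf <- seq_len(n) / n
  sm <- stats::smooth.spline(ev, cdf, df = min(10, n - 1))
  unfolded <- n * stats::predict(sm, ev)$y
  sp <- diff(sort(unfolded))
  sp <- sp[sp > 0]
  if (length(sp) < 15) return(NULL)
  sp / mean(sp)
}

# Chi-square goodness of fit of spacings against the Poisson form e^(-s).
poisson_gof_p <- function(sp) {
  edges <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, Inf)
  obs <- table(cut(sp, edges))
  expp <- diff(stats::pexp(edges))
  expn <- length(sp) * expp
  chi2 <- sum((as.numeric(obs) - expn)^2 / expn)
  stats::pchisq(chi2, df = length(expp) - 2, lower.tail = FALSE)
}

#' Random-matrix-theory threshold selection
#'
#' Scans candidate cut-offs; for each, the adjacency matrix `|r| >= s` is
#' built and the nearest-neighbour spacing distribution (NNSD) of its
#' unfolded eigenvalue spectrum is tested against the Poisson form
#' \eqn{e^{-s}} by chi-square goodness of fit. The chosen threshold is the
#' smallest s whose NNSD is Poisson-consistent (p > 0.05) — the point where
#' random (Wigner-type) spectral correlations have decayed and surviving
#' structure is non-random. If the scan is exhausted the configured
#' fallback is returned with a warning.
#'
#' @param cm correlation matrix (>= 20 taxa for a meaningful spectrum).
#' @param scan numeric vector of candidate thresholds
#'   (default `seq(0.30, 0.95, 0.01)`).
#' @param fallback threshold used when no candidate passes (default 0.80).
#' @param p_cut NNSD Poisson-consistency level (default 0.05).
#' @return chosen threshold `s*`, with attribute `"p"` (the NNSD p-value) and
#'   `"fallback"` (logical).
#' @export
rmt_threshold <- function(cm, scan = seq(0.30, 0.95, by = 0.01),
                          fallback = 0.80, p_cut = 0.05) {
  if (nrow(cm) < 20) stop("need >= 20 taxa for a meaningful spectrum")
  a <- abs(cm); diag(a) <- 0
  for (s in scan) {
    adj <- (a >= s) * 1
    deg <- rowSums(adj)
    keep <- deg > 0
    if (sum(keep) < 20) break  # graph too sparse to test further
    ev <- eigen(adj[keep, keep], symmetric = TRUE, only.values = TRUE)$values
    sp <- nnsd_spacings(ev)
    if (is.null(sp)) next
    p <- poisson_gof_p(sp)
    if (p > p_cut)
      return(structure(s, p = p, fallback = FALSE))
  }
  warning("RMT scan exhausted; using fallback threshold ", fallback)
  structure(fallback, p = NA_real_, fallback = TRUE)
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Edges connect taxon pairs with `|r| >= s*`; the correlation and its sign
#' are kept as edge attributes, isolated taxa are dropped, and modules are
#' detected by seeded greedy modularity maximisation (on absolute weights).
#'
#' @param cm correlation matrix.
#' @param threshold cut-off `s*` in (0, 1).
#' @param domains optional named character vector (taxon -> domain tag such
#'   as `"bacteria"`, `"fungi"`, `"gene"`), stored as a vertex attribute.
#' @param seed seed for module detection (default 1).
#' @param method community detection: `"greedy"` (default) or `"louvain"`.
#' @return a `co_network`: list with `graph` (igraph, attributes `weight`,
#'   `sign`), `threshold`, `membership` (named module ids).
#' @export
build_network <- function(cm, threshold, domains = NULL, seed = 1,
                         method = c("greedy", "louvain")) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  a <- cm; diag(a) <- 0
  idx <- which(abs(a) >= threshold & upper.tri(a), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no edges at threshold ", threshold)
  edges <- data.frame(from = rownames(a)[idx[, 1]],
                      to = colnames(a)[idx[, 2]],
                      r = a[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(edges$r)
  igraph::E(g)$r <- edges$r
  igraph::E(g)$sign <- ifelse(edges$r >= 0, "positive", "negative")
  if (!is.null(domains))
    igraph::V(g)$domain <- unname(domains[igraph::V(g)$name])
  set.seed(seed)
  comm <- if (method == "greedy") igraph::cluster_fast_greedy(g)
          else igraph::cluster_louvain(g)
  membership <- stats::setNames(as.integer(igraph::membership(comm)),
                                igraph::V(g)$name)
  structure(list(graph = g, threshold = threshold, membership = membership),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges, threshold %.2f, %d modules\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, length(unique(x$membership))))
  invisible(x)
}

#' Topological indices of a co-occurrence network
#'
#' Node/edge counts, the fraction of positive edges, the average local
#' clustering coefficient (nodes with degree < 2 contribute 0), the average
#' shortest-path distance GD (unweighted, over the largest connected
#' component when the graph is disconnected), and the modularity of the
#' detected partition.
#'
#' @param net a `co_network`.
#' @return list of class `topology_report` with `nodes`, `edges`,
#'   `positive_fraction`, `avg_cc`, `gd`, `modularity`.
#' @export
topology <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0) stop("network has no edges")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    message("graph disconnected; GD computed on the largest component")
    sub <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
  } else sub <- g
  structure(list(
    nodes = igraph::vcount(g),
    edges = igraph::ecount(g),
    positive_fraction = mean(igraph::E(g)$sign == "positive"),
    avg_cc = mean(igraph::transitivity(g, type = "localundirected",
                                       isolates = "zero", weights = NA)),
    gd = igraph::mean_distance(sub, weights = NA),
    modularity = igraph::modularity(g, net$membership[igraph::V(g)$name],
                                    weights = NULL)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "nodes %d | edges %d | +edges %.1f%% | avgCC %.3f | GD %.3f | M %.3f\n",
    x$nodes, x$edges, 100 * x$positive_fraction, x$avg_cc, x$gd, x$modularity))
  invisible(x)
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' For each node, \eqn{Z_i} is the z-score of its within-module degree
#' relative to its module (0 when the module's within-degrees have zero
#' spread), and \eqn{P_i = 1 - \sum_m (k_{i,m}/k_i)^2} over modules m.
#' Nodes are labelled peripheral / connector / module hub / network hub by
#' the classical cut-offs, and flagged keystone when `Zi >= z_cut` or
#' `Pi >= p_cut`.
#'
#' @param net a `co_network` with a module partition.
#' @param z_cut module-hub cut-off on Zi (default 2.5).
#' @param p_cut connector cut-off on Pi (default 0.62).
#' @return data.frame: `node`, `module`, `degree`, `zi`, `pi`, `role`,
#'   `keystone`.
#' @export
zi_pi <- function(net, z_cut = 2.5, p_cut = 0.62) {
  g <- net$graph
  mem <- net$membership[igraph::V(g)$name]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(mem))
  k_by_mod <- vapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]),
                     numeric(length(k)))
  k_within <- k_by_mod[cbind(seq_along(k), match(mem, mods))]
  zi <- numeric(length(k))
  for (m in mods) {
    in_m <- mem == m
    mu <- mean(k_within[in_m]); s <- stats::sd(k_within[in_m])
    zi[in_m] <- if (is.na(s) || s == 0) 0 else (k_within[in_m] - mu) / s
  }
  pi <- 1 - rowSums((k_by_mod / k)^2)
  role <- ifelse(zi >= z_cut & pi >= p_cut, "network hub",
          ifelse(zi >= z_cut, "module hub",
          ifelse(pi >= p_cut, "connector", "peripheral")))
  data.frame(node = igraph::V(g)$name, module = unname(mem),
             degree = unname(k), zi = zi, pi = pi, role = role,
             keystone = zi >= z_cut | pi >= p_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network robustness under random node removal
#'
#' Each iteration removes a uniform random `removal_fraction` of the nodes,
#' then iteratively prunes surviving nodes left with no edges (secondary
#' extinctions); robustness is the surviving fraction of the original
#' nodes, reported as mean and sd over iterations.
#'
#' @param net a `co_network` with >= 4 nodes and >= 1 edge.
#' @param removal_fraction fraction of nodes removed (default 0.5).
#' @param iterations number of random removals (default 100).
#' @param seed integer seed.
#' @return list of class `stability_report` fragment: `mean`, `sd`,
#'   `iterations`, `removal_fraction`, `seed`, `values`.
#' @export
robustness <- function(net, removal_fraction = 0.5, iterations = 100, seed = 1) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 4) stop("need at least 4 nodes")
  if (igraph::ecount(g) == 0) stop("network has no edges")
  n_rm <- floor(removal_fraction * n)
  set.seed(seed)
  vals <- vapply(seq_len(iterations), function(i) {
    keep <- igraph::induced_subgraph(g, sample(n, n - n_rm))
    repeat {
      iso <- which(igraph::degree(keep) == 0)
      if (length(iso) == 0) break
      keep <- igraph::delete_vertices(keep, iso)
    }
    igraph::vcount(keep) / n
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), iterations = iterations,
       removal_fraction = removal_fraction, seed = seed, values = vals)
}

# global efficiency: mean over ordered node pairs of 1/shortest-path length
global_efficiency_of <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' The vulnerability of node i is the relative loss of global efficiency
#' when i is removed, \eqn{V_i = (E - E_{-i})/E}; the network's
#' vulnerability is the maximum over nodes. Computed on the largest
#' connected component.
#'
#' @param net a `co_network`.
#' @return list with `vulnerability` (max over nodes), `node` (the most
#'   critical node) and `per_node` (named vector).
#' @export
vulnerability <- function(net) {
  g <- net$graph
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(g) < 3) stop("largest component has fewer than 3 nodes")
  e0 <- global_efficiency_of(g)
  vi <- vapply(seq_len(igraph::vcount(g)), function(i)
    (e0 - global_efficiency_of(igraph::delete_vertices(g, i))) / e0,
    numeric(1))
  names(vi) <- igraph::V(g)$name
  list(vulnerability = max(vi), node = names(vi)[which.max(vi)], per_node = vi)
}

#' Combined stability report
#'
#' @inheritParams robustness
#' @return list of class `stability_report`: robustness mean/sd,
#'   vulnerability, iteration count, removal fraction, seed.
#' @export
stability <- function(net, removal_fraction = 0.5, iterations = 100, seed = 1) {
  rb <- robustness(net, removal_fraction, iterations, seed)
  vu <- vulnerability(net)
  structure(list(robustness_mean = rb$mean, robustness_sd = rb$sd,
                 vulnerability = vu$vulnerability,
                 iterations = iterations, removal_fraction = removal_fraction,
                 seed = seed),
            class = "stability_report")
}

#' Positive-edge fractions within and between domains
#'
#' Splits edges into bacteria-bacteria (B-B), fungi-fungi (F-F) and
#' bacteria-fungi (B-F) classes by the vertex `domain` attribute and
#' reports the positive fraction of each; classes without edges are `NA`.
#'
#' @param net a `co_network` whose graph has a `domain` vertex attribute
#'   with values `"bacteria"` and/or `"fungi"`.
#' @return named numeric vector `c(BB, FF, BF)` of positive-edge fractions.
#' @export
edge_domain_ratios <- function(net) {
  g <- net$graph
  dom <- igraph::V(g)$domain
  if (is.null(dom)) stop("network has no domain tags")
  ends <- igraph::ends(g, igraph::E(g))
  d1 <- dom[match(ends[, 1], igraph::V(g)$name)]
  d2 <- dom[match(ends[, 2], igraph::V(g)$name)]
  pos <- igraph::E(g)$sign == "positive"
  cls <- ifelse(d1 == "bacteria" & d2 == "bacteria", "BB",
         ifelse(d1 == "fungi" & d2 == "fungi", "FF", "BF"))
  out <- c(BB = NA_real_, FF = NA_real_, BF = NA_real_)
  for (k in names(out)) if (any(cls == k)) out[k] <- mean(pos[cls == k])
  out
}

#' Taxon-gene co-occurrence network
#'
#' Correlates taxon (e.g. genus-level) abundances with functional-gene
#' abundances across shared samples and keeps edges with `r >= threshold`
#' (positive by default, matching how taxon-function coupling is usually
#' displayed); both matrices are log10-transformed with half-minimum zero
#' replacement.
#'
#' @param table an [abundance_table()] of taxa.
#' @param gene_abund a `gene_abundance` from [qmec_quantify()].
#' @param threshold correlation cut-off.
#' @param keep `"positive"` (default) or `"all"` edge signs.
#' @param seed module-detection seed.
#' @return a `co_network` whose vertices carry `domain` tags `"taxon"` /
#'   `"gene"`, with attribute `"top_taxon"` naming the highest-degree taxon.
#' @export
taxon_gene_network <- function(table, gene_abund, threshold = 0.6,
                               keep = c("positive", "all"), seed = 1) {
  keep <- match.arg(keep)
  shared <- intersect(sample_ids(table), colnames(gene_abund$copies))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  tx <- log_relative_abundance(table$counts[shared, , drop = FALSE])
  gn <- t(gene_abund$copies[, shared, drop = FALSE])
  minpos <- min(gn[gn > 0])
  gn[gn == 0] <- minpos / 2
  gn <- log10(gn)
  keep_tx <- apply(tx, 2, stats::var) > 0
  keep_gn <- apply(gn, 2, stats::var) > 0
  r <- stats::cor(tx[, keep_tx, drop = FALSE], gn[, keep_gn, drop = FALSE])
  sel <- if (keep == "positive") r >= threshold else abs(r) >= threshold
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no taxon-gene edges at threshold ", threshold)
  edges <- data.frame(from = rownames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(edges$r)
  igraph::E(g)$r <- edges$r
  igraph::E(g)$sign <- ifelse(edges$r >= 0, "positive", "negative")
  igraph::V(g)$domain <- ifelse(igraph::V(g)$name %in% rownames(r),
                                "taxon", "gene")
  set.seed(seed)
  membership <- stats::setNames(
    as.integer(igraph::membership(igraph::cluster_fast_greedy(g))),
    igraph::V(g)$name)
  deg <- igraph::degree(g)
  taxa_deg <- deg[igraph::V(g)$domain == "taxon"]
  structure(list(graph = g, threshold = threshold, membership = membership,
                 top_taxon = names(taxa_deg)[which.max(taxa_deg)]),
            class = "co_network")
}
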