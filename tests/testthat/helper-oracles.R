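# Brute-force graph oracles, independent of igraph: direct formula
# implementations over adjacency matrices, used to cross-check every
# topology/stability computation on small graphs.

toy_table <- function(counts, samples = NULL, taxa = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- samples %||% paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- taxa %||% paste0("t", seq_len(ncol(counts)))
  abundance_table(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjacency from an edge list over n nodes
adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  a
}

# co_network from a 0/1 adjacency matrix and a fixed module partition
net_from_adj <- function(adj, membership = NULL, signs = NULL) {
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(adj)[idx[, 1]], to = colnames(adj)[idx[, 2]]),
    directed = FALSE, vertices = rownames(adj)[rowSums(adj) > 0])
  igraph::E(g)$weight <- 1
  igraph::E(g)$r <- 1
  igraph::E(g)$sign <- signs %||% rep("positive", nrow(idx))
  if (is.null(membership)) {
    set.seed(1)
    membership <- stats::setNames(
      as.integer(igraph::membership(igraph::cluster_fast_greedy(g))),
      igraph::V(g)$name)
  }
  structure(list(graph = g, threshold = 0.5, membership = membership),
            class = "co_network")
}

bf_shortest_paths <- function(adj) {      # Floyd-Warshall
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_components <- function(adj) {
  d <- bf_shortest_paths(adj)
  comp <- rep(NA_integer_, nrow(adj)); c0 <- 0
  for (i in seq_len(nrow(adj))) if (is.na(comp[i])) {
    c0 <- c0 + 1
    comp[is.finite(d[i, ])] <- c0
  }
  comp
}

bf_avg_cc <- function(adj) {
  n <- nrow(adj)
  cc <- vapply(1:n, function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
  mean(cc)
}

bf_gd <- function(adj) {                  # mean distance on largest component
  comp <- bf_components(adj)
  big <- which(comp == which.max(tabulate(comp)))
  d <- bf_shortest_paths(adj[big, big, drop = FALSE])
  mean(d[upper.tri(d)])
}

bf_modularity <- function(adj, mem) {
  m2 <- sum(adj)                          # 2m
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj)))
    if (mem[i] == mem[j]) q <- q + adj[i, j] - k[i] * k[j] / m2
  unname(q / m2)
}

bf_global_eff <- function(adj) {
  d <- bf_shortest_paths(adj)
  inv <- 1 / d; diag(inv) <- 0; inv[is.infinite(d)] <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

bf_vulnerability <- function(adj) {
  e0 <- bf_global_eff(adj)
  max(vapply(seq_len(nrow(adj)), function(i)
    (e0 - bf_global_eff(adj[-i, -i, drop = FALSE])) / e0, numeric(1)))
}

bf_zi_pi <- function(adj, mem) {
  k <- rowSums(adj)
  mods <- sort(unique(mem))
  kim <- vapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]),
                numeric(length(k)))
  kw <- kim[cbind(seq_along(k), match(mem, mods))]
  zi <- numeric(length(k))
  for (m in mods) {
    in_m <- mem == m
    s <- stats::sd(kw[in_m])
    zi[in_m] <- if (is.na(s) || s == 0) 0 else (kw[in_m] - mean(kw[in_m])) / s
  }
  list(zi = zi, pi = 1 - rowSums((kim / k)^2))
}

# small library of test graphs (all <= 12 nodes)
toy_graphs <- function() {
  k4 <- adj_from_edges(4, combn(4, 2, simplify = FALSE))
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  two_tri <- adj_from_edges(6, list(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))
  star6 <- adj_from_edges(6, lapply(2:6, function(i) c(1, i)))
  set.seed(42)
  rnd <- list()
  for (r in 1:3) {
    n <- 12
    a <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
    repeat {
      a[,] <- 0
      up <- which(upper.tri(a))
      on <- sample(up, 20)
      a[on] <- 1
      a <- pmax(a, t(a))
      if (all(rowSums(a) > 0)) break
    }
    rnd[[r]] <- a
  }
  c(list(k4 = k4, path3 = path3, two_triangles = two_tri, star6 = star6),
    stats::setNames(rnd, paste0("random", 1:3)))
}
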