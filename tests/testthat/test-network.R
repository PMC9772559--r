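test_that("taxon filtering applies the 0.01% mean-relative-abundance rule", {
  m <- rbind(c(20, 10, 5, 99965), c(20, 10, 5, 99965))
  tab <- toy_table(m)   # means: 2e-4, 1e-4 (boundary), 0.5e-4, filler
  red <- filter_taxa(tab, 1e-4)
  expect_setequal(taxon_ids(red), c("t1", "t4"))   # strict at the boundary
  expect_error(filter_taxa(tab, 0.9999), "no taxa")
})

test_that("correlations are Pearson on log abundances with unit diagonal", {
  set.seed(51)
  m <- matrix(rpois(4 * 5, 40) + 1, 4, 5)
  m[, 2] <- m[, 1] * 3                         # exactly proportional
  tab <- toy_table(m)
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm), setNames(rep(1, 5), taxon_ids(tab)))
  expect_equal(cm["t1", "t2"], 1)
  # matches the direct Pearson formula on the transformed data
  rel <- sweep(m, 1, rowSums(m), "/")
  x <- log10(rel)
  r_direct <- sum((x[, 1] - mean(x[, 1])) * (x[, 3] - mean(x[, 3]))) /
    sqrt(sum((x[, 1] - mean(x[, 1]))^2) * sum((x[, 3] - mean(x[, 3]))^2))
  expect_equal(cm["t1", "t3"], r_direct, tolerance = 1e-12)
  # equal sample depths with a constant taxon: zero variance on the log scale
  m2 <- matrix(c(30, 20, 40, 10,
                 20, 30, 40, 10,
                 25, 25, 40, 10,
                 35, 15, 40, 10), 4, 4, byrow = TRUE)
  expect_warning(cm2 <- correlation_matrix(toy_table(m2)), "zero-variance")
  expect_equal(ncol(cm2), 2)
  expect_error(correlation_matrix(toy_table(m[1:3, ])), "4 samples")
})

test_that("RMT threshold finds structure-preserving cutoffs and falls back", {
  # pure noise, few samples: a threshold is found within the scan
  set.seed(3)
  x <- matrix(rnorm(12 * 60), 12, 60); colnames(x) <- paste0("t", 1:60)
  s_noise <- suppressWarnings(rmt_threshold(cor(x)))
  expect_false(attr(s_noise, "fallback"))
  expect_lt(s_noise, 0.80)
  # planted blocks: threshold sits below the within-block correlation level
  set.seed(2)
  blocks <- lapply(1:3, function(b) {
    f <- rnorm(40); sapply(1:10, function(i) 0.9 * f + 0.45 * rnorm(40))
  })
  xb <- do.call(cbind, blocks); colnames(xb) <- paste0("t", 1:30)
  cb <- cor(xb)
  within <- mean(cb[1:10, 1:10][upper.tri(diag(10))])
  s_blk <- suppressWarnings(rmt_threshold(cb))
  expect_false(attr(s_blk, "fallback"))
  expect_lt(s_blk, within)
  net <- build_network(cb, as.numeric(s_blk))
  expect_gt(igraph::ecount(net$graph), 0)      # blocks preserved as edges
  # scan exhausted -> declared fallback
  expect_warning(s_fb <- rmt_threshold(diag(25) + 0.01), "fallback")
  expect_equal(as.numeric(s_fb), 0.80)
  expect_error(rmt_threshold(diag(5)), "20 taxa")
})

test_that("network construction keeps signs, drops isolates, finds modules", {
  cm <- diag(6)
  rownames(cm) <- colnames(cm) <- paste0("t", 1:6)
  cm["t1", "t2"] <- cm["t2", "t1"] <- 0.9
  cm["t3", "t4"] <- cm["t4", "t3"] <- -0.9
  net <- build_network(cm, 0.8)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(igraph::vcount(net$graph), 4)   # t5, t6 isolated -> dropped
  expect_setequal(igraph::E(net$graph)$sign, c("positive", "negative"))
  expect_error(build_network(cm, 0.95), "no edges")
  expect_error(build_network(cm, 1.2), "in \\(0,1\\)")
  # two disconnected triangles resolve into two modules
  adj <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                c(4, 5), c(5, 6), c(4, 6)))
  cm2 <- adj * 0.9 + diag(6)
  dimnames(cm2) <- dimnames(adj)
  net2 <- build_network(cm2, 0.8)
  expect_equal(length(unique(net2$membership)), 2)
  expect_equal(unname(net2$membership["v1"]), unname(net2$membership["v2"]))
})

test_that("topology matches hand values and brute force on every small graph", {
  k4 <- net_from_adj(toy_graphs()$k4)
  tk4 <- topology(k4)
  expect_equal(tk4$avg_cc, 1)
  expect_equal(tk4$gd, 1)
  expect_equal(tk4$positive_fraction, 1)
  p3 <- net_from_adj(toy_graphs()$path3)
  tp3 <- topology(p3)
  expect_equal(tp3$gd, 4 / 3)
  expect_equal(tp3$avg_cc, 0)
  for (nm in names(toy_graphs())) {
    adj <- toy_graphs()[[nm]]
    mem <- setNames(rep(1:2, length.out = nrow(adj)), rownames(adj))
    net <- net_from_adj(adj, membership = mem)
    topo <- suppressMessages(topology(net))
    expect_equal(topo$avg_cc, bf_avg_cc(adj), tolerance = 1e-12, label = nm)
    expect_equal(topo$gd, bf_gd(adj), tolerance = 1e-12, label = nm)
    expect_equal(topo$modularity, bf_modularity(adj, mem), tolerance = 1e-12,
                 label = nm)
  }
})

test_that("Zi-Pi follow their formulas with degree conservation", {
  adj <- toy_graphs()$two_triangles
  mem <- setNames(c(1, 1, 1, 2, 2, 2), rownames(adj))
  roles <- zi_pi(net_from_adj(adj, membership = mem))
  expect_true(all(roles$pi == 0))              # all links inside own module
  expect_true(all(roles$zi == 0))              # uniform within-degree
  # bridge node splitting links across two modules
  adj2 <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  mem2 <- setNames(c(1, 1, 1, 2, 2), rownames(adj2))
  roles2 <- zi_pi(net_from_adj(adj2, membership = mem2))
  hub <- roles2[roles2$node == "v1", ]
  expect_equal(hub$pi, 0.5)                    # 1 - 2*(2/4)^2
  for (nm in c("random1", "random2", "random3")) {
    adj <- toy_graphs()[[nm]]
    mem <- setNames(rep(1:3, length.out = nrow(adj)), rownames(adj))
    roles <- zi_pi(net_from_adj(adj, membership = mem))
    oracle <- bf_zi_pi(adj, mem)
    expect_equal(roles$zi, unname(oracle$zi), tolerance = 1e-12)
    expect_equal(roles$pi, unname(oracle$pi), tolerance = 1e-12)
    expect_equal(roles$degree, unname(rowSums(adj)))   # sum_m k_im = k_i
  }
  # keystone set shrinks as cutoffs rise
  adj <- toy_graphs()$random1
  mem <- setNames(rep(1:3, length.out = 12), rownames(adj))
  net <- net_from_adj(adj, membership = mem)
  loose <- sum(zi_pi(net, z_cut = 0.5, p_cut = 0.3)$keystone)
  tight <- sum(zi_pi(net, z_cut = 2.5, p_cut = 0.62)$keystone)
  expect_lte(tight, loose)
})

test_that("robustness of K10 is exactly 0.5; hubs drive star collapse", {
  k10 <- net_from_adj(adj_from_edges(10, combn(10, 2, simplify = FALSE)))
  rb <- robustness(k10, 0.5, iterations = 50, seed = 9)
  expect_equal(rb$mean, 0.5)
  expect_equal(rb$sd, 0)
  star <- net_from_adj(toy_graphs()$star6)
  rbs <- robustness(star, 0.5, iterations = 200, seed = 9)
  # hub removed (p = 1/2) -> total collapse; hub kept -> 3 survivors:
  # expectation (1/2)*0 + (1/2)*0.5 = 0.25
  expect_lt(rbs$mean, 0.5)
  expect_equal(rbs$mean, 0.25, tolerance = 0.06)
  expect_error(robustness(net_from_adj(toy_graphs()$path3)), "4 nodes")
})

test_that("vulnerability: zero for complete graphs, cut vertices critical", {
  k4 <- net_from_adj(toy_graphs()$k4)
  expect_equal(vulnerability(k4)$vulnerability, 0)
  p3 <- net_from_adj(toy_graphs()$path3)
  vp <- vulnerability(p3)
  expect_equal(vp$node, "v2")                  # the cut vertex
  expect_equal(vp$vulnerability, bf_vulnerability(toy_graphs()$path3),
               tolerance = 1e-12)
  star <- net_from_adj(toy_graphs()$star6)
  vs <- vulnerability(star)
  expect_equal(vs$node, "v1")
  expect_gt(vs$vulnerability, 0)
  for (nm in names(toy_graphs())) {
    adj <- toy_graphs()[[nm]]
    comp <- bf_components(adj)
    big <- which(comp == which.max(tabulate(comp)))
    expect_equal(vulnerability(net_from_adj(adj))$vulnerability,
                 bf_vulnerability(adj[big, big]), tolerance = 1e-12,
                 label = nm)
  }
})

test_that("interdomain edge ratios count signs per class", {
  adj <- adj_from_edges(4, list(c(1, 2), c(3, 4), c(1, 3), c(1, 4), c(2, 3),
                                c(2, 4)))
  # edge order is column-major over the upper triangle:
  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  net <- net_from_adj(adj, membership = setNames(rep(1, 4), rownames(adj)),
                      signs = c("positive", "positive", "positive", "negative",
                                "positive", "negative"))
  igraph::V(net$graph)$domain <- c("bacteria", "bacteria", "fungi", "fungi")
  r <- edge_domain_ratios(net)
  expect_equal(unname(r["BB"]), 1)             # v1-v2 positive
  expect_equal(unname(r["FF"]), 0)             # v3-v4 negative
  expect_equal(unname(r["BF"]), 3 / 4)
  only_b <- net_from_adj(adj_from_edges(3, list(c(1, 2), c(2, 3))),
                         membership = setNames(rep(1, 3), paste0("v", 1:3)))
  igraph::V(only_b$graph)$domain <- rep("bacteria", 3)
  rb <- edge_domain_ratios(only_b)
  expect_true(is.na(rb["FF"]) && is.na(rb["BF"]))
  expect_equal(unname(rb["BB"]), 1)
})

test_that("taxon-gene networks keep the requested edge signs", {
  set.seed(61)
  m <- t(rmultinom(8, 500, rep(1, 6)))                # equal depths, no zeros
  tab <- toy_table(m)
  copies <- rbind(g_pos = m[, 1] * 2,                 # log-proportional to t1
                  g_neg = 1e6 / m[, 2],               # exact log anticorrelation
                  g_rand = rpois(8, 30) + 1)
  colnames(copies) <- sample_ids(tab)
  ab <- structure(list(copies = copies,
                       cycle = setNames(rep("C", 3), rownames(copies)),
                       detection_ct = 31), class = "gene_abundance")
  net <- taxon_gene_network(tab, ab, threshold = 0.9)
  ends <- igraph::ends(net$graph, igraph::E(net$graph))
  expect_true(any(ends[, 1] == "t1" & ends[, 2] == "g_pos" |
                  ends[, 1] == "g_pos" & ends[, 2] == "t1"))
  expect_false("negative" %in% igraph::E(net$graph)$sign)
  all_net <- taxon_gene_network(tab, ab, threshold = 0.9, keep = "all")
  expect_true("negative" %in% igraph::E(all_net$graph)$sign)
  expect_true(net$top_taxon %in% taxon_ids(tab))
  expect_error(taxon_gene_network(toy_table(m[1:3, ]),
                                  structure(list(copies = copies[, 1:3],
                                                 cycle = ab$cycle,
                                                 detection_ct = 31),
                                            class = "gene_abundance"),
                                  0.9), "4 shared samples")
})
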