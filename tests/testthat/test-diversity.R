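test_that("ACE reduces to observed richness without rare taxa and matches vegan", {
  expect_equal(ace_index(c(20, 15, 12)), 3)
  expect_equal(ace_index(11), 1)
  cts <- c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L)
  expect_equal(ace_index(cts),
               unname(vegan::estimateR(cts)["S.ACE"]), tolerance = 1e-10)
  # random mixtures against the independent estimator
  set.seed(4)
  for (i in 1:5) {
    cts <- as.integer(rpois(40, 4) + 1)
    oracle <- suppressWarnings(unname(vegan::estimateR(cts)["S.ACE"]))
    expect_equal(ace_index(cts), oracle, tolerance = 1e-10)
  }
  expect_error(ace_index(c(0, 0)), "all-zero")
  expect_warning(chao <- ace_index(c(1, 1, 1, 20)), "Chao1")
  expect_gte(chao, 4)
  set.seed(5)
  for (i in 1:20) {                        # ACE never below observed richness
    cts <- rpois(30, 2)
    cts[1] <- cts[1] + 1
    est <- suppressWarnings(ace_index(cts))
    expect_gte(est + 1e-9, sum(cts > 0))
  }
})

test_that("Shannon index: uniform maximum, singleton zero, direct arithmetic", {
  expect_equal(shannon_index(rep(7, 4)), log(4))
  expect_equal(shannon_index(42), 0)
  expect_equal(shannon_index(c(1, 1, 2)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_error(shannon_index(0), "all-zero")
})

test_that("Faith PD spans the right branches and matches picante", {
  star <- read_newick("(A:1,B:1,C:1);")
  expect_equal(faith_pd(c("A", "B", "C"), star), 3)
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(faith_pd("A", tr), 2)       # tip branch + stem to root
  expect_equal(faith_pd(c("A", "B", "C"), tr), 5)
  expect_error(faith_pd("Z", tr), "Z")
  # monotone under taxon addition, and equal to picante's rooted PD
  set.seed(8)
  big <- ape::rcoal(20)
  skip_if_not_installed("picante")
  pd_prev <- 0
  present <- character(0)
  for (tip in sample(big$tip.label, 8)) {
    present <- c(present, tip)
    pd_now <- faith_pd(present, big)
    expect_gte(pd_now, pd_prev - 1e-12)
    pd_prev <- pd_now
    comm <- matrix(as.integer(big$tip.label %in% present), 1,
                   dimnames = list("s", big$tip.label))
    expect_equal(pd_now, picante::pd(comm, big, include.root = TRUE)$PD,
                 tolerance = 1e-10)
  }
})

test_that("abundant/rare partition uses mean relative abundance with 1% boundary", {
  m <- matrix(c(150, 50, 800, 150, 50, 800), 2, 3, byrow = TRUE)
  part <- split_abundant_rare(toy_table(m))
  expect_setequal(part$abundant, c("t1", "t2", "t3"))
  m2 <- rbind(c(15, 5, 980), c(15, 5, 980))          # t2 at exactly 0.5%
  part2 <- split_abundant_rare(toy_table(m2))
  expect_true("t2" %in% part2$rare)
  expect_true("t1" %in% part2$abundant)               # 1.5% mean
  m3 <- rbind(c(10, 990), c(10, 990))                 # exactly 1% -> rare
  expect_true("t1" %in% split_abundant_rare(toy_table(m3))$rare)
})

test_that("Bray-Curtis has its closed-form values and bounds", {
  tab <- toy_table(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 1, 0), c(5, 0, 0),
                         c(0, 0, 7)))
  d <- bray_curtis(tab)
  expect_equal(d["s1", "s2"], 0.5)                    # 2/4
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s4", "s5"], 1)                      # disjoint
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(bray_curtis(toy_table(rbind(c(1, 1, 0), c(0, 0, 0)))),
               "zero total")
})

test_that("PCoA reproduces Euclidean-embeddable geometry", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- suppressWarnings(pcoa(d3))
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-8]
  expect_equal(pos[1], pos[2], tolerance = 1e-8)      # equilateral symmetry
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d3), tolerance = 1e-8)
  # random Euclidean configuration reconstructs to 1e-8
  set.seed(11)
  x <- matrix(rnorm(6 * 3), 6)
  de <- as.matrix(dist(x)); dimnames(de) <- list(paste0("s", 1:6), paste0("s", 1:6))
  orde <- suppressWarnings(pcoa(de))
  k <- sum(orde$eigenvalues > 1e-8)
  expect_equal(unname(as.matrix(dist(orde$coordinates[, 1:k]))), unname(de),
               tolerance = 1e-8)
  dup <- de; dup["s2", ] <- de["s1", ]; dup[, "s2"] <- de[, "s1"]
  dup["s1", "s2"] <- dup["s2", "s1"] <- 0
  ordd <- suppressWarnings(pcoa(dup))
  expect_equal(ordd$coordinates["s1", ], ordd$coordinates["s2", ],
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_lt(sum(ord$explained), 1 + 1e-12)
})

test_that("PERMANOVA is seeded, permutation-invariant and detects separation", {
  set.seed(21)
  m <- rbind(t(replicate(8, rpois(20, c(rep(50, 10), rep(2, 10))))),
             t(replicate(8, rpois(20, c(rep(2, 10), rep(50, 10))))))
  tab <- toy_table(m)
  d <- bray_curtis(tab)
  gr <- rep(c("a", "b"), each = 8)
  r1 <- permanova(d, gr, n_perm = 99, seed = 5)
  r2 <- permanova(d, gr, n_perm = 99, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$p, 1 / 100)                  # maximal separation
  expect_gt(r1$r2, 0.5)
  o <- sample(16)
  r3 <- permanova(d[o, o], gr[o], n_perm = 99, seed = 5)
  expect_equal(r3$f, r1$f, tolerance = 1e-10)  # F invariant to sample order
  expect_error(permanova(d, rep("a", 10)), "2 groups")
  expect_error(permanova(d, c("a", rep("b", 9))), "at least 2 samples")
})

test_that("group comparison letters separate distant groups, merge identical ones", {
  set.seed(31)
  same <- rnorm(12)
  gc1 <- group_compare(same, rep(c("x", "y", "z"), each = 4))
  expect_true(all(gc1$letters == "a"))
  far <- c(rnorm(5), rnorm(5, 10), rnorm(5, 20))   # 10 pooled sd apart
  gc2 <- group_compare(far, rep(c("x", "y", "z"), each = 5))
  expect_equal(length(unique(gc2$letters)), 3)
  expect_lt(attr(gc2, "anova_p"), 1e-6)
  # ANOVA F equals the direct formula on a 3x3 toy table
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- factor(rep(c("a", "b", "c"), each = 3))
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  f_direct <- (ssb / 2) / (ssw / 6)
  fit <- stats::anova(stats::aov(vals ~ grp))
  expect_equal(fit$`F value`[1], f_direct, tolerance = 1e-10)
  expect_error(group_compare(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})
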