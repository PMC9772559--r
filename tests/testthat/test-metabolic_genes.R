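make_flat_plate <- function(kind, value, control = 0.3, times = c(0, 168)) {
  sc <- substrate_scheme(kind)
  od <- matrix(control, nrow(sc), length(times),
               dimnames = list(sc$well, times))
  od[sc$group != "control", ] <- value
  structure(list(kind = kind, od = od, times = times), class = "raw_plate")
}

test_that("control correction averages replicates, subtracts, floors at zero", {
  pl <- make_flat_plate("ECO", 0.3)           # wells equal to control
  prof <- correct_od(pl)
  expect_true(all(prof$corrected == 0))
  expect_equal(nrow(prof$corrected), 31)
  prof2 <- correct_od(make_flat_plate("ECO", 0.8))
  expect_true(all(abs(prof2$corrected - 0.5) < 1e-12))
  prof3 <- correct_od(make_flat_plate("ECO", 0.2))   # below control -> floored
  expect_true(all(prof3$corrected == 0))
  ff <- correct_od(make_flat_plate("FF", 0.9))
  expect_equal(nrow(ff$corrected), 95)
  expect_error(correct_od(make_flat_plate("ECO", 0.5),
                          substrate_scheme("FF")), "kind")
})

test_that("AWCD is the substrate mean at the requested time", {
  prof <- correct_od(make_flat_plate("ECO", 0.8))
  expect_equal(awcd(prof, 168), 0.5)
  expect_equal(awcd(correct_od(make_flat_plate("ECO", 0.3)), 168), 0)
  v <- seq(0, 3, length.out = 31)
  prof$corrected[, 2] <- v
  expect_equal(awcd(prof, 168), mean(v))
  expect_error(awcd(prof, 72), "available")
  # AWCD equals the group-size-weighted mean of group intensities
  gi <- substrate_group_intensity(prof, time = 168)
  sizes <- table(unique(substrate_scheme("ECO")[
    substrate_scheme("ECO")$group != "control",
    c("substrate", "group")])$group)[names(gi)]
  expect_equal(sum(gi * as.numeric(sizes)) / 31, awcd(prof, 168))
})

test_that("substrate groups carry the plates' published sizes", {
  prof <- correct_od(make_flat_plate("ECO", 0.7))
  gi <- substrate_group_intensity(prof, time = 168)
  expect_equal(length(gi), 6)
  expect_true(all(abs(gi - 0.4) < 1e-12))     # uniform plate -> uniform groups
  gff <- substrate_group_intensity(correct_od(make_flat_plate("FF", 0.7)),
                                   time = 168)
  expect_equal(length(gff), 8)
})

test_that("functional diversity: uniform maxima and the Euclidean-norm identity", {
  prof <- correct_od(make_flat_plate("ECO", 0.8))   # 31 equal positives
  div <- functional_diversity(prof, 168)
  expect_equal(div[["H"]], log(31))
  expect_equal(div[["D"]], 1 - 1 / 31)
  expect_equal(div[["U"]], sqrt(31 * 0.25))
  prof$corrected[, 2] <- c(3, 4, rep(0, 29))
  expect_equal(functional_diversity(prof, 168)[["U"]], 5)
  # U scales linearly under scalar multiplication
  prof$corrected[, 2] <- runif(31)
  u1 <- functional_diversity(prof, 168)[["U"]]
  prof$corrected <- prof$corrected * 3
  expect_equal(functional_diversity(prof, 168)[["U"]], 3 * u1)
  prof$corrected[] <- 0
  expect_error(functional_diversity(prof, 168), "all corrected")
})

test_that("efficiency filter keeps the 1.8-2.2 window", {
  eff <- c(ok = 2.0, hot = 2.3, cold = 1.7, lo = 1.8, hi = 2.2)
  expect_message(kept <- efficiency_filter(eff), "hot, cold")
  expect_setequal(kept, c("ok", "lo", "hi"))
  expect_error(efficiency_filter(c(a = -1)), "> 0")
})

test_that("CT quantification decays below the detection limit, zero at it", {
  ct <- matrix(c(27.667, 31, NA, 21), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ab <- qmec_quantify(ct)
  expect_equal(ab$copies["g1", "s1"], 10^((31 - 27.667) * 0.3), tolerance = 1e-9)
  expect_equal(ab$copies["g2", "s1"], 0)     # at the limit
  expect_equal(ab$copies["g1", "s2"], 0)     # non-detected
  expect_equal(ab$copies["g2", "s2"], 1000)  # 10 cycles = 3 logs
  cts <- seq(20, 30.9, by = 0.5)
  vals <- qmec_quantify(matrix(cts, ncol = 1,
                               dimnames = list(paste0("g", seq_along(cts)),
                                               "s")))$copies[, 1]
  expect_true(all(diff(vals) < 0))           # strictly decreasing in CT
  scaled <- qmec_quantify(ct, scale = c(2, 10))
  expect_equal(scaled$copies["g2", "s2"], 10000)
})

test_that("cycle sums conserve the grand total and compare groups", {
  set.seed(12)
  ct <- matrix(runif(8 * 6, 22, 30), 8, 6,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  genes <- structure(list(ct = ct,
                          cycle = setNames(rep(c("C", "N"), each = 4),
                                           rownames(ct))),
                     class = "gene_ct")
  ab <- qmec_quantify(genes)
  cs <- cycle_summaries(ab, groups = rep(c("CK", "H"), each = 3))
  expect_equal(unname(colSums(cs$per_category)),
               unname(cs$per_sample_total))
  expect_equal(unname(cs$per_sample_total), unname(colSums(ab$copies)))
  expect_true(all(c("C", "N") %in% cs$group_letters$category))
  one <- cycle_summaries(
    structure(list(copies = ab$copies,
                   cycle = setNames(rep("C", 8), rownames(ct)),
                   detection_ct = 31), class = "gene_abundance"))
  expect_equal(one$per_category["C", ], cs$per_sample_total)
})
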