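test_that("region histograms are unit-area densities on shared edges", {
  set.seed(17)
  tc <- two_class_dop(runif(500, -1, 1), rnorm(800, 0, 0.2))
  h <- region_histograms(tc$dop, tc$mask)
  expect_length(h$tumor_density, 80)
  expect_equal(sum(h$tumor_density) * h$bin_width, 1, tolerance = 1e-12)
  expect_equal(sum(h$nontumor_density) * h$bin_width, 1, tolerance = 1e-12)
  expect_true(all(h$tumor_density >= 0))
  expect_equal(unname(h$counts), c(500, 800))

  # delta distribution: all mass in one bin at density 1/width
  tc2 <- two_class_dop(rep(0.3, 50), rep(-0.2, 50))
  h2 <- region_histograms(tc2$dop, tc2$mask)
  expect_equal(max(h2$tumor_density), 1 / h2$bin_width)
  expect_equal(sum(h2$tumor_density > 0), 1)
})

test_that("uniform values give flat densities near 0.5", {
  set.seed(23)
  n <- 1e6
  tc <- two_class_dop(runif(n, -1, 1), runif(1000, -1, 1))
  h <- region_histograms(tc$dop, tc$mask)
  se <- sqrt(0.5 / (n * h$bin_width))   # binomial SE of a density estimate
  expect_true(all(abs(h$tumor_density - 0.5) < 3.5 * se))
})

test_that("empty classes are reported by name", {
  d <- dop_image(matrix(0.1, 4, 4), "circular")
  expect_error(region_histograms(d, matrix(TRUE, 4, 4)), "nontumor")
  expect_error(region_histograms(d, matrix(FALSE, 4, 4)), "tumor")
})

test_that("overlap endpoints, symmetry, scale invariance, Gaussian oracle", {
  tc_id <- two_class_dop(rep(c(-.5, .5), 100), rep(c(-.5, .5), 100))
  expect_equal(overlap_area(region_histograms(tc_id$dop, tc_id$mask))$overlap_area, 1)

  tc_dis <- two_class_dop(runif(200, 0.5, 0.9), runif(200, -0.9, -0.5))
  expect_equal(overlap_area(region_histograms(tc_dis$dop, tc_dis$mask))$overlap_area, 0)

  set.seed(29)
  a <- rnorm(4000, 0.2, 0.15); b <- rnorm(6000, -0.1, 0.15)
  o_ab <- overlap_area(region_histograms(two_class_dop(a, b)$dop,
                                         two_class_dop(a, b)$mask))
  o_ba <- overlap_area(region_histograms(two_class_dop(b, a)$dop,
                                         two_class_dop(b, a)$mask))
  expect_equal(o_ab$overlap_area, o_ba$overlap_area, tolerance = 1e-12)
  # pixel-count scaling invariance: triple one class
  o_3a <- overlap_area(region_histograms(two_class_dop(rep(a, 3), b)$dop,
                                         two_class_dop(rep(a, 3), b)$mask))
  expect_equal(o_3a$overlap_area, o_ab$overlap_area, tolerance = 1e-12)

  # two equal-variance Gaussians with delta-mu = 2 sd: OVL = 2 Phi(-1)
  set.seed(31)
  g1 <- rnorm(1e5, 0.15, 0.15); g2 <- rnorm(1e5, -0.15, 0.15)
  tc <- two_class_dop(g1, g2)
  ovl <- overlap_area(region_histograms(tc$dop, tc$mask))$overlap_area
  expect_equal(ovl, 2 * pnorm(-1), tolerance = 0.01)
})

test_that("roc_curve counts conserve classes and sweep the stated grid", {
  set.seed(37)
  tc <- two_class_dop(rnorm(3000, 0.3, 0.15), rnorm(5000, 0, 0.15))
  roc <- roc_curve(tc$dop, tc$mask)
  tab <- roc$table
  expect_equal(tab$threshold, seq(-0.95, 0.95, by = 0.05), tolerance = 1e-12)
  expect_equal(nrow(tab), 39)
  expect_true(all(tab$TP + tab$FN == 3000))
  expect_true(all(tab$TN + tab$FP == 5000))
  # monotone: rising threshold never raises sensitivity, never lowers specificity
  expect_true(all(diff(tab$sensitivity) <= 0))
  expect_true(all(diff(tab$specificity) >= 0))
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  # strictly-greater boundary: a value exactly at a threshold counts negative
  th30 <- (-1 + 0.05 * (1:39))[30]   # the realized grid point near +0.5
  tc_tie <- two_class_dop(rep(th30, 10), rep(-0.5, 10))
  tt <- roc_curve(tc_tie$dop, tc_tie$mask)$table
  expect_equal(tt$TP[30], 0)
  expect_equal(tt$TP[29], 10)
})

test_that("auc endpoints: perfect, chance, inverted", {
  tc <- two_class_dop(rep(0.9, 20), rep(-0.9, 30))
  expect_equal(roc_curve(tc$dop, tc$mask)$auc, 1)
  tc_inv <- two_class_dop(rep(-0.9, 20), rep(0.9, 30))
  expect_equal(roc_curve(tc_inv$dop, tc_inv$mask)$auc, 0)
  set.seed(41)
  pool <- rnorm(2e5, 0, 0.2)
  tc_c <- two_class_dop(pool[1:1e5], pool[1e5 + 1:1e5])
  expect_equal(roc_curve(tc_c$dop, tc_c$mask)$auc, 0.5, tolerance = 0.01)
})

test_that("swept AUC agrees with Mann-Whitney and brute-force sweeps", {
  set.seed(43)
  tumor <- rnorm(1e4, 0.3, 0.15); nontumor <- rnorm(1e4, 0, 0.15)
  tc <- two_class_dop(tumor, nontumor)
  roc <- roc_curve(tc$dop, tc$mask)
  expect_equal(roc$auc, brute_sweep_auc(tumor, nontumor), tolerance = 1e-12)
  expect_equal(roc$auc, mw_auc(tumor, nontumor), tolerance = 0.01)
  # class inversion maps the anchored trapezoid AUC to 1 - AUC exactly
  neg <- two_class_dop(-tumor, -nontumor)
  expect_equal(roc_curve(neg$dop, neg$mask)$auc, 1 - roc$auc, tolerance = 1e-12)
})

test_that("magnitude variant ranks a more-negative tumor above chance", {
  set.seed(47)
  tc <- two_class_dop(rnorm(5000, -0.4, 0.12), rnorm(5000, -0.1, 0.12))
  expect_lt(roc_curve(tc$dop, tc$mask)$auc, 0.5)
  expect_gt(roc_curve(tc$dop, tc$mask, use_magnitude = TRUE)$auc, 0.85)
})

test_that("auc_ci is deterministic, collapses for separated classes, and matches a literal bootstrap", {
  tc_sep <- two_class_dop(rep(0.8, 50), rep(-0.8, 60))
  ci <- auc_ci(tc_sep$dop, tc_sep$mask, n_boot = 200, seed = 1)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))

  set.seed(53)
  tumor <- rnorm(2000, 0.25, 0.15); nontumor <- rnorm(2500, 0, 0.15)
  tc <- two_class_dop(tumor, nontumor)
  ci1 <- auc_ci(tc$dop, tc$mask, n_boot = 300, seed = 99)
  ci2 <- auc_ci(tc$dop, tc$mask, n_boot = 300, seed = 99)
  expect_identical(ci1, ci2)

  # multinomial-over-bins bootstrap reproduces literal pixel resampling
  lit <- brute_boot_ci(tumor, nontumor, n_boot = 600, seed = 7)
  ci3 <- auc_ci(tc$dop, tc$mask, n_boot = 600, seed = 8)
  expect_lt(abs(ci3$lo - lit[1]), 0.01)
  expect_lt(abs(ci3$hi - lit[2]), 0.01)
  expect_error(auc_ci(two_class_dop(rep(.1, 5), rep(0, 50))$dop,
                      two_class_dop(rep(.1, 5), rep(0, 50))$mask,
                      n_boot = 10, seed = 1), "tumor")
})

test_that("region_summary reports class means, SDs, counts, and total DOP", {
  # constant fields: |DOPtotal| = 0.5 in both classes, SD = 0
  mask <- matrix(c(TRUE, FALSE), 10, 10)
  dolp <- dop_image(matrix(0.6, 10, 10), "linear")
  docp <- dop_image(matrix(-0.4, 10, 10), "circular")
  s <- region_summary(dolp, docp, mask)
  tot <- s[s$metric == "total_magnitude", ]
  expect_equal(tot$mean, c(0.5, 0.5))
  expect_equal(s$sd, rep(0, 6))
  expect_equal(s$n, rep(c(sum(mask), sum(!mask)), 3))

  # sampled tumor mean recovered within 3 standard errors
  set.seed(59)
  n <- 1e4
  vals_c <- c(rnorm(n, -0.4, 0.1), rnorm(n, -0.1, 0.1))
  vals_l <- c(rnorm(n, -0.5, 0.1), rnorm(n, -0.45, 0.1))
  m <- matrix(c(rep(TRUE, n), rep(FALSE, n)), 200, 100)
  s2 <- region_summary(dop_image(matrix(vals_l, 200, 100), "linear"),
                       dop_image(matrix(vals_c, 200, 100), "circular"), m)
  mt <- s2[s2$metric == "circular" & s2$class == "tumor", ]
  expect_lt(abs(mt$mean - (-0.4)), 3 * 0.1 / sqrt(n))
})
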