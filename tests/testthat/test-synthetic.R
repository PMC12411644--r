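small_cfg <- function(seed = 1, ...) {
  scene_config(image_shape = c(96, 96), tumor_center = c(48, 48),
               tumor_axes = c(24, 16), seed = seed, ...)
}

test_that("scene_config validates its invariants", {
  expect_error(scene_config(), "seed")
  expect_error(small_cfg(docp_tumor = c(1.2, 0.1)), "docp_tumor")
  expect_error(small_cfg(docp_tumor = c(0.2, 0)), "docp_tumor")
  expect_error(scene_config(image_shape = c(64, 64), tumor_center = c(32, 32),
                            tumor_axes = c(40, 10), seed = 1), "outside")
  expect_error(small_cfg(linear_split = 1.5), "linear_split")
})

test_that("noise-free constant scene reproduces configured values exactly", {
  cfg <- small_cfg(docp_tumor = c(-0.4, 1e-9), docp_nontumor = c(-0.1, 1e-9),
                   dolp_tumor = c(-0.55, 1e-9), dolp_nontumor = c(-0.45, 1e-9),
                   noise_sd = 0, fluor_noise_sd = 0)
  sc <- make_dop_scene(cfg)
  docp <- signed_docp(sc$frames$R, sc$frames$L, cfg$incident_helicity)
  dolp <- signed_dolp(sc$frames$H, sc$frames$V, sc$frames$P45, sc$frames$M45)
  expect_equal(unclass(docp)[sc$class_map], rep(-0.4, sum(sc$class_map)),
               tolerance = 1e-7)
  expect_equal(unclass(docp)[!sc$class_map],
               rep(-0.1, sum(!sc$class_map)), tolerance = 1e-7)
  expect_equal(unclass(dolp)[sc$class_map], rep(-0.55, sum(sc$class_map)),
               tolerance = 1e-7)
  # generated frames invert the sampled fields exactly (inverse-then-forward)
  expect_equal(unclass(docp)[, ], sc$docp_true, tolerance = 1e-12)
  expect_equal(unclass(dolp)[, ], sc$dolp_true, tolerance = 1e-12)
})

test_that("the linear split ratio distributes DOLP across both terms", {
  cfg <- small_cfg(noise_sd = 0, fluor_noise_sd = 0, linear_split = 0.6)
  sc <- make_dop_scene(cfg)
  dolp <- signed_dolp(sc$frames$H, sc$frames$V, sc$frames$P45, sc$frames$M45)
  expect_equal(unclass(dolp)[, ], sc$dolp_true, tolerance = 1e-12)
  # and the H/V term alone carries 60% of it
  hv_term <- -(sc$frames$H - sc$frames$V) / (sc$frames$H + sc$frames$V)
  expect_equal(hv_term, 0.6 * sc$dolp_true, tolerance = 1e-12)
})

test_that("same seed gives bit-identical scenes; different seed differs", {
  a <- make_dop_scene(small_cfg(seed = 5))
  b <- make_dop_scene(small_cfg(seed = 5))
  expect_identical(a$frames, b$frames)
  expect_identical(a$fluor, b$fluor)
  expect_identical(a$docp_true, b$docp_true)
  c <- make_dop_scene(small_cfg(seed = 6))
  expect_false(identical(a$frames$R, c$frames$R))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(make_dop_scene(small_cfg(seed = 9))); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("tumor pixel count matches the brute-force ellipse rasterization", {
  cfg <- scene_config(image_shape = c(96, 96), tumor_center = c(50, 44),
                      tumor_axes = c(40, 25), tumor_rotation = 0.3, seed = 2)
  sc <- make_dop_scene(cfg)
  expect_equal(sum(sc$class_map),
               brute_ellipse_count(c(96, 96), c(50, 44), c(40, 25), 0.3))
})

test_that("fluorescence blob co-locates with the tumor after registration", {
  cfg <- small_cfg(fluor_noise_sd = 0)
  sc <- make_dop_scene(cfg)
  fid <- sc$fiducials
  src <- as.matrix(fid[fid$frame == "fluorescence", c("row", "col")])
  dst <- as.matrix(fid[fid$frame == "polarimetry", c("row", "col")])
  tr <- estimate_transform(src, dst, "similarity")
  # recovered transform matches the configured one to < 0.1 px on the frame
  probe <- as.matrix(expand.grid(c(0, 48, 95), c(0, 48, 95)))
  expect_lt(sqrt(mean((transform_points(tr, probe) -
                       transform_points(sc$transform, probe))^2)), 0.1)
  mask <- apply_transform(threshold_fluorescence(sc$fluor, 0.95), tr,
                          dim(sc$class_map))
  # thresholded-and-warped mask sits inside the true tumor (blur shrinks it)
  expect_gt(sum(mask & sc$class_map) / sum(mask), 0.98)
  expect_gt(sum(mask) / sum(sc$class_map), 0.5)
})

test_that("mueller scene round-trips noiselessly and propagates the M44 sign", {
  cfg <- small_cfg(noise_sd = 0)
  ms <- make_mueller_scene(cfg, tumor_diag = c(0.45, -0.35),
                           nontumor_diag = c(0.55, 0.10))
  rec <- mueller_from_measurements(ms$frames, ms$scheme, normalize = TRUE)
  m44 <- mueller_element(rec, 4, 4)
  expect_lt(max(abs(m44[ms$class_map] - (-0.35))), 1e-10)
  expect_lt(max(abs(m44[!ms$class_map] - 0.10)), 1e-10)

  # with noise, tumor-region M44 histogram mean stays negative
  msn <- make_mueller_scene(small_cfg(seed = 3, noise_sd = 5))
  recn <- mueller_from_measurements(msn$frames, msn$scheme, normalize = TRUE)
  expect_lt(mean(mueller_element(recn, 4, 4)[msn$class_map]), 0)
  expect_error(make_mueller_scene(cfg, tumor_diag = c(1.2, 0)), "non-physical")
})

test_that("beam-splitter factors wrap the scene and are removed by correction", {
  cfg <- small_cfg(noise_sd = 0)
  set.seed(71)
  M_ill <- diag(4) + matrix(rnorm(16, 0, 0.03), 4)
  M_det <- diag(4) + matrix(rnorm(16, 0, 0.03), 4)
  ms <- make_mueller_scene(cfg, M_ill = M_ill, M_det = M_det)
  raw <- mueller_from_measurements(ms$frames, ms$scheme)
  corrected <- correct_beam_splitter(raw, M_ill, M_det)
  expect_lt(max(abs(corrected$M - ms$M_true)), 1e-8)
  # identity beam splitter arguments give the same frames as none
  a <- make_mueller_scene(cfg)
  b <- make_mueller_scene(cfg, M_ill = diag(4), M_det = diag(4))
  expect_identical(a$frames, b$frames)
})

test_that("closed-form expectations match their formulas and refuse truncation", {
  cfg <- small_cfg(docp_tumor = c(0.25, 0.15), docp_nontumor = c(-0.05, 0.15))
  cf <- closed_form_expectations(cfg)
  expect_equal(cf$auc, pnorm(sqrt(2)), tolerance = 1e-12)
  expect_equal(cf$overlap, 2 * pnorm(-1), tolerance = 1e-12)
  same <- small_cfg(docp_tumor = c(0.1, 0.1), docp_nontumor = c(0.1, 0.1))
  cf2 <- closed_form_expectations(same)
  expect_equal(cf2$auc, 0.5)
  expect_equal(cf2$overlap, 1)
  expect_error(closed_form_expectations(
    small_cfg(docp_tumor = c(-0.8, 0.1), docp_nontumor = c(0, 0.1))),
    "truncation")
  # unequal SDs: overlap closed form does not apply
  expect_true(is.na(closed_form_expectations(
    small_cfg(docp_tumor = c(0.2, 0.1), docp_nontumor = c(0, 0.12)))$overlap))
})

test_that("smoothing keeps fields in range and preserves class contrast", {
  cfg <- small_cfg(smooth_sd = 1.5, noise_sd = 0)
  sc <- make_dop_scene(cfg)
  expect_true(all(abs(sc$docp_true) <= 1))
  expect_lt(mean(sc$docp_true[sc$class_map]), mean(sc$docp_true[!sc$class_map]))
})
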