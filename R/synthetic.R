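#' Synthetic scene configuration
#'
#' Assembles and validates the parameters of the two-class synthetic world the
#' pipeline is tested on: an elliptical tumor in a uniform non-tumor
#' background, class-conditional truncated-normal distributions of signed
#' circular and linear DOP, a fluorescence blob co-located with the tumor
#' under a known similarity transform, fiducial disks visible in both frames,
#' and additive detector noise.
#'
#' Defaults emulate the qualitative structure reported for pancreatic-tumor
#' window-chamber imaging: tumor circular DOP markedly more negative and
#' larger in magnitude than non-tumor; linear DOP larger in magnitude than
#' circular in both classes, with only a slight tumor shift; linear noise and
#' means chosen so that |DOLP| > |DOCP| overall.
#'
#' @param image_shape `c(rows, cols)`; default 256 x 256.
#' @param tumor_center,tumor_axes,tumor_rotation ellipse geometry (px, px,
#'   radians); must fit inside the frame.
#' @param docp_tumor,docp_nontumor,dolp_tumor,dolp_nontumor length-2 vectors
#'   `c(mean, sd)` of the class-conditional signed DOP distributions,
#'   truncated to \[-1, 1\].
#' @param s0 mean detector intensity (counts) of an unpolarized-equivalent
#'   pixel.
#' @param noise_sd additive Gaussian noise SD on every intensity frame
#'   (counts); negative values are clamped to zero after noising.
#' @param poisson_noise also apply Poisson resampling of each frame?
#' @param incident_helicity,incident_hv,incident_diag incident states used to
#'   realize the configured DOP values in the frames.
#' @param linear_split fraction of the signed linear DOP carried by the H/V
#'   term (the remainder goes to the +/-45 term); default 1.
#' @param fluor_background,fluor_contrast,fluor_blur_sd,fluor_noise_sd
#'   fluorescence rendering: background level, added tumor contrast, Gaussian
#'   blur SD (px), additive noise SD.
#' @param fiducials n x 2 matrix of (row, col) fiducial centres in the
#'   polarimetry frame; default four rim points.
#' @param fiducial_radius stamped disk radius (px).
#' @param transform fluorescence-to-polarimetry `registration_transform`;
#'   default a small rigid offset, as manual chamber repositioning would give.
#' @param smooth_sd optional Gaussian correlation length (px) applied to the
#'   DOP fields (0 = i.i.d. pixels, the default).
#' @param seed mandatory integer seed.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(256, 256),
                         tumor_center = c(128, 128),
                         tumor_axes = c(60, 40),
                         tumor_rotation = 0.4,
                         docp_tumor = c(-0.40, 0.12),
                         docp_nontumor = c(-0.10, 0.12),
                         dolp_tumor = c(-0.55, 0.10),
                         dolp_nontumor = c(-0.45, 0.10),
                         s0 = 1000,
                         noise_sd = 2,
                         poisson_noise = FALSE,
                         incident_helicity = "R",
                         incident_hv = "H",
                         incident_diag = "P45",
                         linear_split = 1,
                         fluor_background = 20,
                         fluor_contrast = 200,
                         fluor_blur_sd = 2,
                         fluor_noise_sd = 2,
                         fiducials = NULL,
                         fiducial_radius = 3,
                         transform = make_transform(rotation = 0.02,
                                                    translation = c(4, -6)),
                         smooth_sd = 0,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(fiducials)) {
    m <- image_shape
    fiducials <- rbind(c(20, 20), c(20, m[2] - 21), c(m[1] - 21, 20),
                       c(m[1] - 21, m[2] - 21))
  }
  cfg <- list(image_shape = as.integer(image_shape),
              tumor_center = tumor_center, tumor_axes = tumor_axes,
              tumor_rotation = tumor_rotation,
              docp_tumor = docp_tumor, docp_nontumor = docp_nontumor,
              dolp_tumor = dolp_tumor, dolp_nontumor = dolp_nontumor,
              s0 = s0, noise_sd = noise_sd, poisson_noise = poisson_noise,
              incident_helicity = incident_helicity,
              incident_hv = incident_hv, incident_diag = incident_diag,
              linear_split = linear_split,
              fluor_background = fluor_background,
              fluor_contrast = fluor_contrast,
              fluor_blur_sd = fluor_blur_sd,
              fluor_noise_sd = fluor_noise_sd,
              fiducials = as.matrix(fiducials),
              fiducial_radius = fiducial_radius,
              transform = transform, smooth_sd = smooth_sd,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  for (nm in c("docp_tumor", "docp_nontumor", "dolp_tumor", "dolp_nontumor")) {
    p <- cfg[[nm]]
    if (length(p) != 2 || abs(p[1]) >= 1 || p[2] <= 0)
      stop(nm, " must be c(mean, sd) with |mean| < 1 and sd > 0")
  }
  ext <- max(cfg$tumor_axes)
  if (any(cfg$tumor_center - ext < 0) ||
      any(cfg$tumor_center + ext > cfg$image_shape - 1))
    stop("tumor ellipse extends outside the frame")
  if (cfg$linear_split < 0 || cfg$linear_split > 1)
    stop("linear_split must be in [0, 1]")
  if (cfg$s0 <= 0 || cfg$noise_sd < 0) stop("invalid intensity parameters")
  invisible(cfg)
}

# Rasterize the configured ellipse: pixel (r, c), 0-based, is tumor iff its
# centre lies inside the rotated ellipse.
ellipse_mask <- function(shape, center, axes, rotation) {
  r <- matrix(0:(shape[1] - 1), shape[1], shape[2]) - center[1]
  c <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE) - center[2]
  u <- cos(rotation) * r + sin(rotation) * c
  v <- -sin(rotation) * r + cos(rotation) * c
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# Truncated-normal sampling by rejection; all draws come from the current
# RNG stream so a single seed fixes the whole scene.
rtruncnorm_vec <- function(n, mean, sd, lo = -1, hi = 1) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  pad_conv <- function(m) {   # separable 1-D convolution along rows, edge-replicated
    nr <- nrow(m)
    idx <- pmin(pmax(seq_len(nr + 2 * half) - half, 1), nr)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, nr, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nr - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

sample_class_field <- function(class_map, tumor_par, nontumor_par, smooth_sd) {
  field <- matrix(NA_real_, nrow(class_map), ncol(class_map))
  n_t <- sum(class_map)
  field[class_map] <- rtruncnorm_vec(n_t, tumor_par[1], tumor_par[2])
  field[!class_map] <- rtruncnorm_vec(length(field) - n_t,
                                      nontumor_par[1], nontumor_par[2])
  if (smooth_sd > 0) {
    field <- gaussian_blur(field, smooth_sd)
    field[field > 1] <- 1; field[field < -1] <- -1
  }
  field
}

stamp_disks <- function(img, centers, radius, value) {
  for (i in seq_len(nrow(centers))) {
    rr <- round(centers[i, 1]); cc <- round(centers[i, 2])
    rs <- max(0, rr - radius):min(nrow(img) - 1, rr + radius)
    cs <- max(0, cc - radius):min(ncol(img) - 1, cc + radius)
    for (r in rs) for (c in cs)
      if ((r - rr)^2 + (c - cc)^2 <= radius^2) img[r + 1, c + 1] <- value
  }
  img
}

add_noise <- function(frame, cfg) {
  if (cfg$poisson_noise) frame <- matrix(rpois(length(frame), pmax(frame, 0)),
                                         nrow(frame), ncol(frame))
  if (cfg$noise_sd > 0)
    frame <- frame + matrix(rnorm(length(frame), 0, cfg$noise_sd),
                            nrow(frame), ncol(frame))
  frame[frame < 0] <- 0
  frame
}

#' Generate a synthetic DOP scene
#'
#' Samples per-pixel signed circular and linear DOP from the configured
#' class-conditional truncated normals and constructs intensity frames that
#' realize them exactly before noise: the circular pair splits S0 so that
#' [signed_docp()] of the clean frames returns the sampled field under the
#' configured incident helicity, and the two linear pairs split the sampled
#' linear DOP in the configured ratio. Fluorescence is the class map scaled
#' by `fluor_contrast`, blurred, noised, and rendered in its own frame under
#' the inverse of the configured fluorescence-to-polarimetry transform.
#' Fiducial disks are stamped bright in both modalities; in the polarimetry
#' frames the disk scales intensity without altering the local DOP.
#'
#' @param cfg a [scene_config()].
#' @return list of class `scene_truth`: `class_map` (logical, polarimetry
#'   frame), `docp_true`, `dolp_true` (clean fields), `frames` (named list:
#'   `R`, `L` under circular incidence; `H`, `V` under `incident_hv`; `P45`,
#'   `M45` under `incident_diag`), `fluor` (fluorescence-frame image),
#'   `fiducials` (data.frame frame/point_id/row/col for both frames),
#'   `transform`, `config`.
#' @export
make_dop_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  shape <- cfg$image_shape
  class_map <- ellipse_mask(shape, cfg$tumor_center, cfg$tumor_axes,
                            cfg$tumor_rotation)
  d_c <- sample_class_field(class_map, cfg$docp_tumor, cfg$docp_nontumor,
                            cfg$smooth_sd)
  d_l <- sample_class_field(class_map, cfg$dolp_tumor, cfg$dolp_nontumor,
                            cfg$smooth_sd)

  s0 <- matrix(cfg$s0, shape[1], shape[2])
  s0 <- stamp_disks(s0, cfg$fiducials, cfg$fiducial_radius, 3 * cfg$s0)

  sgn_c <- if (cfg$incident_helicity == "R") 1 else -1
  sgn_1 <- if (cfg$incident_hv == "H") 1 else -1
  sgn_2 <- if (cfg$incident_diag == "P45") 1 else -1
  term1 <- cfg$linear_split * d_l
  term2 <- (1 - cfg$linear_split) * d_l
  frames <- list(
    R   = s0 * (1 + sgn_c * d_c) / 2,
    L   = s0 * (1 - sgn_c * d_c) / 2,
    H   = s0 * (1 - sgn_1 * term1) / 2,
    V   = s0 * (1 + sgn_1 * term1) / 2,
    P45 = s0 * (1 - sgn_2 * term2) / 2,
    M45 = s0 * (1 + sgn_2 * term2) / 2)
  frames <- lapply(frames, add_noise, cfg = cfg)

  fluor_pol <- cfg$fluor_background + cfg$fluor_contrast * class_map
  inv <- invert_transform(cfg$transform)
  # fluorescence pixel (r, c) images the tissue at transform(r, c) in the
  # polarimetry frame, so the warp samples fluor_pol there
  fluor <- warp_image(fluor_pol, cfg$transform, shape, fill = cfg$fluor_background)
  fluor <- gaussian_blur(fluor, cfg$fluor_blur_sd)
  fid_fluor <- transform_points(inv, cfg$fiducials)
  fluor <- stamp_disks(fluor, fid_fluor, cfg$fiducial_radius,
                       cfg$fluor_background + 0.5 * cfg$fluor_contrast)
  if (cfg$fluor_noise_sd > 0)
    fluor <- pmax(fluor + matrix(rnorm(length(fluor), 0, cfg$fluor_noise_sd),
                                 shape[1], shape[2]), 0)

  fid <- rbind(
    data.frame(frame = "polarimetry", point_id = seq_len(nrow(cfg$fiducials)),
               row = cfg$fiducials[, 1], col = cfg$fiducials[, 2]),
    data.frame(frame = "fluorescence", point_id = seq_len(nrow(cfg$fiducials)),
               row = fid_fluor[, 1], col = fid_fluor[, 2]))

  structure(list(class_map = class_map, docp_true = d_c, dolp_true = d_l,
                 frames = frames, fluor = fluor, fiducials = fid,
                 transform = cfg$transform, config = cfg),
            class = "scene_truth")
}

# Inverse-warp a numeric image with nearest-neighbour sampling: target pixel
# (r, c) copies src at t_src_from_target(r, c).
warp_image <- function(img, t_target_to_src, target_shape, fill = 0) {
  nr <- target_shape[1]; nc <- target_shape[2]
  grid <- cbind(rep(0:(nr - 1), nc), rep(0:(nc - 1), each = nr))
  srcpos <- transform_points(t_target_to_src, grid)
  sr <- as.integer(round(srcpos[, 1])) + 1L
  sc <- as.integer(round(srcpos[, 2])) + 1L
  ok <- sr >= 1L & sr <= nrow(img) & sc >= 1L & sc <= ncol(img)
  out <- matrix(fill, nr, nc)
  out[cbind(grid[ok, 1] + 1L, grid[ok, 2] + 1L)] <- img[cbind(sr[ok], sc[ok])]
  out
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d px, %d tumor px, %d frames, seed %d\n",
              nrow(x$class_map), ncol(x$class_map), sum(x$class_map),
              length(x$frames), x$config$seed))
  invisible(x)
}

#' Generate a synthetic 16-frame Mueller scene
#'
#' Forward-simulates all generator/analyzer intensities of the measurement
#' scheme from a two-class field of diagonal Mueller matrices
#' `s0 * diag(1, a, a, b)` (optionally pre/post-multiplied by beam-splitter
#' matrices), then adds noise. The noiseless frames round-trip exactly
#' through [mueller_from_measurements()].
#'
#' @param cfg a [scene_config()] (geometry, s0, noise and seed are used).
#' @param tumor_diag,nontumor_diag length-2 `c(a, b)` with |a|, |b| <= 1: the
#'   linear- and circular-channel diagonal entries per class. Defaults give
#'   the tumor a negative circular channel (net helicity flip).
#' @param M_ill,M_det optional beam-splitter Mueller factors applied as
#'   `M_det %*% M %*% M_ill` before simulation.
#' @param scheme a [measurement_scheme()].
#' @return list of class `mueller_scene`: `class_map`, `frames` (named list
#'   of 16 matrices), `M_true` (clean 4 x 4 x rows x cols array, beam
#'   splitter excluded), `scheme`, `config`.
#' @export
make_mueller_scene <- function(cfg,
                               tumor_diag = c(0.45, -0.35),
                               nontumor_diag = c(0.55, 0.10),
                               M_ill = NULL, M_det = NULL,
                               scheme = measurement_scheme()) {
  stopifnot(inherits(cfg, "scene_config"))
  for (p in list(tumor_diag, nontumor_diag))
    if (length(p) != 2 || any(abs(p) > 1))
      stop("non-physical diagonal parameters: need |a|, |b| <= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  shape <- cfg$image_shape
  class_map <- ellipse_mask(shape, cfg$tumor_center, cfg$tumor_axes,
                            cfg$tumor_rotation)
  a <- ifelse(class_map, tumor_diag[1], nontumor_diag[1])
  b <- ifelse(class_map, tumor_diag[2], nontumor_diag[2])
  M <- array(0, dim = c(4, 4, shape[1], shape[2]))
  M[1, 1, , ] <- cfg$s0
  M[2, 2, , ] <- cfg$s0 * a
  M[3, 3, , ] <- cfg$s0 * a
  M[4, 4, , ] <- cfg$s0 * b
  M_meas <- M
  if (!is.null(M_ill) || !is.null(M_det)) {
    if (is.null(M_ill)) M_ill <- diag(4)
    if (is.null(M_det)) M_det <- diag(4)
    K <- t(M_ill) %x% M_det   # vec(D M I) = (t(I) kron D) vec(M)
    M_meas <- array(K %*% matrix(M, nrow = 16), dim = dim(M))
  }
  frames <- simulate_mueller_frames(mueller_image(M_meas), scheme)
  frames <- lapply(frames, add_noise, cfg = cfg)
  structure(list(class_map = class_map, frames = frames, M_true = M,
                 scheme = scheme, config = cfg),
            class = "mueller_scene")
}

#' Closed-form expected AUC and histogram overlap of a configured scene
#'
#' For Gaussian class-conditional distributions with negligible truncation
#' (|mean| + 4 sd < 1), the signed-value swept AUC tends to
#' `pnorm((mu_T - mu_N) / sqrt(sd_T^2 + sd_N^2))` and, for equal SDs, the
#' overlapping coefficient tends to `2 * pnorm(-|mu_T - mu_N| / (2 sd))`.
#' Used as the analytic oracle for end-to-end recovery tests.
#'
#' @param cfg a [scene_config()].
#' @param metric `"circular"` or `"linear"`.
#' @return list with `auc` and `overlap` (overlap is `NA` when the class SDs
#'   differ).
#' @export
closed_form_expectations <- function(cfg, metric = c("circular", "linear")) {
  metric <- match.arg(metric)
  p <- if (metric == "circular") list(t = cfg$docp_tumor, n = cfg$docp_nontumor)
       else list(t = cfg$dolp_tumor, n = cfg$dolp_nontumor)
  for (q in p)
    if (abs(q[1]) + 4 * q[2] >= 1)
      stop("truncation non-negligible for ", metric,
           " (need |mean| + 4*sd < 1); closed forms do not apply")
  auc <- pnorm((p$t[1] - p$n[1]) / sqrt(p$t[2]^2 + p$n[2]^2))
  overlap <- if (isTRUE(all.equal(p$t[2], p$n[2])))
    2 * pnorm(-abs(p$t[1] - p$n[1]) / (2 * p$t[2])) else NA_real_
  list(auc = auc, overlap = overlap)
}
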