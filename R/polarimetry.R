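check_frames <- function(frames, need = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (!is.null(need)) {
    miss <- setdiff(need, names(frames))
    if (length(miss)) stop("missing frames: ", paste(miss, collapse = ", "))
  }
  dims <- lapply(frames, dim)
  ref <- dims[[1]]
  if (is.null(ref)) stop("frames must be matrices")
  ok <- vapply(dims, function(d) !is.null(d) && all(d == ref), logical(1))
  if (!all(ok)) stop("frame shape mismatch: all frames must share one image shape")
  for (nm in names(frames)) {
    if (any(frames[[nm]] < 0, na.rm = TRUE))
      stop("negative intensity in frame '", nm, "'")
  }
  invisible(ref)
}

#' DOP image container
#'
#' A 2-D field of signed degree-of-polarization values with a metric tag and a
#' validity mask. Circular values lie in \[-1, +1\]; total-magnitude values in
#' \[0, 1\]; linear values can mathematically exceed magnitude 1 when the two
#' incident-state experiments disagree, in which case they are flagged (never
#' clamped) via the `out_of_range` attribute.
#'
#' @param values numeric matrix.
#' @param metric one of `"circular"`, `"linear"`, `"total_magnitude"`.
#' @param valid logical matrix marking pixels with sufficient intensity.
#' @return object of class `dop_image`: the values matrix with attributes
#'   `metric`, `valid`, `out_of_range`.
#' @export
dop_image <- function(values, metric = c("circular", "linear", "total_magnitude"),
                      valid = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(is.logical(valid), all(dim(valid) == dim(values)))
  lim <- if (metric == "linear") 2 else 1
  oor <- valid & !is.na(values) & (abs(values) > 1 + 1e-12)
  if (metric != "linear" && any(oor))
    warning(sum(oor), " ", metric, " DOP pixels outside [-1, 1]")
  structure(values, metric = metric, valid = valid, out_of_range = oor,
            limit = lim, class = c("dop_image", "matrix", "array"))
}

#' @export
print.dop_image <- function(x, ...) {
  cat(sprintf("<dop_image> %s, %d x %d, %d valid px, %d flagged out-of-range\n",
              attr(x, "metric"), nrow(x), ncol(x),
              sum(attr(x, "valid")), sum(attr(x, "out_of_range"))))
  invisible(x)
}

#' Stokes image from six analyzed-state intensity frames
#'
#' Computes per-pixel Stokes components from intensities detected behind the
#' six canonical analyzers under a single incident state:
#' S0 = I_H + I_V, S1 = I_H - I_V, S2 = I_P45 - I_M45, S3 = I_R - I_L.
#' S0 is cross-checked against I_P45 + I_M45 and I_R + I_L; disagreement beyond
#' `tol` (relative to the image-wide maximum S0) sets the `consistency_ok`
#' attribute to FALSE with a warning rather than an error, since detector noise
#' routinely perturbs the three estimates.
#'
#' @param frames named list of nonnegative matrices `H, V, P45, M45, R, L`.
#' @param tol relative tolerance for the S0 consistency check.
#' @return object of class `stokes_image`: list of matrices `S0, S1, S2, S3`,
#'   with attributes `consistency_ok` and `realizable` (logical matrix flagging
#'   pixels where S1^2+S2^2+S3^2 <= S0^2 holds; violations are flagged, not
#'   clipped).
#' @export
stokes_from_intensities <- function(frames, tol = 1e-6) {
  check_frames(frames, need = pol_state_names())
  S0 <- frames$H + frames$V
  S1 <- frames$H - frames$V
  S2 <- frames$P45 - frames$M45
  S3 <- frames$R - frames$L
  s0b <- frames$P45 + frames$M45
  s0c <- frames$R + frames$L
  scale <- max(S0, s0b, s0c, 1e-300)
  ok <- max(abs(S0 - s0b), abs(S0 - s0c)) <= tol * scale
  if (!ok) warning("S0 consistency check failed beyond tolerance; flagged")
  realizable <- (S1^2 + S2^2 + S3^2) <= S0^2 * (1 + 1e-12)
  structure(list(S0 = S0, S1 = S1, S2 = S2, S3 = S3),
            consistency_ok = ok, realizable = realizable,
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  cat(sprintf("<stokes_image> %d x %d, S0 consistent: %s, %d unphysical px\n",
              nrow(x$S0), ncol(x$S0), attr(x, "consistency_ok"),
              sum(!attr(x, "realizable"))))
  invisible(x)
}

intensity_floor_mask <- function(total, floor_frac = 1e-6) {
  total > floor_frac * max(total, 0)
}

#' Signed circular degree of polarization
#'
#' Per pixel, `sign(S3_in) * (I_R - I_L) / (I_R + I_L)` for co-/cross-circular
#' detected intensities under a pure circular incident state. Negative values
#' encode helicity flipping (the detected handedness opposes the incident
#' handedness, as in direct backscatter), positive values helicity
#' preservation; the magnitude equals the conventional unsigned circular DOP
#' S3_out/S0_out.
#'
#' Pixels whose total intensity I_R + I_L falls at or below
#' `floor_frac * max(I_R + I_L)` are marked invalid and set `NA` rather than
#' risking division by zero.
#'
#' @param I_R,I_L nonnegative matrices of detected right/left circular
#'   intensity.
#' @param incident_helicity `"R"` or `"L"`; the pure circular incident state.
#' @param floor_frac intensity floor as a fraction of the image maximum.
#' @return [dop_image()] with metric `"circular"`.
#' @export
signed_docp <- function(I_R, I_L, incident_helicity = c("R", "L"),
                        floor_frac = 1e-6) {
  incident_helicity <- match.arg(incident_helicity)
  check_frames(list(R = I_R, L = I_L))
  s <- if (incident_helicity == "R") 1 else -1
  tot <- I_R + I_L
  valid <- intensity_floor_mask(tot, floor_frac)
  vals <- matrix(NA_real_, nrow(I_R), ncol(I_R))
  vals[valid] <- s * (I_R[valid] - I_L[valid]) / tot[valid]
  dop_image(vals, "circular", valid)
}

#' Signed linear degree of polarization
#'
#' Two-term signed linear DOP: one term from the H/V analyzer pair acquired
#' under a pure H or V incident state, one from the +/-45 pair under a pure
#' +45 or -45 incident state. Each term is `-sign(S_in) * (I_co_axis -
#' I_cross_axis)/(I_co_axis + I_cross_axis)` in its own basis, so each term
#' (and their sum) is negative when co-linear detected intensity dominates
#' cross-linear, mirroring the helicity-flip sign of the circular metric under
#' direct backscatter. The printed range is \[-1, +1\]; sums outside it (the
#' two experiments can disagree) are flagged via `out_of_range`, never clamped.
#'
#' @param I_H,I_V matrices: H/V-analyzed intensities under the `incident_hv`
#'   state.
#' @param I_P45,I_M45 matrices: +/-45-analyzed intensities under the
#'   `incident_diag` state.
#' @param incident_hv `"H"` or `"V"` (pure linear incident state of the first
#'   experiment).
#' @param incident_diag `"P45"` or `"M45"` (second experiment).
#' @param floor_frac intensity floor as a fraction of each pair's maximum.
#' @return [dop_image()] with metric `"linear"`.
#' @export
signed_dolp <- function(I_H, I_V, I_P45, I_M45,
                        incident_hv = c("H", "V"),
                        incident_diag = c("P45", "M45"),
                        floor_frac = 1e-6) {
  incident_hv <- match.arg(incident_hv)
  incident_diag <- match.arg(incident_diag)
  check_frames(list(H = I_H, V = I_V, P45 = I_P45, M45 = I_M45))
  s1 <- if (incident_hv == "H") 1 else -1
  s2 <- if (incident_diag == "P45") 1 else -1
  tot1 <- I_H + I_V
  tot2 <- I_P45 + I_M45
  valid <- intensity_floor_mask(tot1, floor_frac) &
    intensity_floor_mask(tot2, floor_frac)
  vals <- matrix(NA_real_, nrow(I_H), ncol(I_H))
  vals[valid] <- -s1 * (I_H[valid] - I_V[valid]) / tot1[valid] +
    (-s2) * (I_P45[valid] - I_M45[valid]) / tot2[valid]
  dop_image(vals, "linear", valid)
}

#' Total DOP magnitude
#'
#' Per pixel, the average of |linear DOP| and |circular DOP|. The valid mask is
#' the intersection of the two inputs' masks.
#'
#' @param dolp [dop_image()] with metric `"linear"`.
#' @param docp [dop_image()] with metric `"circular"`.
#' @return [dop_image()] with metric `"total_magnitude"`.
#' @export
total_dop_magnitude <- function(dolp, docp) {
  stopifnot(inherits(dolp, "dop_image"), inherits(docp, "dop_image"))
  if (attr(dolp, "metric") != "linear" || attr(docp, "metric") != "circular")
    stop("metric tag mismatch: need (linear, circular), got (",
         attr(dolp, "metric"), ", ", attr(docp, "metric"), ")")
  if (!all(dim(dolp) == dim(docp))) stop("frame shape mismatch")
  valid <- attr(dolp, "valid") & attr(docp, "valid")
  vals <- matrix(NA_real_, nrow(dolp), ncol(dolp))
  vals[valid] <- (abs(unclass(dolp)[valid]) + abs(unclass(docp)[valid])) / 2
  dop_image(vals, "total_magnitude", valid)
}
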