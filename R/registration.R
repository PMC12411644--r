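#' Estimate a rigid or similarity transform from point correspondences
#'
#' Closed-form least-squares (Procrustes/Umeyama) fit of
#' `dst ~= s * R %*% src + t` on (row, col) coordinates, 0-based, origin
#' top-left, row-down. `model = "rigid"` fixes the scale at 1. Reflections are
#' excluded (det(R) = +1). The residual RMSE over the correspondences is
#' reported; a degenerate source configuration (all points collinear or
#' coincident) triggers a condition warning since the rotation is then poorly
#' determined.
#'
#' @param src_points,dst_points n x 2 matrices (or data.frames) of (row, col)
#'   coordinates, n >= 2; fluorescence-frame fiducials in `src`, their
#'   polarimetry-frame mates in `dst`.
#' @param model `"rigid"` or `"similarity"`.
#' @return object of class `registration_transform`: list with `model`,
#'   `rotation` (radians), `scale`, `translation` (length 2), the 2x3 matrix
#'   `A` (so `dst = A %*% c(src, 1)`), and `rmse` (px).
#' @export
estimate_transform <- function(src_points, dst_points,
                               model = c("similarity", "rigid")) {
  model <- match.arg(model)
  src <- as.matrix(src_points); dst <- as.matrix(dst_points)
  storage.mode(src) <- "double"; storage.mode(dst) <- "double"
  if (ncol(src) != 2 || ncol(dst) != 2) stop("points must be (row, col) pairs")
  n <- nrow(src)
  if (n != nrow(dst)) stop("src and dst point counts differ")
  if (n < 2) stop("need at least 2 point pairs, got ", n)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  X <- sweep(src, 2, mu_s); Y <- sweep(dst, 2, mu_d)
  var_s <- sum(X^2) / n
  if (var_s < 1e-24) stop("degenerate correspondences: source points coincide")
  S <- crossprod(Y, X) / n      # 2x2 covariance
  sv <- svd(S)
  if (sv$d[2] / max(sv$d[1], 1e-300) < 1e-9)
    warning("near-collinear point configuration: rotation is ill-conditioned")
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  scale <- if (model == "similarity") sum(diag(D) * sv$d) / var_s else 1
  t_vec <- mu_d - scale * as.vector(R %*% mu_s)
  A <- cbind(scale * R, t_vec)
  fit <- t(A %*% rbind(t(src), 1))
  rmse <- sqrt(mean(rowSums((fit - dst)^2)))
  structure(list(model = model, rotation = atan2(R[2, 1], R[1, 1]),
                 scale = scale, translation = t_vec, A = A, rmse = rmse),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf(
    "<registration_transform> %s: rotation %.4f rad, scale %.4f, translation (%.3f, %.3f), RMSE %.3g px\n",
    x$model, x$rotation, x$scale, x$translation[1], x$translation[2], x$rmse))
  invisible(x)
}

#' Build a transform from explicit parameters
#'
#' @param rotation radians, counter-clockwise in (row, col) space.
#' @param translation length-2 numeric (row, col) offset.
#' @param scale isotropic scale factor.
#' @return a `registration_transform`.
#' @export
make_transform <- function(rotation = 0, translation = c(0, 0), scale = 1) {
  R <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2)
  structure(list(model = if (scale == 1) "rigid" else "similarity",
                 rotation = rotation, scale = scale,
                 translation = as.numeric(translation),
                 A = cbind(scale * R, as.numeric(translation)), rmse = 0),
            class = "registration_transform")
}

#' Apply or invert a transform on point coordinates
#'
#' @param t a `registration_transform`.
#' @param points n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(t, points) {
  points <- as.matrix(points)
  t(t$A %*% rbind(t(points), 1))
}

#' @rdname transform_points
#' @export
invert_transform <- function(t) {
  Rinv <- t(t$A[, 1:2]) / t$scale^2   # (sR)^-1 = R^T / s
  tr <- -as.vector(Rinv %*% t$translation)
  structure(list(model = t$model, rotation = -t$rotation, scale = 1 / t$scale,
                 translation = tr, A = cbind(Rinv, tr), rmse = t$rmse),
            class = "registration_transform")
}

#' Warp a mask or outline into the polarimetry frame
#'
#' Inverse-warps binary data with nearest-neighbour interpolation: each target
#' pixel looks up its pre-image under `t` (the fluorescence-to-polarimetry
#' transform) and copies the nearest source pixel; out-of-frame pixels are
#' FALSE. Pixel centres sit on the integer lattice (0-based).
#'
#' @param mask logical matrix ([threshold_fluorescence()] or
#'   [extract_outline()] result), in the source (fluorescence) frame.
#' @param t a `registration_transform` mapping source to target coordinates.
#' @param target_shape `c(rows, cols)` of the polarimetry frame.
#' @return logical matrix of class matching the input class, in the target
#'   frame.
#' @export
apply_transform <- function(mask, t, target_shape = dim(mask)) {
  stopifnot(is.matrix(mask), is.logical(c(mask)))
  inv <- invert_transform(t)
  nr <- target_shape[1]; nc <- target_shape[2]
  grid <- cbind(rep(0:(nr - 1), nc), rep(0:(nc - 1), each = nr))
  srcpos <- transform_points(inv, grid)
  sr <- as.integer(round(srcpos[, 1])) + 1L
  sc <- as.integer(round(srcpos[, 2])) + 1L
  ok <- sr >= 1L & sr <= nrow(mask) & sc >= 1L & sc <= ncol(mask)
  out <- matrix(FALSE, nr, nc)
  out[cbind(grid[ok, 1] + 1L, grid[ok, 2] + 1L)] <- mask[cbind(sr[ok], sc[ok])]
  attrs <- attributes(mask)
  attrs$dim <- c(nr, nc)
  attributes(out) <- attrs
  if (inherits(mask, "region_mask")) attr(out, "frame") <- "polarimetry"
  out
}
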