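#' Mueller image container
#'
#' Per-pixel 4x4 real Mueller matrix field stored as a 4 x 4 x rows x cols
#' array, indexed M11..M44 with the first index the row. If `normalized`,
#' every valid pixel has M11 == 1 and M44 of a physical sample lies in
#' \[-1, +1\] (-1: helicity-flipped, +1: helicity-preserved).
#'
#' @param M numeric array, dim `c(4, 4, rows, cols)`.
#' @param normalized logical; has the field been divided by M11?
#' @param valid logical rows x cols matrix.
#' @return object of class `mueller_image`.
#' @export
mueller_image <- function(M, normalized = FALSE, valid = NULL) {
  stopifnot(is.array(M), length(dim(M)) == 4, all(dim(M)[1:2] == 4))
  if (is.null(valid)) valid <- matrix(TRUE, dim(M)[3], dim(M)[4])
  structure(list(M = M, normalized = normalized, valid = valid),
            class = "mueller_image")
}

#' @export
print.mueller_image <- function(x, ...) {
  cat(sprintf("<mueller_image> %d x %d px, normalized: %s\n",
              dim(x$M)[3], dim(x$M)[4], x$normalized))
  invisible(x)
}

#' Extract one Mueller element as a matrix
#'
#' @param m [mueller_image()].
#' @param row,col element indices; `mueller_element(m, 4, 4)` is M44.
#' @return numeric rows x cols matrix.
#' @export
mueller_element <- function(m, row, col) {
  stopifnot(inherits(m, "mueller_image"), row %in% 1:4, col %in% 1:4)
  m$M[row, col, , ]
}

#' Reconstruct a Mueller image from a 16-state measurement set
#'
#' Inverts the linear forward model `I(g, a) = a . (M s_g)` pixel-wise, where
#' `s_g` is the generator Stokes vector and `a` the ideal-analyzer row vector
#' of each of 16 (generator, analyzer) pairs. The default scheme
#' \{H, V, P45, R\} x \{H, V, P45, R\} gives an exactly invertible 16 x 16
#' design; reconstruction is a single `solve()` applied to all pixels at once.
#'
#' @param frames named list of 16 nonnegative matrices, names `"g:a"` (e.g.
#'   `"H:P45"`) matching `scheme$scheme`.
#' @param scheme a [measurement_scheme()].
#' @param normalize divide each pixel's matrix by its M11?
#' @param floor_frac pixels whose reconstructed M11 is at or below
#'   `floor_frac * max(M11)` are marked invalid (and skipped by
#'   normalization).
#' @return [mueller_image()].
#' @export
mueller_from_measurements <- function(frames, scheme = measurement_scheme(),
                                      normalize = FALSE, floor_frac = 1e-6) {
  stopifnot(inherits(scheme, "measurement_scheme"))
  need <- frame_keys(scheme)
  check_frames(frames, need = need)
  if (nrow(scheme$A) != 16)
    stop("scheme must contain exactly 16 generator/analyzer pairs")
  rc <- rcond(scheme$A)
  if (rc < 1e-12)
    stop("singular design matrix for scheme {",
         paste(unique(scheme$scheme$generator), collapse = ","), "} x {",
         paste(unique(scheme$scheme$analyzer), collapse = ","),
         "} (rcond = ", format(rc), ")")
  shp <- dim(frames[[need[1]]])
  I <- do.call(rbind, lapply(need, function(k) as.vector(frames[[k]])))
  Mvec <- solve(scheme$A, I)  # 16 x npix
  M <- array(Mvec, dim = c(4, 4, shp[1], shp[2]))
  m11 <- M[1, 1, , , drop = TRUE]
  if (length(shp) == 2 && any(shp == 1)) m11 <- matrix(m11, shp[1], shp[2])
  valid <- intensity_floor_mask(m11, floor_frac)
  if (normalize) {
    norm <- ifelse(valid, m11, NA_real_)
    M <- sweep(M, 3:4, norm, "/")
  }
  mueller_image(M, normalized = normalize, valid = valid)
}

frame_keys <- function(scheme) {
  paste(scheme$scheme$generator, scheme$scheme$analyzer, sep = ":")
}

#' Forward-simulate measurement frames from a Mueller field
#'
#' The exact forward model used (and inverted) by
#' [mueller_from_measurements()]: for each scheme pair,
#' `I = analyzer . M . generator` per pixel. Serves as the reconstruction
#' oracle and powers the synthetic Mueller scene.
#'
#' @param m [mueller_image()] (unnormalized, in intensity units).
#' @param scheme a [measurement_scheme()].
#' @return named list of matrices keyed `"g:a"`.
#' @export
simulate_mueller_frames <- function(m, scheme = measurement_scheme()) {
  stopifnot(inherits(m, "mueller_image"))
  shp <- dim(m$M)[3:4]
  Mvec <- matrix(m$M, nrow = 16)
  I <- scheme$A %*% Mvec
  keys <- frame_keys(scheme)
  out <- lapply(seq_along(keys), function(i) matrix(I[i, ], shp[1], shp[2]))
  names(out) <- keys
  out
}

#' Beam-splitter correction of a raw Mueller image
#'
#' Removes measured beam-splitter Mueller factors from the raw reconstruction:
#' `M_sample = M_det^-1 . M_raw . M_ill^-1` per pixel. Identity corrections
#' leave the image bit-identical (the matrix multiplications are skipped).
#'
#' @param raw [mueller_image()].
#' @param M_ill,M_det 4x4 invertible Mueller matrices of the beam splitter in
#'   the illumination and detection arms; default identity (no hardware
#'   calibration).
#' @return corrected [mueller_image()].
#' @export
correct_beam_splitter <- function(raw, M_ill = diag(4), M_det = diag(4)) {
  stopifnot(inherits(raw, "mueller_image"))
  check_correction <- function(M, arm) {
    stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
    k <- kappa(M, exact = TRUE)
    if (!is.finite(k) || rcond(M) < .Machine$double.eps * 100)
      stop("non-invertible ", arm, " beam-splitter matrix (condition number ",
           format(k), ")")
  }
  check_correction(M_ill, "illumination")
  check_correction(M_det, "detection")
  if (identical(M_ill, diag(4)) && identical(M_det, diag(4))) return(raw)
  di <- solve(M_det)
  ii <- solve(M_ill)
  shp <- dim(raw$M)[3:4]
  # vec(D^-1 M I^-1) = (t(I^-1) kron D^-1) vec(M), applied to all pixels at once
  K <- t(ii) %x% di
  Mvec <- K %*% matrix(raw$M, nrow = 16)
  mueller_image(array(Mvec, dim = c(4, 4, shp[1], shp[2])),
                normalized = raw$normalized, valid = raw$valid)
}
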