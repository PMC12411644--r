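#' Threshold a fluorescence image into a tumor mask
#'
#' A pixel belongs to the tumor iff its value is at least
#' `fraction * max(image)`; the comparison is `>=`, so a pixel sitting exactly
#' at the threshold is included. The default 0.95 keeps only pixels within 5%
#' of the brightest fluorescence.
#'
#' @param fluor nonnegative, non-constant numeric matrix.
#' @param fraction threshold fraction in (0, 1].
#' @param keep_largest keep only the largest 8-connected component (off by
#'   default; useful for noisy fluorescence with speckle above threshold).
#' @return object of class `region_mask`: logical matrix with attributes
#'   `fraction` and `frame`.
#' @export
threshold_fluorescence <- function(fluor, fraction = 0.95, keep_largest = FALSE) {
  stopifnot(is.matrix(fluor), fraction > 0, fraction <= 1)
  if (any(fluor < 0, na.rm = TRUE)) stop("negative intensity in fluorescence image")
  mx <- max(fluor, na.rm = TRUE)
  mn <- min(fluor, na.rm = TRUE)
  if (mx == mn) stop("constant fluorescence image: threshold relative to max is undefined")
  mask <- !is.na(fluor) & fluor >= fraction * mx
  if (keep_largest) mask <- largest_component(mask)
  region_mask(mask, fraction = fraction, frame = "fluorescence")
}

region_mask <- function(mask, fraction = NA_real_, frame = "fluorescence") {
  structure(mask, fraction = fraction, frame = frame,
            class = c("region_mask", "matrix", "array"))
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d, %d tumor px (%.1f%%), frame: %s\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x), attr(x, "frame")))
  invisible(x)
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  keep <- which.max(tabulate(lab[lab > 0]))
  lab == keep
}

# 8-connected component labelling by iterative flood fill (BFS over pixel
# queues); adequate for mask-sized images.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  nxt <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue
      queue <- integer(0)
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        j <- (cc[ok] - 1L) * nr + rr[ok]
        j <- j[mask[j] & lab[j] == 0L]
        if (length(j)) {
          lab[j] <- nxt
          queue <- c(queue, unique(j))
        }
      }
    }
  }
  lab
}

# Binary erosion by a (2t+1) square structuring element; pixels outside the
# frame count as background, so mask pixels on the image border erode away.
erode_square <- function(mask, t) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  for (dr in -t:t) for (dc in -t:t) {
    if (dr == 0 && dc == 0) next
    out <- out & shift(mask, dr, dc)
    if (!any(out)) break
  }
  out
}

#' Extract the border outline of a mask
#'
#' Keeps the mask pixels within `thickness` (Chebyshev distance) of a non-mask
#' pixel — equivalently `mask & !erode(mask, square(2*thickness + 1))` — and
#' discards the interior, reproducing a thick tumor-margin outline. Pixels
#' outside the frame count as background, so a mask touching the image border
#' is outlined there too.
#'
#' @param mask logical matrix or [threshold_fluorescence()] result.
#' @param thickness outline thickness in pixels (>= 1); default 5.
#' @return object of class `outline_image`: logical matrix with attribute
#'   `thickness`. Empty mask gives an empty outline.
#' @export
extract_outline <- function(mask, thickness = 5) {
  stopifnot(is.matrix(mask), is.logical(c(mask)), thickness >= 1)
  thickness <- as.integer(thickness)
  out <- mask & !erode_square(mask, thickness)
  structure(out, thickness = thickness,
            class = c("outline_image", "matrix", "array"))
}

#' @export
print.outline_image <- function(x, ...) {
  cat(sprintf("<outline_image> %d x %d, %d outline px, thickness %d\n",
              nrow(x), ncol(x), sum(x), attr(x, "thickness")))
  invisible(x)
}
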