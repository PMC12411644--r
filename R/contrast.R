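class_values <- function(dop, mask, drop_oor = TRUE) {
  stopifnot(inherits(dop, "dop_image"))
  stopifnot(is.matrix(mask), is.logical(c(mask)))
  if (!all(dim(mask) == dim(dop))) stop("mask not registered to DOP frame: shape mismatch")
  valid <- attr(dop, "valid") & !is.na(unclass(dop))
  if (drop_oor) valid <- valid & !attr(dop, "out_of_range")
  v <- unclass(dop)
  list(tumor = v[mask & valid], nontumor = v[!mask & valid])
}

require_both_classes <- function(cv, minimum = 1) {
  for (cl in c("tumor", "nontumor"))
    if (length(cv[[cl]]) < minimum)
      stop("empty or too-small class: ", cl, " has ", length(cv[[cl]]),
           " valid pixels (need >= ", minimum, ")")
  invisible(cv)
}

#' Unit-area tumor / non-tumor histograms of a DOP image
#'
#' Bins the valid tumor and non-tumor pixels on one fixed set of `bins` equal
#' bins spanning \[-1 - eps, +1 + eps\] and normalizes each class to a density
#' (probability per unit DOP), so the area under each curve equals 1.
#' Out-of-range linear-DOP pixels are excluded (they carry the
#' `out_of_range` flag upstream).
#'
#' @param dop [dop_image()].
#' @param mask logical tumor mask registered to `dop`.
#' @param bins number of bins; default 80 (bin width 0.025).
#' @return object of class `region_histograms`: list with `bin_edges`,
#'   `bin_width`, `tumor_density`, `nontumor_density`, `counts` (per-class
#'   pixel totals).
#' @export
region_histograms <- function(dop, mask, bins = 80) {
  stopifnot(bins >= 2)
  cv <- require_both_classes(class_values(dop, mask))
  eps <- 1e-9
  edges <- seq(-1 - eps, 1 + eps, length.out = bins + 1)
  width <- diff(edges)[1]
  dens <- function(x) {
    h <- hist(x, breaks = edges, plot = FALSE, right = FALSE)
    h$counts / (length(x) * width)
  }
  structure(list(bin_edges = edges, bin_width = width,
                 tumor_density = dens(cv$tumor),
                 nontumor_density = dens(cv$nontumor),
                 counts = c(tumor = length(cv$tumor),
                            nontumor = length(cv$nontumor))),
            class = "region_histograms")
}

#' Histogram overlap area
#'
#' The overlapping coefficient of the two unit-area class histograms:
#' `sum(pmin(tumor, nontumor)) * bin_width`, in \[0, 1\]. 1 means identical
#' distributions (no separation), 0 disjoint supports (total separation).
#' Symmetric in the two classes and invariant to pixel-count scaling; the bin
#' width is reported alongside since the coefficient is binning-dependent.
#'
#' @param h a [region_histograms()] result.
#' @return list of class `overlap_result` with `overlap_area` and
#'   `bin_width`.
#' @export
overlap_area <- function(h) {
  stopifnot(inherits(h, "region_histograms"))
  ov <- sum(pmin(h$tumor_density, h$nontumor_density)) * h$bin_width
  structure(list(overlap_area = ov, bin_width = h$bin_width),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> overlap area %.4f (bin width %.4g)\n",
              x$overlap_area, x$bin_width))
  invisible(x)
}

roc_thresholds <- function(step = 0.05, lo = -1, hi = 1) {
  n <- round((hi - lo) / step)
  lo + step * seq_len(n - 1)   # interior thresholds: -0.95, ..., +0.95
}

# Threshold-sweep counts from per-class values. Positives are strictly above
# the threshold. Returns a data.frame of counts and rates per threshold.
sweep_counts <- function(tumor, nontumor, thresholds) {
  n_t <- length(tumor); n_n <- length(nontumor)
  TP <- vapply(thresholds, function(th) sum(tumor > th), numeric(1))
  FP <- vapply(thresholds, function(th) sum(nontumor > th), numeric(1))
  FN <- n_t - TP
  TN <- n_n - FP
  data.frame(threshold = thresholds, TP = TP, TN = TN, FP = FP, FN = FN,
             sensitivity = TP / (TP + FN), specificity = TN / (TN + FP))
}

#' Pixel-level ROC curve over a fixed threshold sweep
#'
#' Sweeps a DOP classification threshold over the interior grid -0.95, -0.90,
#' ..., +0.95 (step `step`). At each threshold, tumor-mask pixels strictly
#' above it are true positives and non-tumor pixels at or below it are true
#' negatives; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). The curve
#' plots (1 - specificity, sensitivity) and is anchored at (0,0) and (1,1)
#' for area integration.
#'
#' @param dop [dop_image()].
#' @param mask logical tumor mask registered to `dop`.
#' @param step threshold step; default 0.05 (39 interior thresholds).
#' @param use_magnitude classify on |value| instead of the signed value (the
#'   signed-value sweep is the literal definition; the magnitude variant is
#'   offered because helicity-flipping tumors are *more negative*, which the
#'   signed sweep scores below 0.5).
#' @return object of class `roc_result`: list with `table` (per-threshold
#'   counts and rates), `points` (x = 1 - specificity, y = sensitivity,
#'   anchors included), `auc`, `use_magnitude`, class pixel counts.
#' @export
roc_curve <- function(dop, mask, step = 0.05, use_magnitude = FALSE) {
  cv <- require_both_classes(class_values(dop, mask))
  if (use_magnitude) cv <- lapply(cv, abs)
  thresholds <- roc_thresholds(step)
  tab <- sweep_counts(cv$tumor, cv$nontumor, thresholds)
  pts <- data.frame(x = 1 - tab$specificity, y = tab$sensitivity)
  pts <- rbind(data.frame(x = 1, y = 1), pts, data.frame(x = 0, y = 0))
  pts <- pts[order(pts$x, pts$y), ]
  res <- structure(list(table = tab, points = pts, auc = NA_real_,
                        use_magnitude = use_magnitude,
                        n = c(tumor = length(cv$tumor),
                              nontumor = length(cv$nontumor))),
                   class = "roc_result")
  res$auc <- auc(res)
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d thresholds (%s values), %d / %d px\n",
              x$auc, nrow(x$table),
              if (x$use_magnitude) "magnitude" else "signed",
              x$n["tumor"], x$n["nontumor"]))
  invisible(x)
}

#' Trapezoidal AUC of a swept ROC curve
#'
#' Integrates the anchored (0,0)..(1,1) polyline by the trapezoidal rule.
#' Values below 0.5 are reported as-is: a classifier that ranks tumor *below*
#' non-tumor scores under chance, and no orientation flip is applied.
#'
#' @param roc a [roc_curve()] result (or any list with a sorted `points`
#'   data.frame).
#' @return scalar AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  p <- roc$points
  stopifnot(!is.unsorted(p$x))
  sum(diff(p$x) * (head(p$y, -1) + tail(p$y, -1)) / 2)
}

auc_from_bins <- function(ct, cn) {
  # swept AUC from per-class counts on the threshold bins (bins ordered
  # ascending in value; thresholds are the interior bin boundaries)
  n_t <- sum(ct); n_n <- sum(cn)
  sens <- rev(cumsum(rev(ct)))[-1] / n_t   # P(tumor > threshold_k)
  fpr <- rev(cumsum(rev(cn)))[-1] / n_n
  x <- c(0, rev(fpr), 1)
  y <- c(0, rev(sens), 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

bin_for_sweep <- function(values, step = 0.05) {
  # bin index 1..(2/step) by the threshold grid; "strictly above" positives
  # mean a value equal to a threshold belongs to the bin below it
  edges <- c(-Inf, roc_thresholds(step), Inf)
  findInterval(values, edges, left.open = TRUE)
}

#' Bootstrap confidence interval for the swept AUC
#'
#' Percentile 95% interval over `n_boot` stratified pixel resamples. Because
#' the threshold-sweep AUC depends on the data only through the per-class
#' counts on the 40 threshold bins, resampling pixels with replacement within
#' each class is realized exactly as a multinomial draw over those bins,
#' which makes the bootstrap O(bins) per replicate regardless of pixel count.
#' Deterministic given `seed`.
#'
#' @param dop [dop_image()].
#' @param mask logical tumor mask registered to `dop`.
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed integer seed (mandatory).
#' @param step threshold step of the sweep.
#' @param use_magnitude classify on absolute values (see [roc_curve()]).
#' @return list of class `auc_ci`: `lo`, `hi`, `n_boot`, `method`.
#' @export
auc_ci <- function(dop, mask, n_boot = 1000, seed, step = 0.05,
                   use_magnitude = FALSE) {
  stopifnot(!missing(seed))
  cv <- require_both_classes(class_values(dop, mask), minimum = 10)
  if (use_magnitude) cv <- lapply(cv, abs)
  nbin <- length(roc_thresholds(step)) + 1
  ct <- tabulate(bin_for_sweep(cv$tumor, step), nbins = nbin)
  cn <- tabulate(bin_for_sweep(cv$nontumor, step), nbins = nbin)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bt <- rmultinom(n_boot, sum(ct), ct / sum(ct))
  bn <- rmultinom(n_boot, sum(cn), cn / sum(cn))
  reps <- vapply(seq_len(n_boot), function(i) {
    if (sum(bt[, i]) == 0 || sum(bn[, i]) == 0) return(NA_real_)
    auc_from_bins(bt[, i], bn[, i])
  }, numeric(1))
  dropped <- sum(is.na(reps))
  if (dropped) message(dropped, " degenerate single-class resamples skipped")
  qs <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE, type = 7))
  structure(list(lo = qs[1], hi = qs[2], n_boot = n_boot,
                 method = "stratified percentile bootstrap (multinomial over sweep bins)"),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("<auc_ci> 95%% CI (%.4f, %.4f), %d replicates\n",
              x$lo, x$hi, x$n_boot))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Per-class region summary of linear and circular DOP
#'
#' Class-wise mean, SD and pixel count of each signed metric over valid
#' pixels, plus the per-class mean of the per-pixel total DOP magnitude
#' (|DOLP| + |DOCP|) / 2 — the bold inset numbers of a violin-plot summary.
#'
#' @param dolp,docp [dop_image()] objects with metrics linear and circular.
#' @param mask logical tumor mask registered to both.
#' @return data.frame of class `region_summary` with columns `metric`,
#'   `class`, `mean`, `sd`, `n`.
#' @export
region_summary <- function(dolp, docp, mask) {
  stopifnot(attr(dolp, "metric") == "linear", attr(docp, "metric") == "circular")
  cl <- require_both_classes(class_values(dolp, mask))
  cc <- require_both_classes(class_values(docp, mask))
  tot <- total_dop_magnitude(dolp, docp)
  ct <- require_both_classes(class_values(tot, mask))
  row <- function(metric, class, x)
    data.frame(metric = metric, class = class, mean = mean(x),
               sd = stats::sd(x), n = length(x))
  out <- rbind(
    row("linear", "tumor", cl$tumor), row("linear", "nontumor", cl$nontumor),
    row("circular", "tumor", cc$tumor), row("circular", "nontumor", cc$nontumor),
    row("total_magnitude", "tumor", ct$tumor),
    row("total_magnitude", "nontumor", ct$nontumor))
  class(out) <- c("region_summary", "data.frame")
  out
}
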