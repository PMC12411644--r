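# Independent oracles used across test files. These never call the code paths
# they check.

const_img <- function(v, nr = 2, nc = 2) matrix(v, nr, nc)

# Brute-force outline: a mask pixel is on the outline iff some non-mask pixel
# (or the frame edge) lies within Chebyshev distance `t`.
brute_outline <- function(mask, t) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    hit <- FALSE
    for (dr in -t:t) {
      for (dc in -t:t) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    out[r, c] <- hit
  }
  out
}

# Exact Mann-Whitney AUC (pair-count probability with ties counted 1/2),
# computed through the rank-sum identity.
mw_auc <- function(tumor, nontumor) {
  r <- rank(c(tumor, nontumor))
  n1 <- length(tumor); n2 <- length(nontumor)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Swept AUC recomputed from first principles (no package code): counts above
# each threshold, trapezoid over anchored points.
brute_sweep_auc <- function(tumor, nontumor, step = 0.05) {
  th <- seq(-1 + step, 1 - step, by = step)
  sens <- vapply(th, function(t) mean(tumor > t), numeric(1))
  fpr <- vapply(th, function(t) mean(nontumor > t), numeric(1))
  x <- c(0, rev(fpr), 1); y <- c(0, rev(sens), 1)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Literal stratified pixel-resampling bootstrap CI for the swept AUC.
brute_boot_ci <- function(tumor, nontumor, n_boot, seed, step = 0.05) {
  set.seed(seed)
  reps <- replicate(n_boot, {
    t2 <- sample(tumor, replace = TRUE)
    n2 <- sample(nontumor, replace = TRUE)
    brute_sweep_auc(t2, n2, step)
  })
  unname(quantile(reps, c(0.025, 0.975)))
}

# Brute-force rasterized-ellipse pixel count (0-based pixel centres).
brute_ellipse_count <- function(shape, center, axes, rot) {
  n <- 0L
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
    u <- cos(rot) * (r - center[1]) + sin(rot) * (c - center[2])
    v <- -sin(rot) * (r - center[1]) + cos(rot) * (c - center[2])
    if ((u / axes[1])^2 + (v / axes[2])^2 <= 1) n <- n + 1L
  }
  n
}

# Physical Mueller matrices of standard elements, for building realistic
# (passive, hence nonnegative-intensity) beam-splitter factors.
mm_diattenuator <- function(t) {
  0.5 * rbind(c(1 + t, 1 - t, 0, 0), c(1 - t, 1 + t, 0, 0),
              c(0, 0, 2 * sqrt(t), 0), c(0, 0, 0, 2 * sqrt(t)))
}
mm_retarder <- function(delta) {
  rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
        c(0, 0, cos(delta), sin(delta)), c(0, 0, -sin(delta), cos(delta)))
}
mm_rotator <- function(theta) {
  rbind(c(1, 0, 0, 0),
        c(0, cos(2 * theta), sin(2 * theta), 0),
        c(0, -sin(2 * theta), cos(2 * theta), 0),
        c(0, 0, 0, 1))
}
mm_beamsplitter <- function(theta, delta, t) {
  mm_rotator(theta) %*% mm_retarder(delta) %*% mm_diattenuator(t)
}

# Frames realizing a given constant signed DOP pair, clean (no noise).
clean_dop_frames <- function(d_c, d_l, nr = 4, nc = 4, s0 = 1) {
  list(R = const_img(s0 * (1 + d_c) / 2, nr, nc),
       L = const_img(s0 * (1 - d_c) / 2, nr, nc),
       H = const_img(s0 * (1 - d_l) / 2, nr, nc),
       V = const_img(s0 * (1 + d_l) / 2, nr, nc),
       P45 = const_img(s0 / 2, nr, nc),
       M45 = const_img(s0 / 2, nr, nc))
}

# dop_image holding given per-class values on a half/half split mask.
two_class_dop <- function(tumor_vals, nontumor_vals, metric = "circular") {
  n <- length(tumor_vals) + length(nontumor_vals)
  nr <- ceiling(sqrt(n))
  nc <- ceiling(n / nr)
  v <- rep(NA_real_, nr * nc)
  v[seq_along(tumor_vals)] <- tumor_vals
  v[length(tumor_vals) + seq_along(nontumor_vals)] <- nontumor_vals
  vals <- matrix(v, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  mask[seq_along(tumor_vals)] <- TRUE
  list(dop = dop_image(vals, metric, valid = !is.na(vals)), mask = mask)
}
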