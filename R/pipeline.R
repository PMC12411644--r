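#' Run configuration
#'
#' Loads a YAML or JSON run configuration, applies defaults, and checks that
#' every referenced input exists. A configuration either names on-disk inputs
#' (`frames_dir`, `fluorescence`, `fiducials`) or sets `simulate: true` to
#' generate them from the embedded scene parameters first.
#'
#' @param path YAML/JSON file, or a named list of the same shape.
#' @param overrides named list taking precedence over file values (CLI
#'   flags).
#' @return validated list of class `run_config`.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(simulate = FALSE, out_dir = "polcontrast_run",
                   threshold_fraction = 0.95, outline_thickness = 5,
                   bins = 80, roc_step = 0.05, n_boot = 1000, seed = 1,
                   transform_model = "similarity", mueller = FALSE,
                   figures = TRUE, scene = list())
  cfg <- utils::modifyList(defaults, cfg)
  cfg <- utils::modifyList(cfg, overrides)
  if (!cfg$simulate) {
    for (p in c("frames_dir", "fluorescence", "fiducials")) {
      if (is.null(cfg[[p]])) stop("run config: missing required path '", p, "'")
      if (!file.exists(cfg[[p]]))
        stop("run config: ", p, " does not exist: ", cfg[[p]])
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

run_log <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full contrast pipeline
#'
#' Orchestrates simulate/ingest, DOP (and optionally Mueller) image
#' computation, fluorescence masking and fiducial registration, and the
#' contrast statistics, writing CSV/JSON results (and figures) under
#' `out_dir`. Every stage logs its parameters and pixel counts to stderr and
#' to `run.log`; any stage error aborts with the stage name in the message.
#'
#' The ROC/AUC block reports both orientations: the literal signed-value
#' sweep (tumors that flip helicity score *below* 0.5 there) and the
#' magnitude sweep.
#'
#' @param config a [load_run_config()] result, config path, or list.
#' @return invisibly, the result bundle: list with `docp`, `dolp`, `mask`,
#'   `outline`, `transform`, `histograms`, `overlap`, `roc`, `roc_magnitude`,
#'   `auc_ci`, `summary`, `mueller` (optional), `paths` of written files.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "run.log"), "w")
  on.exit(close(logf), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  run_log(logf, "config", sprintf(
    "seed=%d threshold=%.3g thickness=%d bins=%d step=%.3g n_boot=%d",
    cfg$seed, cfg$threshold_fraction, cfg$outline_thickness, cfg$bins,
    cfg$roc_step, cfg$n_boot))

  ## ingest or simulate -----------------------------------------------------
  inputs <- stage("ingest", {
    if (isTRUE(cfg$simulate)) {
      sc_args <- cfg$scene
      sc_args$seed <- cfg$seed
      scene <- make_dop_scene(do.call(scene_config, sc_args))
      sim_dir <- file.path(cfg$out_dir, "simulated")
      write_frame_set(scene$frames, sim_dir)
      write_image_csv(scene$fluor, file.path(sim_dir, "fluorescence.csv"))
      write_fiducials(scene$fiducials, file.path(sim_dir, "fiducials.csv"))
      run_log(logf, "simulate", sprintf("scene %dx%d, %d tumor px -> %s",
              nrow(scene$class_map), ncol(scene$class_map),
              sum(scene$class_map), sim_dir))
      list(frames = scene$frames, fluor = scene$fluor,
           fid = read_fiducials(file.path(sim_dir, "fiducials.csv")),
           scene = scene)
    } else {
      list(frames = read_frame_set(cfg$frames_dir),
           fluor = read_image_csv(cfg$fluorescence),
           fid = read_fiducials(cfg$fiducials), scene = NULL)
    }
  })

  ## DOP images -------------------------------------------------------------
  docp <- stage("dop", signed_docp(inputs$frames$R, inputs$frames$L))
  dolp <- stage("dop", signed_dolp(inputs$frames$H, inputs$frames$V,
                                   inputs$frames$P45, inputs$frames$M45))
  run_log(logf, "dop", sprintf("docp valid px=%d, dolp valid px=%d",
          sum(attr(docp, "valid")), sum(attr(dolp, "valid"))))

  mueller <- NULL
  if (isTRUE(cfg$mueller)) {
    mueller <- stage("mueller", {
      keys <- frame_keys(measurement_scheme())
      if (all(keys %in% names(inputs$frames)))
        mueller_from_measurements(inputs$frames[keys], normalize = TRUE)
      else NULL
    })
    run_log(logf, "mueller",
            if (is.null(mueller)) "16-state frames absent; skipped"
            else "reconstructed and normalized")
  }

  ## segmentation + registration --------------------------------------------
  mask_fl <- stage("segment",
                   threshold_fluorescence(inputs$fluor, cfg$threshold_fraction))
  outline_fl <- stage("segment", extract_outline(mask_fl, cfg$outline_thickness))
  tr <- stage("register", estimate_transform(inputs$fid$src, inputs$fid$dst,
                                             model = cfg$transform_model))
  mask <- stage("register", apply_transform(mask_fl, tr, dim(docp)))
  outline <- stage("register", apply_transform(outline_fl, tr, dim(docp)))
  run_log(logf, "segment", sprintf("mask px=%d, outline px=%d", sum(mask),
          sum(outline)))
  run_log(logf, "register", sprintf(
    "%s: rot=%.4f rad scale=%.4f shift=(%.2f, %.2f) rmse=%.3g px",
    tr$model, tr$rotation, tr$scale, tr$translation[1], tr$translation[2],
    tr$rmse))

  ## contrast statistics -----------------------------------------------------
  hists <- stage("contrast", list(circular = region_histograms(docp, mask, cfg$bins),
                                  linear = region_histograms(dolp, mask, cfg$bins)))
  ovl <- lapply(hists, overlap_area)
  roc_signed <- stage("contrast", roc_curve(docp, mask, cfg$roc_step))
  roc_mag <- stage("contrast", roc_curve(docp, mask, cfg$roc_step,
                                         use_magnitude = TRUE))
  ci <- stage("contrast", auc_ci(docp, mask, n_boot = cfg$n_boot,
                                 seed = cfg$seed + 1L, step = cfg$roc_step))
  summ <- stage("contrast", region_summary(dolp, docp, mask))
  run_log(logf, "contrast", sprintf(
    "AUC signed=%.4f magnitude=%.4f CI=(%.4f, %.4f) overlap circ=%.4f lin=%.4f",
    roc_signed$auc, roc_mag$auc, ci$lo, ci$hi,
    ovl$circular$overlap_area, ovl$linear$overlap_area))

  ## outputs ----------------------------------------------------------------
  paths <- stage("report", {
    od <- cfg$out_dir
    write_image_csv(docp, file.path(od, "docp.csv"))
    write_image_csv(dolp, file.path(od, "dolp.csv"))
    write_mask_png(mask, file.path(od, "mask.png"))
    write_mask_png(outline, file.path(od, "outline.png"))
    data.table::fwrite(roc_signed$table, file.path(od, "roc_table.csv"))
    data.table::fwrite(summ, file.path(od, "region_summary.csv"))
    jsonlite::write_json(list(
      auc_signed = roc_signed$auc, auc_magnitude = roc_mag$auc,
      auc_ci = c(ci$lo, ci$hi),
      overlap_circular = ovl$circular$overlap_area,
      overlap_linear = ovl$linear$overlap_area,
      bin_width = hists$circular$bin_width,
      registration = list(model = tr$model, rotation = tr$rotation,
                          scale = tr$scale, translation = tr$translation,
                          rmse = tr$rmse),
      seed = cfg$seed), file.path(od, "contrast.json"),
      auto_unbox = TRUE, digits = NA)
    c(docp = file.path(od, "docp.csv"), dolp = file.path(od, "dolp.csv"),
      mask = file.path(od, "mask.png"), outline = file.path(od, "outline.png"),
      roc = file.path(od, "roc_table.csv"),
      summary = file.path(od, "region_summary.csv"),
      json = file.path(od, "contrast.json"))
  })

  bundle <- structure(list(docp = docp, dolp = dolp, mask = mask,
                           outline = outline, transform = tr,
                           histograms = hists, overlap = ovl,
                           roc = roc_signed, roc_magnitude = roc_mag,
                           auc_ci = ci, summary = summ, mueller = mueller,
                           scene = inputs$scene, paths = paths,
                           config = cfg),
                      class = "contrast_bundle")
  if (isTRUE(cfg$figures)) {
    figs <- stage("report", render_report(bundle, cfg$out_dir))
    bundle$paths <- c(bundle$paths, figs)
  }
  run_log(logf, "done", "all stages complete")
  invisible(bundle)
}

#' Render report figures from a result bundle
#'
#' Writes PNG figures mirroring the analysis layout: the DOP images with the
#' tumor outline overlaid, overlaid unit-area class histograms annotated with
#' the overlap area, the ROC curve annotated with its AUC, a violin-style
#' per-class summary panel, and (when present) the 4 x 4 Mueller element
#' grid. Annotated numbers are the same objects written to CSV/JSON. Missing
#' sub-results skip their panel with a warning.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return named character vector of figure paths.
#' @export
render_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  figs <- c()
  fig <- function(name, width, height, draw) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    figs[[name]] <<- p
  }

  show_dop <- function(img, outline, main) {
    v <- pmax(pmin(unclass(img), 1), -1)
    v[!attr(img, "valid")] <- NA
    graphics::image(t(v)[, nrow(v):1], zlim = c(-1, 1), useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    axes = FALSE, main = main, asp = nrow(v) / ncol(v))
    if (!is.null(outline)) {
      o <- which(outline, arr.ind = TRUE)
      graphics::points((o[, 2] - 1) / (ncol(outline) - 1),
                       1 - (o[, 1] - 1) / (nrow(outline) - 1),
                       pch = ".", col = "black")
    }
  }

  fig("fig_dop_images.png", 900, 480, function() {
    graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
    show_dop(bundle$docp, bundle$outline, "signed circular DOP")
    show_dop(bundle$dolp, bundle$outline, "signed linear DOP")
  })

  fig("fig_histograms.png", 900, 480, function() {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
    for (metric in c("circular", "linear")) {
      h <- bundle$histograms[[metric]]
      mid <- (head(h$bin_edges, -1) + tail(h$bin_edges, -1)) / 2
      ylim <- c(0, max(h$tumor_density, h$nontumor_density))
      graphics::plot(mid, h$nontumor_density, type = "h", col = "darkgreen",
                     lwd = 2, xlab = paste("signed", metric, "DOP"),
                     ylab = "density", ylim = ylim,
                     main = sprintf("%s: overlap %.3f", metric,
                                    bundle$overlap[[metric]]$overlap_area))
      graphics::lines(mid, h$tumor_density, type = "h",
                      col = grDevices::adjustcolor("red", 0.6), lwd = 2)
      graphics::legend("topleft", c("tumor", "non-tumor"), bty = "n",
                       col = c("red", "darkgreen"), lwd = 2)
    }
  })

  fig("fig_roc.png", 480, 480, function() {
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::plot(bundle$roc$points$x, bundle$roc$points$y, type = "b",
                   pch = 16, cex = 0.6, xlab = "1 - specificity",
                   ylab = "sensitivity",
                   main = sprintf("ROC: AUC %.3f (signed), %.3f (|DOP|)",
                                  bundle$roc$auc, bundle$roc_magnitude$auc))
    graphics::lines(bundle$roc_magnitude$points$x, bundle$roc_magnitude$points$y,
                    type = "b", pch = 1, cex = 0.6, col = "grey40")
    graphics::abline(0, 1, lty = 3)
  })

  fig("fig_summary.png", 640, 480, function() {
    s <- bundle$summary
    graphics::par(mar = c(7, 4, 3, 1))
    lab <- paste(s$metric, s$class, sep = "\n")
    bp <- graphics::barplot(s$mean, names.arg = lab, las = 2,
                            ylim = range(0, s$mean - s$sd, s$mean + s$sd),
                            ylab = "mean signed DOP",
                            main = "per-class summary (bars: mean, whiskers: SD)")
    graphics::arrows(bp, s$mean - s$sd, bp, s$mean + s$sd, angle = 90,
                     code = 3, length = 0.04)
    graphics::text(bp, s$mean, sprintf("%.3f", s$mean), pos = 3, cex = 0.8)
  })

  if (!is.null(bundle$mueller)) {
    fig("fig_mueller.png", 960, 960, function() {
      graphics::par(mfrow = c(4, 4), mar = c(0.5, 0.5, 2, 0.5))
      for (r in 1:4) for (c in 1:4) {
        el <- mueller_element(bundle$mueller, r, c)
        graphics::image(t(el)[, nrow(el):1], useRaster = TRUE, axes = FALSE,
                        col = grDevices::hcl.colors(64, "Blue-Red 3"),
                        zlim = c(-1, 1) * max(abs(el), 1e-12),
                        main = sprintf("M%d%d", r, c))
      }
    })
  } else if (isTRUE(bundle$config$mueller)) {
    warning("Mueller stage result missing; Mueller panel skipped")
  }
  unlist(figs)
}
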