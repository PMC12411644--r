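#' Read and write image matrices as CSV grids
#'
#' Float images travel as headerless CSV grids (one row per pixel row);
#' binary masks as PNG (0/255). Each writer drops a JSON sidecar
#' (`<file>.json`) carrying the metadata the containers track: metric,
#' convention, valid-pixel count, provenance.
#'
#' @param img numeric matrix (or `dop_image`).
#' @param path output file path.
#' @param meta named list merged into the sidecar.
#' @return `write_image_csv()` returns `path` invisibly; `read_image_csv()`
#'   the matrix (with the sidecar, if present, in attribute `meta`).
#' @export
write_image_csv <- function(img, path, meta = list()) {
  m <- unclass(img)
  if (inherits(img, "dop_image"))
    meta <- c(meta, list(metric = attr(img, "metric"),
                         valid_pixels = sum(attr(img, "valid")),
                         out_of_range_pixels = sum(attr(img, "out_of_range"))))
  attributes(m) <- list(dim = dim(m))
  data.table::fwrite(data.table::as.data.table(m), path,
                     col.names = FALSE)
  meta <- c(list(rows = nrow(m), cols = ncol(m),
                 convention = "S1=H-V, S2=P45-M45, S3=R-L (R positive)"), meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(m, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  m
}

#' @rdname write_image_csv
#' @export
write_mask_png <- function(img, path, meta = list()) {
  m <- unclass(img)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  meta <- c(list(rows = nrow(m), cols = ncol(m), true_pixels = sum(m)), meta)
  if (!is.null(attr(img, "fraction"))) meta$threshold_fraction <- attr(img, "fraction")
  if (!is.null(attr(img, "thickness"))) meta$thickness <- attr(img, "thickness")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_mask_png <- function(path) {
  png::readPNG(path) >= 0.5
}

#' Write or read a measurement-frame set with its manifest
#'
#' Frames are written one CSV grid per (incident, analyzed) state with a
#' `manifest.json` mapping file names to state pairs; `read_frame_set()`
#' reconstitutes the named list from the manifest.
#'
#' @param frames named list of matrices; names either analyzer states
#'   (`"R"`, `"L"`, ...) or `"generator:analyzer"` pairs.
#' @param dir directory (created if absent).
#' @return `write_frame_set()`: the manifest path, invisibly;
#'   `read_frame_set()`: named list of matrices.
#' @export
write_frame_set <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(frames), function(nm) {
    fn <- paste0("frame_", gsub(":", "_", nm), ".csv")
    write_image_csv(frames[[nm]], file.path(dir, fn))
    fn
  }, character(1))
  manifest <- list(frames = as.list(stats::setNames(files, names(frames))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  invisible(mp)
}

#' @rdname write_frame_set
#' @export
read_frame_set <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("frames manifest not found: ", mp)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  out <- lapply(manifest$frames, function(fn) read_image_csv(file.path(dir, fn)))
  names(out) <- names(manifest$frames)
  out
}

#' Fiducial correspondence I/O
#'
#' CSV with columns `frame` (`fluorescence` / `polarimetry`), `point_id`,
#' `row`, `col`, 0-based pixel coordinates.
#'
#' @param fid data.frame in that layout.
#' @param path CSV path.
#' @return `read_fiducials()` returns a list with `src` and `dst` n x 2
#'   matrices (fluorescence and polarimetry points, matched by `point_id`).
#' @export
write_fiducials <- function(fid, path) {
  data.table::fwrite(fid, path)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  fid <- as.data.frame(data.table::fread(path))
  need <- c("frame", "point_id", "row", "col")
  if (!all(need %in% names(fid)))
    stop("fiducial CSV must have columns ", paste(need, collapse = ", "))
  s <- fid[fid$frame == "fluorescence", ]
  d <- fid[fid$frame == "polarimetry", ]
  ids <- intersect(s$point_id, d$point_id)
  if (length(ids) < 2) stop("need >= 2 matched fiducial pairs, got ", length(ids))
  s <- s[match(ids, s$point_id), ]; d <- d[match(ids, d$point_id), ]
  list(src = as.matrix(s[, c("row", "col")]),
       dst = as.matrix(d[, c("row", "col")]))
}
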