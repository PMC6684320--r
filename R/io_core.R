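#' Read a (multi-channel) TIFF image
#'
#' Reads a TIFF into plain numeric matrices and resolves channels by role.
#' The physical pixel size is taken from the TIFF resolution metadata when
#' present; otherwise `pixel_size_um` must be supplied (an explicit override
#' always wins).
#'
#' @param path TIFF file.
#' @param channel_map optional named list/vector mapping role names to plane
#'   indices, e.g. `c(nucleus = 1, golgi = 2)`.
#' @param pixel_size_um pixel size override (um/px).
#' @return list with `images` (named list of matrices) and `pixel_size_um`
#'   (may be `NA` when unknown and not overridden; downstream steps that
#'   need physical units will then error naming `pixel_size_um`).
#' @export
read_image <- function(path, channel_map = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  planes <- list()
  for (p in pages) {
    if (length(dim(p)) == 3L) {
      for (k in seq_len(dim(p)[3]))
        planes[[length(planes) + 1L]] <- strip(p[, , k])
    } else planes[[length(planes) + 1L]] <- strip(p)
  }
  px <- pixel_size_um
  if (is.null(px)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    px <- if (!is.null(xres) && !is.null(unit) && xres > 0) {
      switch(as.character(unit), cm = 1e4 / xres, inch = 25400 / xres,
             NA_real_)
    } else NA_real_
  }
  if (!is.null(channel_map)) {
    planes <- setNames(planes[as.integer(channel_map)], names(channel_map))
  } else names(planes) <- paste0("channel", seq_along(planes))
  list(images = planes, pixel_size_um = px)
}

#' Write an image matrix as TIFF
#'
#' Intensities are stored as 32-bit floats on the TIFF [0, 1] scale:
#' values are divided by `scale` before writing (multiply by the same scale
#' after [read_image()] to recover physical intensities). Values outside
#' [0, scale] are an error rather than silent clipping.
#'
#' @param image numeric matrix (or list of matrices for a stack).
#' @param path output file.
#' @param scale full-scale intensity mapped to TIFF white (default 1).
#' @export
write_image <- function(image, path, scale = 1) {
  planes <- if (is.list(image)) image else list(image)
  planes <- lapply(planes, function(m) as.matrix(m) / scale)
  rng <- range(unlist(lapply(planes, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities outside [0, scale]: pass a suitable 'scale'",
         call. = FALSE)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Run configuration snapshot
#'
#' Collects the stage parameters, paths and unit metadata of an analysis run
#' into a single object that is embedded in every output, so any result can
#' be reproduced from its emitted config and seed.
#'
#' @param ... named parameters (bin widths, thresholds, seeds, paths, ...).
#' @return list of class `run_config` with a `package_version` field added.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && is.null(names(cfg)))
    stop("run_config() takes named parameters only", call. = FALSE)
  cfg$package_version <- as.character(utils::packageVersion("ecpolarity"))
  structure(cfg, class = "run_config")
}

#' Write result tables plus a JSON summary and config snapshot
#'
#' Writes each table as `<prefix>_<name>.csv` with a deterministic column
#' order (as given), a `<prefix>_summary.json`, and a `<prefix>_config.json`
#' snapshot. Re-running with identical inputs produces byte-identical
#' files; the prefix namespaces stages sharing one directory.
#'
#' @param tables named list of data.frames (may be empty).
#' @param summary named list of summary values.
#' @param out_dir output directory (created if needed).
#' @param config optional [run_config()].
#' @param prefix file-name prefix (default `"results"`).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables = list(), summary = list(), out_dir,
                          config = NULL, prefix = "results") {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir", call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, sprintf("%s_%s.csv", prefix, nm))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (is.null(summary$n)) summary$n <- sum(vapply(tables, nrow, integer(1)))
  ps <- file.path(out_dir, sprintf("%s_summary.json", prefix))
  jsonlite::write_json(summary, ps, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, ps)
  if (!is.null(config)) {
    pc <- file.path(out_dir, sprintf("%s_config.json", prefix))
    jsonlite::write_json(unclass(config), pc, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, pc)
  }
  invisible(paths)
}
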