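#' End-to-end measurement and batch grading
#'
#' The on-screen record of a grading rig, as machine-readable output: one
#' row per egg with picture id, weight, axes, shape index, volume,
#' density, size class, freshness percentage and band.
#'
#' @name pipeline
NULL

.resolve_calibration <- function(calibration) {
  if (inherits(calibration, "calibration_profile")) return(calibration)
  if (is.character(calibration)) return(read_calibration(calibration))
  if (is.numeric(calibration)) return(calibration_profile(calibration))
  stop("`calibration` must be a profile, a file path or mm-per-px",
       call. = FALSE)
}

.resolve_scheme <- function(config) {
  if (is.null(config)) return(default_grading_scheme())
  if (inherits(config, "grading_scheme")) return(config)
  if (is.character(config)) return(read_grading_config(config))
  stop("`config` must be a grading scheme or a config file path",
       call. = FALSE)
}

#' Measure and grade a single egg image
#'
#' Runs the full pipeline — denoise, grayscale, segment, measure axes,
#' convert to mm, compute morphometrics, classify — and returns the
#' grading record. Optionally serialises it as JSON and appends it to a
#' CSV log.
#'
#' @param image File path (PNG/TIFF) or raster as accepted by
#'   [measure_image()].
#' @param weight Egg weight in grams.
#' @param calibration A `calibration_profile`, a calibration file path, or
#'   a bare mm-per-px number.
#' @param config Optional `grading_scheme` or config file path; the
#'   built-in scheme is used when omitted.
#' @param json Optional path: write the record as a JSON object.
#' @param csv Optional path: append the record (header written once).
#' @return One-row data.frame (the grading record) with an `image_id`
#'   column first; segmentation details in attribute `"segmentation"`.
#' @export
run_measure <- function(image, weight, calibration, config = NULL,
                        json = NULL, csv = NULL) {
  profile <- .resolve_calibration(calibration)
  scheme <- .resolve_scheme(config)
  meas <- measure_image(image, profile, weight)
  rec <- grade_egg(meas, scheme)
  rec <- cbind(
    data.frame(image_id = if (is.character(image)) basename(image) else "<raster>",
               stringsAsFactors = FALSE),
    rec)
  if (!is.null(json)) {
    jsonlite::write_json(as.list(rec), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv)) {
    utils::write.table(rec, csv, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv), append = file.exists(csv))
  }
  attr(rec, "segmentation") <- attr(meas, "segmentation")
  rec
}

#' Grade a manifest of egg images
#'
#' The manifest lists one egg per row (`image`, `weight`). Rows that fail
#' (unreadable file, no egg detected) are logged and skipped; the batch
#' always continues. The returned report carries per-class and per-band
#' counts as its `summary` attribute.
#'
#' @param manifest CSV path or data.frame with columns `image`, `weight`.
#' @param calibration As in [run_measure()].
#' @param config As in [run_measure()].
#' @param csv Optional output CSV for the full report.
#' @return A list of class `batch_report`: `report` (data.frame of
#'   grading records), `failures` (data.frame `image`, `error`), and
#'   `summary` (counts per size class and freshness band).
#' @export
run_batch <- function(manifest, calibration, config = NULL, csv = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                     call. = FALSE)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(manifest))
  if (!all(c("image", "weight") %in% names(manifest))) {
    stop("manifest needs `image` and `weight` columns", call. = FALSE)
  }
  profile <- .resolve_calibration(calibration)
  scheme <- .resolve_scheme(config)
  if (nrow(manifest) == 0) {
    warning("empty manifest: nothing to grade", call. = FALSE)
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      run_measure(manifest$image[i], manifest$weight[i], profile, scheme),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        image = manifest$image[i], error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      attr(res, "segmentation") <- NULL
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0))
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(image = character(0), error = character(0),
               stringsAsFactors = FALSE)
  summary <- list(
    n_input = nrow(manifest), n_graded = nrow(report),
    n_failed = nrow(failures),
    by_size_class = if (nrow(report)) table(report$size_class, useNA = "ifany")
                    else table(integer(0)),
    by_band = if (nrow(report)) table(report$freshness_band) else
      table(character(0)))
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  structure(list(report = report, failures = failures, summary = summary),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<batch_report> %d input, %d graded, %d failed\n",
              s$n_input, s$n_graded, s$n_failed))
  if (s$n_graded > 0) {
    cat("  size classes: ",
        paste(sprintf("%s:%d", names(s$by_size_class), s$by_size_class),
              collapse = " "), "\n")
    cat("  bands:        ",
        paste(sprintf("%s:%d", names(s$by_band), s$by_band),
              collapse = " "), "\n")
  }
  invisible(x)
}
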