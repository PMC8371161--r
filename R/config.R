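#' Configuration and calibration files
#'
#' Grading schemes and calibration profiles are plain YAML or JSON
#' documents so they can be versioned alongside the rig they describe.
#'
#' @name config
NULL

.read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a grading scheme from a config file
#'
#' Recognised keys (all optional; defaults fill the gaps):
#' `reference_densities` — named map of size class to fresh-laid density
#' in g/mm^3; `rho_min_mean` — mean per-size minimum density in g/mm^3;
#' `size_classes` — list of `{class, label, low, high}` records in grams.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return A `grading_scheme`; see [derive_thresholds()].
#' @export
read_grading_config <- function(path) {
  cfg <- .read_structured(path)
  ref <- if (!is.null(cfg$reference_densities)) {
    unlist(cfg$reference_densities)
  } else default_reference_densities()
  rmin <- if (!is.null(cfg$rho_min_mean)) cfg$rho_min_mean else 983.41e-6
  sc <- if (is.data.frame(cfg$size_classes)) {
    cfg$size_classes[, c("class", "label", "low", "high")]
  } else if (!is.null(cfg$size_classes)) {
    do.call(rbind, lapply(cfg$size_classes, function(r)
      data.frame(class = as.integer(r$class), label = r$label,
                 low = r$low, high = r$high, stringsAsFactors = FALSE)))
  } else default_size_classes()
  derive_thresholds(unname(ref), rho_min_mean = rmin,
                    reference_densities = ref, size_classes = sc)
}

#' Write a grading scheme to a config file
#'
#' @param scheme A `grading_scheme`.
#' @param path Output path; format chosen by extension (`.json` else YAML).
#' @return `path`, invisibly.
#' @export
write_grading_config <- function(scheme, path) {
  stopifnot(inherits(scheme, "grading_scheme"))
  cfg <- list(
    reference_densities = as.list(scheme$reference_densities),
    rho_min_mean = scheme$rho_min_mean,
    size_classes = lapply(seq_len(nrow(scheme$size_classes)), function(i)
      as.list(scheme$size_classes[i, c("class", "label", "low", "high")]))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' Pixel-to-millimetre calibration profile
#'
#' A single isotropic scale factor linking image space to metric space,
#' normally obtained by photographing a reference object of known size
#' under the same rig geometry as the eggs.
#'
#' @param mm_per_px Millimetres per pixel, > 0.
#' @param source `"reference-object"` or `"manual"`.
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(mm_per_px, source = "manual") {
  .check_positive(mm_per_px, "mm_per_px")
  source <- match.arg(source, c("manual", "reference-object"))
  structure(list(mm_per_px = mm_per_px, source = source),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> %.6g mm/px (%s)\n", x$mm_per_px, x$source))
  invisible(x)
}

#' Derive a calibration profile from a reference object
#'
#' @param reference_diameter_mm True size of the reference object in mm.
#' @param reference_diameter_px Its measured extent in pixels.
#' @return A `calibration_profile` with
#'   `mm_per_px = reference_diameter_mm / reference_diameter_px`.
#' @examples
#' calibrate_scale(30, 100)$mm_per_px  # 0.3
#' @export
calibrate_scale <- function(reference_diameter_mm, reference_diameter_px) {
  .check_positive(reference_diameter_mm, "reference_diameter_mm")
  .check_positive(reference_diameter_px, "reference_diameter_px")
  calibration_profile(reference_diameter_mm / reference_diameter_px,
                      source = "reference-object")
}

#' Read / write a calibration profile
#'
#' Stored as a small JSON or YAML document `{mm_per_px, source}`.
#'
#' @param path File path; format chosen by extension.
#' @return For `read_calibration`, a `calibration_profile`.
#' @export
read_calibration <- function(path) {
  cfg <- .read_structured(path)
  if (is.null(cfg$mm_per_px)) stop("calibration file lacks `mm_per_px`",
                                   call. = FALSE)
  calibration_profile(cfg$mm_per_px,
                      source = if (is.null(cfg$source)) "manual" else cfg$source)
}

#' @rdname read_calibration
#' @param profile A `calibration_profile` to serialise.
#' @export
write_calibration <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  payload <- list(mm_per_px = profile$mm_per_px, source = profile$source)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path, precision = 15)
  }
  invisible(path)
}
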