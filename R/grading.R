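#' Size classification, freshness thresholds and band assignment
#'
#' Weight-based size classes (jumbo through small), derivation of the two
#' global density thresholds that split freshness into high/medium/low, and
#' the composite per-egg grading record.
#'
#' @name grading
NULL

#' Default weight-based size classes
#'
#' Commercial five-class scheme: class 0 jumbo (70--100 g), 1 extra-large
#' (65--69.99 g), 2 large (60--64.99 g), 3 medium (55--59.99 g), 4 small
#' (50--54.99 g). Intervals are closed at both printed two-decimal bounds.
#'
#' @return A data.frame with columns `class` (integer), `label`, `low`,
#'   `high` (grams).
#' @export
default_size_classes <- function() {
  data.frame(
    class = 0:4,
    label = c("jumbo", "extra-large", "large", "medium", "small"),
    low  = c(70, 65, 60, 55, 50),
    high = c(100, 69.99, 64.99, 59.99, 54.99),
    stringsAsFactors = FALSE
  )
}

#' Default per-size fresh-laid reference densities
#'
#' Mean density of each size class at highest freshness, in g/mm^3. These
#' are the denominators of the freshness percentage; override them with a
#' config file when calibrating to a different flock.
#'
#' @return Named numeric vector, names `"0"`..`"4"`.
#' @export
default_reference_densities <- function() {
  c(`0` = 1067.41e-6, `1` = 1090.00e-6, `2` = 1071.47e-6,
    `3` = 1072.50e-6, `4` = 1061.63e-6)
}

.validate_size_classes <- function(sc) {
  stopifnot(is.data.frame(sc),
            all(c("class", "label", "low", "high") %in% names(sc)))
  if (any(sc$low >= sc$high)) stop("size-class intervals must have low < high",
                                   call. = FALSE)
  o <- order(sc$low)
  if (any(sc$high[o][-nrow(sc)] >= sc$low[o][-1])) {
    stop("size-class intervals must be disjoint", call. = FALSE)
  }
  invisible(sc)
}

#' Classify an egg by weight
#'
#' Weights are rounded to 2 decimals (the precision of the interval bounds)
#' and matched against closed intervals. Weights falling outside every
#' interval return `NA` ("unclassified").
#'
#' @param weight Egg weight(s) in grams, > 0.
#' @param size_classes Interval table as from [default_size_classes()].
#' @return Integer vector of class numbers; `NA` where unclassified.
#' @examples
#' classify_size(76.60)  # 0 (jumbo)
#' classify_size(49.99)  # NA, below the smallest interval
#' @export
classify_size <- function(weight, size_classes = default_size_classes()) {
  .check_positive(weight, "weight")
  .validate_size_classes(size_classes)
  w <- round(weight, 2)
  vapply(w, function(wi) {
    hit <- which(size_classes$low <= wi & wi <= size_classes$high)
    if (length(hit) == 1L) as.integer(size_classes$class[hit]) else NA_integer_
  }, integer(1))
}

#' Derive the freshness density thresholds
#'
#' The density span observed over a full storage experiment — from the mean
#' of the per-size maximum (fresh-laid) densities down to the mean of the
#' per-size minimum densities — is split into three equal bands. The two
#' cut points `t_low` and `t_high` then grade any egg's density as low,
#' medium or high freshness.
#'
#' @param per_size_max_densities Per-size maximum (initial) densities,
#'   g/mm^3; their mean is the top of the span.
#' @param rho_min_mean Mean of the per-size minimum densities, g/mm^3;
#'   the bottom of the span.
#' @param reference_densities Optional named per-size reference densities
#'   carried along for freshness computation; defaults to
#'   `per_size_max_densities` named `"0"`, `"1"`, ... in order.
#' @param size_classes Size-class interval table carried into the scheme.
#' @return A list of class `grading_scheme` with fields `rho_max_mean`,
#'   `rho_min_mean`, `band_width`, `t_low`, `t_high`,
#'   `reference_densities`, `size_classes`.
#' @examples
#' sc <- derive_thresholds(
#'   c(1067.41e-6, 1090.00e-6, 1071.47e-6, 1072.50e-6, 1061.63e-6),
#'   rho_min_mean = 983.41e-6)
#' round(sc$t_low * 1e6, 2)   # 1013.14
#' round(sc$t_high * 1e6, 2)  # 1042.87
#' @export
derive_thresholds <- function(per_size_max_densities, rho_min_mean,
                              reference_densities = NULL,
                              size_classes = default_size_classes()) {
  .check_positive(per_size_max_densities, "per_size_max_densities")
  .check_positive(rho_min_mean, "rho_min_mean")
  rho_max_mean <- mean(per_size_max_densities)
  if (rho_min_mean >= rho_max_mean) {
    stop("degenerate scheme: `rho_min_mean` must be below the mean maximum density",
         call. = FALSE)
  }
  if (is.null(reference_densities)) {
    reference_densities <- per_size_max_densities
    names(reference_densities) <- as.character(seq_along(reference_densities) - 1L)
  }
  band_width <- (rho_max_mean - rho_min_mean) / 3
  structure(list(
    rho_max_mean = rho_max_mean,
    rho_min_mean = rho_min_mean,
    band_width = band_width,
    t_low = rho_min_mean + band_width,
    t_high = rho_min_mean + 2 * band_width,
    reference_densities = reference_densities,
    size_classes = size_classes
  ), class = "grading_scheme")
}

#' Built-in grading scheme
#'
#' The default scheme: per-size fresh-laid densities from
#' [default_reference_densities()] and a mean minimum density of
#' 983.41e-6 g/mm^3, giving thresholds 1013.14e-6 and 1042.87e-6.
#'
#' @return A `grading_scheme`; see [derive_thresholds()].
#' @export
default_grading_scheme <- function() {
  derive_thresholds(unname(default_reference_densities()),
                    rho_min_mean = 983.41e-6,
                    reference_densities = default_reference_densities())
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat(sprintf(paste0("<grading_scheme> span %.2f--%.2f x1e-6 g/mm^3, band %.2f\n",
                     "  low < %.2f <= medium <= %.2f < high\n"),
              x$rho_min_mean * 1e6, x$rho_max_mean * 1e6, x$band_width * 1e6,
              x$t_low * 1e6, x$t_high * 1e6))
  invisible(x)
}

#' Assign a freshness band to a density
#'
#' Strictly above `t_high` is high freshness, strictly below `t_low` is low;
#' the closed interval in between, boundaries included, is medium. As with
#' the weight intervals, the comparison happens at the thresholds' printed
#' precision (2 decimals on the x1e-6 g/mm^3 scale), so a density quoted
#' exactly at a published boundary lands in the medium band.
#'
#' @param rho Egg density (or densities) in g/mm^3, > 0.
#' @param scheme A `grading_scheme`.
#' @return Ordered factor with levels `low < medium < high`.
#' @examples
#' classify_freshness(1090.00e-6)  # high
#' classify_freshness(1013.14e-6)  # medium (boundary belongs to medium)
#' @export
classify_freshness <- function(rho, scheme = default_grading_scheme()) {
  .check_positive(rho, "rho")
  stopifnot(inherits(scheme, "grading_scheme"))
  r <- round(rho * 1e6, 2)
  t_low <- round(scheme$t_low * 1e6, 2)
  t_high <- round(scheme$t_high * 1e6, 2)
  band <- ifelse(r > t_high, "high", ifelse(r < t_low, "low", "medium"))
  factor(band, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Grade one egg
#'
#' Composes the whole chain for one egg: shape index, volume, density, size
#' class, freshness percentage against the size class's reference density,
#' and the freshness band. If the weight falls outside every size interval
#' there is no reference density, so the record carries `NA` freshness and a
#' warning is raised; the band (density-only) is still assigned.
#'
#' @param measurement An [egg_measurement()].
#' @param scheme A `grading_scheme`.
#' @return One-row data.frame with columns `weight`, `length`, `breadth`,
#'   `shape_index`, `volume`, `density`, `density_1e6`, `size_class`,
#'   `size_label`, `freshness`, `freshness_band`.
#' @examples
#' grade_egg(egg_measurement(70.60, 60.75, 45.60))
#' @export
grade_egg <- function(measurement, scheme = default_grading_scheme()) {
  stopifnot(inherits(measurement, "egg_measurement"),
            inherits(scheme, "grading_scheme"))
  mm <- morphometrics(measurement)
  cls <- classify_size(measurement$weight, scheme$size_classes)
  fresh <- NA_real_
  if (!is.na(cls) && as.character(cls) %in% names(scheme$reference_densities)) {
    fresh <- freshness_percent(mm$density,
                               scheme$reference_densities[[as.character(cls)]])
  } else {
    warning("weight outside all size classes: no reference density, freshness omitted",
            call. = FALSE)
  }
  lab <- if (is.na(cls)) NA_character_ else
    scheme$size_classes$label[match(cls, scheme$size_classes$class)]
  data.frame(
    weight = measurement$weight,
    length = measurement$length,
    breadth = measurement$breadth,
    shape_index = mm$shape_index,
    volume = mm$volume,
    density = mm$density,
    density_1e6 = mm$density * 1e6,
    size_class = cls,
    size_label = lab,
    freshness = fresh,
    freshness_band = as.character(classify_freshness(mm$density, scheme)),
    stringsAsFactors = FALSE
  )
}
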