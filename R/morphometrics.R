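#' Closed-form egg morphometrics
#'
#' The four scalar quantities at the core of density-based egg grading:
#' shape index, ellipsoid volume, density and freshness percentage. All are
#' vectorised and validate their inputs; rounding happens only when values
#' are printed, never inside a computation.
#'
#' @name morphometrics
NULL

.check_positive <- function(x, name) {
  if (length(x) == 0 || !is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("`%s` must be numeric and strictly positive", name),
         call. = FALSE)
  }
  invisible(x)
}

#' One egg's physical readings
#'
#' Bundles the three measured quantities grading needs: weight in grams,
#' length (long-axis extent) and breadth (maximum transverse extent) in
#' millimetres. Breadth may equal but never exceed length.
#'
#' @param weight Egg weight in grams.
#' @param length Long-axis extent L in mm.
#' @param breadth Maximum transverse extent B in mm; `breadth <= length`.
#' @return An object of class `egg_measurement`: a list with fields
#'   `weight`, `length`, `breadth`.
#' @examples
#' egg_measurement(weight = 70.60, length = 60.75, breadth = 45.60)
#' @export
egg_measurement <- function(weight, length, breadth) {
  .check_positive(weight, "weight")
  .check_positive(length, "length")
  .check_positive(breadth, "breadth")
  if (any(breadth > length)) {
    stop("`breadth` must not exceed `length`", call. = FALSE)
  }
  structure(list(weight = weight, length = length, breadth = breadth),
            class = "egg_measurement")
}

#' @export
print.egg_measurement <- function(x, ...) {
  cat(sprintf("<egg_measurement> weight %.2f g, L %.2f mm, B %.2f mm\n",
              x$weight, x$length, x$breadth))
  invisible(x)
}

#' Shape index of an egg
#'
#' The breadth-to-length ratio expressed as a percentage,
#' `SI = (B / L) * 100`. A sphere scores 100; typical chicken eggs fall
#' around 72--78. Scale-invariant: only the ratio of the two axes matters.
#'
#' @param length Long-axis extent in mm (or any unit shared with `breadth`).
#' @param breadth Maximum transverse extent, same unit; `breadth <= length`.
#' @return Shape index in percent, in (0, 100].
#' @examples
#' shape_index(60.75, 45.60)  # 75.06
#' shape_index(50, 50)        # spherical limit, 100
#' @export
shape_index <- function(length, breadth) {
  .check_positive(length, "length")
  .check_positive(breadth, "breadth")
  if (any(breadth > length)) {
    stop("`breadth` must not exceed `length`", call. = FALSE)
  }
  breadth / length * 100
}

#' Egg volume from its two principal axes
#'
#' Ellipsoid-of-revolution model `V = pi * L * B^2 / 6`, the standard
#' image-based estimator for egg volume: the egg is treated as a spheroid
#' with the long axis L and the transverse diameter B. For `L == B` this is
#' the sphere volume `pi d^3 / 6`.
#'
#' @param length Long-axis extent L in mm.
#' @param breadth Maximum transverse extent B in mm; `breadth <= length`.
#' @return Volume in cubic millimetres.
#' @examples
#' egg_volume(60.75, 45.60)  # 66141.58 mm^3
#' @export
egg_volume <- function(length, breadth) {
  .check_positive(length, "length")
  .check_positive(breadth, "breadth")
  if (any(breadth > length)) {
    stop("`breadth` must not exceed `length`", call. = FALSE)
  }
  pi * length * breadth^2 / 6
}

#' Egg density
#'
#' `rho = m / V` in g/mm^3. Densities of fresh eggs are of order 1e-3
#' g/mm^3; reports conventionally display them multiplied by 1e6.
#'
#' @param mass Mass in grams.
#' @param volume Volume in mm^3.
#' @return Density in g/mm^3.
#' @examples
#' egg_density(70.60, 66141.58) * 1e6  # 1067.41
#' @export
egg_density <- function(mass, volume) {
  .check_positive(mass, "mass")
  .check_positive(volume, "volume")
  mass / volume
}

#' Freshness percentage from density
#'
#' Freshness is the ratio of an egg's current density `rho_E` to the
#' reference fresh-laid (highest-freshness) density `rho_HE` of its size
#' class, times 100. A newly laid egg scores 100; as water evaporates
#' through the shell during storage, density and hence freshness drop.
#'
#' @param rho_E Current egg density, g/mm^3.
#' @param rho_HE Reference initial density of the egg's size class, g/mm^3.
#' @return Freshness in percent.
#' @examples
#' freshness_percent(1042.87e-6, 1072.60e-6)  # 97.23
#' @export
freshness_percent <- function(rho_E, rho_HE) {
  .check_positive(rho_E, "rho_E")
  .check_positive(rho_HE, "rho_HE")
  rho_E / rho_HE * 100
}

#' Derived morphometrics for one egg
#'
#' Convenience wrapper computing shape index, volume and density from an
#' [egg_measurement()], plus the freshness percentage when a reference
#' density is supplied.
#'
#' @param measurement An [egg_measurement()].
#' @param rho_HE Optional reference initial density (g/mm^3) for the
#'   freshness percentage; if `NULL`, freshness is left `NA`.
#' @return A list of class `egg_morphometrics` with fields `shape_index`
#'   (%), `volume` (mm^3), `density` (g/mm^3) and `freshness` (% or `NA`).
#' @examples
#' m <- egg_measurement(70.60, 60.75, 45.60)
#' morphometrics(m, rho_HE = 1067.41e-6)
#' @export
morphometrics <- function(measurement, rho_HE = NULL) {
  stopifnot(inherits(measurement, "egg_measurement"))
  v <- egg_volume(measurement$length, measurement$breadth)
  rho <- egg_density(measurement$weight, v)
  structure(list(
    shape_index = shape_index(measurement$length, measurement$breadth),
    volume = v,
    density = rho,
    freshness = if (is.null(rho_HE)) NA_real_ else freshness_percent(rho, rho_HE)
  ), class = "egg_morphometrics")
}

#' @export
print.egg_morphometrics <- function(x, ...) {
  cat(sprintf("<egg_morphometrics> SI %.2f %%, V %.2f mm^3, rho %.2f x1e-6 g/mm^3",
              x$shape_index, x$volume, x$density * 1e6))
  if (!is.na(x$freshness)) cat(sprintf(", freshness %.2f %%", x$freshness))
  cat("\n")
  invisible(x)
}
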