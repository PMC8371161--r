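#' Seeded synthetic data generators
#'
#' Two generators make every other module testable without hardware:
#' a renderer producing egg images with exact geometric ground truth, and
#' a storage-series generator producing linear weight-decay curves with
#' Gaussian noise. Both are deterministic given their seed.
#'
#' @name synthetic
NULL

# run `expr` under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic egg image
#'
#' Emulates a top-down photograph in a dark matte enclosure lit from
#' above: a bright convex egg-shaped blob on a dark uniform background,
#' with optional additive Gaussian noise and a linear illumination
#' gradient across the frame. Intensities are 8-bit gray levels (0--255);
#' a contrast floor of 50 levels between foreground and background keeps
#' the regime the segmentation is specified for.
#'
#' @param length_px Major-axis extent in pixels (tight, inclusive count).
#' @param breadth_px Maximal perpendicular extent in pixels;
#'   `breadth_px <= length_px`.
#' @param taper Asymmetry coefficient in [0, 0.3]; 0 is an ellipse,
#'   larger values narrow one end (the "pointy" pole of a hen egg is
#'   around 0.1--0.2).
#' @param orientation Major-axis angle in degrees.
#' @param fg,bg Foreground / background gray levels in [0, 255] with
#'   `fg - bg >= 50`.
#' @param noise_sigma Additive Gaussian noise SD in gray levels.
#' @param illumination_gradient Total left-to-right intensity ramp across
#'   the frame, gray levels.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param margin Blank border around the egg's circumscribing box, pixels.
#' @return A list of class `synthetic_egg_spec`.
#' @export
synthetic_egg_spec <- function(length_px, breadth_px, taper = 0,
                               orientation = 0, fg = 200, bg = 40,
                               noise_sigma = 0, illumination_gradient = 0,
                               seed = 1L, margin = 16) {
  .check_positive(length_px, "length_px")
  .check_positive(breadth_px, "breadth_px")
  if (breadth_px > length_px) stop("`breadth_px` must not exceed `length_px`",
                                   call. = FALSE)
  if (length_px < 5) stop("`length_px` must be at least 5 px", call. = FALSE)
  if (taper < 0 || taper > 0.3) stop("`taper` must lie in [0, 0.3]",
                                     call. = FALSE)
  if (fg < 0 || fg > 255 || bg < 0 || bg > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (fg - bg < 50) stop("contrast floor violated: need fg - bg >= 50",
                         call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  structure(list(length_px = as.integer(round(length_px)),
                 breadth_px = as.integer(round(breadth_px)),
                 taper = taper, orientation = orientation,
                 fg = fg, bg = bg, noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed), margin = as.integer(margin)),
            class = "synthetic_egg_spec")
}

# half-breadth profile of the egg outline, relative units: u in [-1, 1]
# along the major axis -> half-width before breadth renormalisation
.egg_profile <- function(u, taper) {
  sqrt(pmax(0, 1 - u^2)) * (1 + taper * u)
}

#' Render a synthetic egg image
#'
#' The outline is a tapered ellipse whose half-breadth profile is
#' renormalised so the maximal perpendicular extent is exactly
#' `breadth_px`. At orientations that are multiples of 180 degrees the
#' pixel membership test is discretised on the pixel grid (with parity
#' offsets and a tip fill) so that the brute-force tight extents of the
#' noiseless mask equal `length_px` x `breadth_px` exactly; at other
#' orientations the continuous outline is sampled at pixel centres and
#' extents are exact to within about one pixel. The illumination gradient
#' and Gaussian noise are added after rasterisation and the result is
#' clipped to [0, 255] (stored as [0, 1]).
#'
#' @param spec A [synthetic_egg_spec()].
#' @return A list of class `synthetic_egg`: `raster` (matrix in [0, 1]),
#'   `mask` (noiseless ground-truth logical matrix), and `truth` with
#'   `length_px`, `breadth_px`, `orientation`, `area`, `centroid`, `seed`.
#'   Identical specs (same seed) give bit-identical rasters.
#' @examples
#' egg <- render_egg(synthetic_egg_spec(200, 150, seed = 7))
#' egg$truth$length_px
#' @export
render_egg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_egg_spec"))
  L <- spec$length_px; B <- spec$breadth_px
  side <- ceiling(sqrt(L^2 + B^2)) + 2 * spec$margin
  c0 <- floor((side - 1) / 2)
  a <- (L - 1) / 2
  bh <- (B - 1) / 2
  th <- (spec$orientation %% 360) * pi / 180
  cols <- matrix(rep(0:(side - 1), each = side), side, side)   # x
  rows <- matrix(rep(0:(side - 1), times = side), side, side)  # y

  if (spec$orientation %% 180 == 0) {
    flip <- if (spec$orientation %% 360 == 180) -1 else 1
    cx <- c0 + if (L %% 2 == 0) 0.5 else 0
    cy <- c0 + if (B %% 2 == 0) 0.5 else 0
    xs <- flip * (cols - cx)
    ys <- flip * (rows - cy)
    # per-column half-widths, renormalised over the discrete x grid so the
    # maximal extent is attained at a pixel row
    ugrid <- (seq_len(L) - 1 - a) / a
    fac <- .egg_profile(ugrid, spec$taper)
    bscale <- bh / max(fac)
    minabs_y <- if (B %% 2 == 0) 0.5 else 0
    hw <- pmax(bscale * .egg_profile(xs / a, spec$taper), minabs_y)
    mask <- abs(xs) <= a + 1e-9 & abs(ys) <= hw + 1e-9
  } else {
    dx <- cols - c0; dy <- rows - c0
    xs <- cos(th) * dx + sin(th) * dy
    ys <- -sin(th) * dx + cos(th) * dy
    maxfac <- stats::optimize(function(u) .egg_profile(u, spec$taper),
                              c(-1, 1), maximum = TRUE)$objective
    bscale <- bh / maxfac
    inside <- abs(xs) <= a
    mask <- inside & abs(ys) <= bscale * .egg_profile(xs / a, spec$taper)
  }

  img <- matrix(spec$bg, side, side)
  img[mask] <- spec$fg
  if (spec$illumination_gradient != 0) {
    ramp <- spec$illumination_gradient * (cols / (side - 1) - 0.5)
    img <- img + ramp
  }
  if (spec$noise_sigma > 0) {
    img <- img + .with_seed(spec$seed,
                            matrix(stats::rnorm(side^2, 0, spec$noise_sigma),
                                   side, side))
  }
  img <- pmin(pmax(img, 0), 255) / 255

  idx <- which(mask, arr.ind = TRUE)
  structure(list(
    raster = img,
    mask = mask,
    truth = list(length_px = L, breadth_px = B,
                 orientation = spec$orientation %% 180,
                 area = sum(mask),
                 centroid = c(row = mean(idx[, 1] - 1), col = mean(idx[, 2] - 1)),
                 seed = spec$seed),
    spec = spec
  ), class = "synthetic_egg")
}

#' Specification of a storage-time weight series
#'
#' Eggs stored at room temperature lose water through shell pores, so the
#' weight normalised to its day-0 value decays linearly with storage day.
#' The generator draws
#' `normalized_weight(x) = intercept + slope_per_day * x + eps`,
#' `eps ~ N(0, noise_sigma^2)` independently per day (day 0 included), and
#' `weight = initial_weight * normalized_weight`.
#'
#' @param initial_weight Day-0 weight in grams.
#' @param slope_per_day Decay slope in normalised units per day (negative
#'   for real eggs; around -0.0023 to -0.0031).
#' @param days Number of storage days; the series covers days 0..days.
#' @param noise_sigma Per-day Gaussian noise SD, normalised units.
#' @param intercept Intercept of the decay line (1 for exact day-0
#'   normalisation; fitted decay models report values near 1.003).
#' @param seed Integer RNG seed.
#' @return A list of class `storage_series_spec`.
#' @export
storage_series_spec <- function(initial_weight, slope_per_day, days,
                                noise_sigma = 0, intercept = 1, seed = 1L) {
  .check_positive(initial_weight, "initial_weight")
  if (days < 1) stop("`days` must be at least 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  structure(list(initial_weight = initial_weight,
                 slope_per_day = slope_per_day,
                 days = as.integer(days), noise_sigma = noise_sigma,
                 intercept = intercept, seed = as.integer(seed)),
            class = "storage_series_spec")
}

#' Generate a storage-time weight series
#'
#' @param spec A [storage_series_spec()].
#' @return A data.frame with columns `day` (0..days), `weight` (g) and
#'   `normalized_weight`. With `noise_sigma = 0` the series is exactly
#'   affine in day.
#' @examples
#' # the average decay model evaluated noiselessly at day 30
#' s <- storage_series_spec(60, -0.0028, days = 30, intercept = 1.0030)
#' generate_storage_series(s)$normalized_weight[31]  # 0.919
#' @export
generate_storage_series <- function(spec) {
  stopifnot(inherits(spec, "storage_series_spec"))
  day <- 0:spec$days
  eps <- if (spec$noise_sigma > 0) {
    .with_seed(spec$seed, stats::rnorm(length(day), 0, spec$noise_sigma))
  } else rep(0, length(day))
  norm <- spec$intercept + spec$slope_per_day * day + eps
  data.frame(day = day,
             weight = spec$initial_weight * norm,
             normalized_weight = norm)
}

#' Write a batch of synthetic eggs to disk
#'
#' Renders `n` seeded eggs spanning a realistic size range, writes each as
#' a PNG and collects the ground truth in a CSV (`file, length_px,
#' breadth_px, orientation, area, seed`).
#'
#' @param n Number of eggs.
#' @param out_dir Output directory (created if missing).
#' @param seed Base seed; egg i uses `seed + i`.
#' @param length_range,breadth_range Pixel ranges sampled uniformly; the
#'   defaults correspond to hen-egg axes of 50--65 mm by 40--48 mm at a
#'   0.15 mm/px calibration.
#' @param noise_sigma,taper,illumination_gradient Passed to each spec;
#'   orientation is drawn uniformly in [0, 180).
#' @return Invisibly, the ground-truth data.frame (also written to
#'   `ground_truth.csv` in `out_dir`).
#' @export
write_synthetic_eggs <- function(n, out_dir, seed = 1L,
                                 length_range = c(333, 433),
                                 breadth_range = c(267, 320),
                                 noise_sigma = 10, taper = 0.15,
                                 illumination_gradient = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- .with_seed(seed, data.frame(
    L = round(stats::runif(n, length_range[1], length_range[2])),
    B = round(stats::runif(n, breadth_range[1], breadth_range[2])),
    ang = stats::runif(n, 0, 180)))
  draws$B <- pmin(draws$B, draws$L)
  rows <- lapply(seq_len(n), function(i) {
    sp <- synthetic_egg_spec(draws$L[i], draws$B[i], taper = taper,
                             orientation = draws$ang[i],
                             noise_sigma = noise_sigma,
                             illumination_gradient = illumination_gradient,
                             seed = seed + i)
    egg <- render_egg(sp)
    file <- file.path(out_dir, sprintf("egg_%03d.png", i))
    EBImage::writeImage(EBImage::Image(egg$raster), file)
    data.frame(file = file, length_px = egg$truth$length_px,
               breadth_px = egg$truth$breadth_px,
               orientation = egg$truth$orientation,
               area = egg$truth$area, seed = sp$seed,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}
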