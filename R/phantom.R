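# Synthetic longitudinal carotid-ultrasound phantom with exact ground
# truth. The scene is a dark lumen band following a (possibly sloped and
# curved) centerline, bounded by two bright wall bands over a mid-gray
# tissue background; degradations are multiplicative gamma speckle
# (fully-developed-speckle intensity model, unit mean, variance 1/looks),
# a smooth multiplicative intensity-inhomogeneity field, and optional
# wall gaps (echo dropout) that break the boundary.

#' Phantom specification
#'
#' Geometry, gray levels and degradation parameters of one synthetic
#' longitudinal B-mode frame. The lumen band is
#' `|row - centerline(col)| <= lumen_half_thickness` with
#' `centerline(col) = lumen_center_row + slope*(col - (width+1)/2) +
#' curvature_amp * sin(2*pi*col/curvature_period)`; each wall is a
#' `wall_px`-thick bright band hugging the lumen.
#'
#' @param height,width image size (px).
#' @param lumen_center_row centerline row at the image center.
#' @param lumen_half_thickness vertical half-thickness of the lumen (px);
#'   must satisfy `2*lumen_half_thickness < height/2`.
#' @param slope centerline slope (rows per column).
#' @param curvature_amp,curvature_period sinusoidal centerline bend
#'   (amplitude px, period px).
#' @param lumen_intensity,wall_intensity,tissue_intensity mean gray levels
#'   (0-255); the lumen must be darker than the walls.
#' @param wall_px wall band thickness (px).
#' @param speckle_looks gamma-speckle shape (number of looks); lower is
#'   noisier, `>= 1`. Values `>= 1e6` are treated as noise-free.
#' @param inhomogeneity_amp amplitude of the smooth multiplicative
#'   low-frequency field (0 disables it).
#' @param gap_columns list of `c(start, length)` column spans where the
#'   wall intensity is zeroed (boundary discontinuities).
#' @param seed RNG seed for the noise draws.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 160L, width = 240L,
                         lumen_center_row = height / 2,
                         lumen_half_thickness = 24,
                         slope = 0, curvature_amp = 0,
                         curvature_period = width,
                         lumen_intensity = 30, wall_intensity = 200,
                         tissue_intensity = 110, wall_px = 6L,
                         speckle_looks = 4, inhomogeneity_amp = 0.2,
                         gap_columns = list(), seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               lumen_center_row = lumen_center_row,
               lumen_half_thickness = lumen_half_thickness,
               slope = slope, curvature_amp = curvature_amp,
               curvature_period = curvature_period,
               lumen_intensity = lumen_intensity,
               wall_intensity = wall_intensity,
               tissue_intensity = tissue_intensity,
               wall_px = as.integer(wall_px),
               speckle_looks = speckle_looks,
               inhomogeneity_amp = inhomogeneity_amp,
               gap_columns = gap_columns, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$lumen_intensity >= s$wall_intensity)
    stop("phantom spec: lumen must be darker than the walls", call. = FALSE)
  if (2 * s$lumen_half_thickness >= s$height / 2)
    stop("phantom spec: lumen too thick for the image height", call. = FALSE)
  if (s$speckle_looks < 1)
    stop("phantom spec: speckle_looks must be >= 1", call. = FALSE)
  cl <- phantom_centerline(s)
  lo <- min(cl) - s$lumen_half_thickness - s$wall_px
  hi <- max(cl) + s$lumen_half_thickness + s$wall_px
  if (lo < 1 || hi > s$height)
    stop("phantom spec: lumen/walls leave the image", call. = FALSE)
  invisible(s)
}

phantom_centerline <- function(s) {
  cc <- seq_len(s$width)
  s$lumen_center_row + s$slope * (cc - (s$width + 1) / 2) +
    s$curvature_amp * sin(2 * pi * cc / s$curvature_period)
}

# smooth multiplicative field: bilinear upsampling of a coarse uniform grid
inhomogeneity_field <- function(nr, nc, amp, coarse = c(4L, 6L)) {
  if (amp <= 0) return(matrix(1, nr, nc))
  gr <- matrix(stats::runif(prod(coarse), -1, 1), coarse[1], coarse[2])
  ry <- seq(1, coarse[1], length.out = nr)
  rx <- seq(1, coarse[2], length.out = nc)
  y0 <- pmin(floor(ry), coarse[1] - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), coarse[2] - 1L); fx <- rx - x0
  a <- gr[cbind(rep(y0, nc), rep(x0, each = nr))]
  b <- gr[cbind(rep(y0 + 1, nc), rep(x0, each = nr))]
  c_ <- gr[cbind(rep(y0, nc), rep(x0 + 1, each = nr))]
  d <- gr[cbind(rep(y0 + 1, nc), rep(x0 + 1, each = nr))]
  fyv <- rep(fy, nc); fxv <- rep(fx, each = nr)
  v <- a * (1 - fyv) * (1 - fxv) + b * fyv * (1 - fxv) +
    c_ * (1 - fyv) * fxv + d * fyv * fxv
  matrix(1 + amp * v, nr, nc)
}

# unit-mean gamma speckle factor, variance 1/looks
speckle_field <- function(nr, nc, looks) {
  if (looks >= 1e6) return(matrix(1, nr, nc))
  matrix(stats::rgamma(nr * nc, shape = looks, rate = looks), nr, nc)
}

#' Generate one phantom sample
#'
#' Builds the noiseless scene, zeroes the wall intensity over the gap
#' columns, applies the smooth inhomogeneity field and multiplicative
#' speckle, and clips to `[0, 255]`. The ground-truth mask is the noiseless
#' lumen band, so it is exact and independent of the noise realization.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_sample`: list with `image` (numeric
#'   matrix), `truth` (logical lumen mask) and `spec`.
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  nr <- spec$height; nc <- spec$width
  cl <- phantom_centerline(spec)
  rows <- matrix(seq_len(nr), nr, nc)
  ctr <- matrix(cl, nr, nc, byrow = TRUE)
  vd <- abs(rows - ctr)
  lumen <- vd <= spec$lumen_half_thickness
  wall <- vd > spec$lumen_half_thickness &
    vd <= spec$lumen_half_thickness + spec$wall_px
  scene <- matrix(spec$tissue_intensity, nr, nc)
  scene[wall] <- spec$wall_intensity
  scene[lumen] <- spec$lumen_intensity
  for (gap in spec$gap_columns) {
    gcols <- seq(gap[1], length.out = gap[2])
    gcols <- gcols[gcols >= 1 & gcols <= nc]
    gm <- wall & col(wall) %in% gcols
    scene[gm] <- 0
  }
  img <- with_seed(spec$seed, {
    inh <- inhomogeneity_field(nr, nc, spec$inhomogeneity_amp)
    spk <- speckle_field(nr, nc, spec$speckle_looks)
    scene * inh * spk
  })
  img <- pmin(pmax(img, 0), 255)
  structure(list(image = img, truth = lumen, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<phantom_sample %dx%d: half-thickness %.1f px, slope %.2f, looks %g, %d gap(s), seed %d>\n",
    s$height, s$width, s$lumen_half_thickness, s$slope, s$speckle_looks,
    length(s$gap_columns), s$seed))
  invisible(x)
}

#' Randomized phantom suite at a fixed degradation level
#'
#' `n` phantoms with randomized geometry (vertical lumen thickness 15-41
#' px, slope in ±0.3, sinusoidal curvature on or off, random centerline
#' row) at one of three noise presets: `clean` (noise-free, no gaps),
#' `moderate` (4-look speckle, inhomogeneity 0.2, one 10-px wall gap),
#' `severe` (1-look speckle, inhomogeneity 0.4, two 15-px wall gaps).
#' Reproducible: the suite is a pure function of `seed`.
#'
#' @param n number of samples.
#' @param level `"clean"`, `"moderate"` or `"severe"`.
#' @param seed suite seed.
#' @param height,width image size of every sample.
#' @return list of `phantom_sample` objects.
#' @export
degradation_suite <- function(n, level = c("clean", "moderate", "severe"),
                              seed = 1L, height = 128L, width = 192L) {
  level <- match.arg(level)
  stopifnot(n >= 1)
  preset <- switch(level,
    clean    = list(looks = 1e6, inhom = 0,   gaps = 0L, gap_len = 0L),
    moderate = list(looks = 4,   inhom = 0.2, gaps = 1L, gap_len = 10L),
    severe   = list(looks = 1,   inhom = 0.4, gaps = 2L, gap_len = 15L))
  wall_px <- 6L
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      # geometry ranges are clipped so lumen + walls always fit the frame
      ht <- stats::runif(1, 7, min(20, (height - 30) / 4))
      curved <- stats::runif(1) < 0.5
      amp <- if (curved) stats::runif(1, 2, min(6, height / 16)) else 0
      period <- stats::runif(1, width / 2, width)
      slope_max <- min(0.3, (height / 2 - ht - wall_px - amp - 4) /
                              (width / 2))
      slope <- stats::runif(1, -slope_max, slope_max)
      margin <- ht + wall_px + amp + abs(slope) * (width / 2) + 2
      center <- stats::runif(1, margin + 1, height - margin)
      gaps <- if (preset$gaps > 0)
        lapply(seq_len(preset$gaps), function(j)
          c(floor(stats::runif(1, width * 0.2, width * 0.8 - preset$gap_len)),
            preset$gap_len))
      else list()
      list(ht = ht, slope = slope, amp = amp, period = period,
           center = center, gaps = gaps,
           seed = sample.int(.Machine$integer.max - 1L, 1))
    })
  })
  lapply(draws, function(d)
    phantom_generate(phantom_spec(
      height = height, width = width,
      lumen_center_row = d$center, lumen_half_thickness = d$ht,
      slope = d$slope, curvature_amp = d$amp, curvature_period = d$period,
      speckle_looks = preset$looks, inhomogeneity_amp = preset$inhom,
      gap_columns = d$gaps, seed = d$seed)))
}
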