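# Fully automatic shape-prior generation and contour initialization.
#
# Pipeline on a raw longitudinal B-mode frame:
#   Otsu rough segmentation -> largest 8-connected component (the lumen)
#   -> morphological wall extraction (diagnostic)
#   -> erosion by a disk (radius 20, with fallbacks) = initial-contour core
#   -> per-column centerline + narrowest wall-to-wall radius
#   -> prior band around the centerline, phi0 = its signed distance.
# Entirely deterministic: no RNG anywhere in this file.

#' Otsu rough segmentation of the dark lumen
#'
#' Global threshold maximizing the between-class variance over a 256-bin
#' histogram of the (0-255) intensities; returns the below-threshold class,
#' since blood is hypoechoic (dark) in B-mode. Set `dark = FALSE` to return
#' the bright class instead.
#'
#' @param img numeric intensity matrix with at least two distinct values.
#' @param dark return the below-threshold (dark) class.
#' @return logical mask; the chosen threshold (bin upper edge) is attached
#'   as `attr(, "threshold")`.
#' @export
otsu_mask <- function(img, dark = TRUE) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (length(unique(as.vector(img))) < 2L)
    stop("degenerate input: constant image has no Otsu threshold",
         call. = FALSE)
  bins <- pmin(pmax(floor(as.vector(img)), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  mids <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[256L]
  # between-class variance for thresholds t = 0..254 (class0 = bins <= t)
  w0t <- w0[1:255]; m0t <- m0[1:255]
  valid <- w0t > 0 & w0t < 1
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mt * w0t[valid] - m0t[valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  t_star <- which.max(bcv) - 1L
  mask <- matrix(bins <= t_star, nrow(img), ncol(img))
  if (!dark) mask <- !mask
  structure(mask, threshold = t_star)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find over the label graph
label_components8 <- function(mask) {
  mask <- as_mask(mask)
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  dim(lab) <- dim(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]        # down-right diagonal
  pairs1 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]        # up-right diagonal
  pairs2 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
  pairs <- unique(rbind(pairs1, pairs2))
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Largest 8-connected component of a mask
#'
#' Keeps only the component with the greatest pixel count; size ties are
#' broken by the component containing the earliest pixel in row-major scan
#' order.
#'
#' @param mask non-empty logical matrix.
#' @return logical mask with exactly one 8-connected component.
#' @export
largest_component <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("degenerate input: empty mask", call. = FALSE)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # row-major order: scan row 1 left to right, then row 2, ...
    ord <- order(row(lab)[lab > 0], col(lab)[lab > 0])
    labs_in_order <- lab[lab > 0][ord]
    best <- labs_in_order[labs_in_order %in% best][1]
  }
  lab == best
}

# closing (disk radius 3) + hole filling; shared by wall and init stages
fill_lumen <- function(lumen, close_radius = 3) {
  lumen <- as_mask(lumen)
  k <- disk_kernel(close_radius)
  closed <- erode_mask(dilate_mask(lumen, k), k)
  as_mask(as.matrix(EBImage::fillHull(closed * 1)) > 0.5)
}

#' Rough lumen-wall contour
#'
#' Morphological closing (disk radius 3) and hole filling of the lumen
#' component, followed by boundary extraction (mask minus its erosion by a
#' 3x3 cross): a 1-2 px contour tracing the lumen wall.
#'
#' @param lumen logical lumen-component mask (at least 20 px).
#' @param close_radius disk radius of the closing.
#' @return logical wall-contour mask.
#' @export
rough_wall <- function(lumen, close_radius = 3) {
  lumen <- as_mask(lumen)
  if (sum(lumen) < 20L)
    stop("degenerate lumen (< 20 px): check ROI crop and image quality",
         call. = FALSE)
  filled <- fill_lumen(lumen, close_radius)
  mask_boundary(filled)
}

#' Initial-contour mask by disk erosion of the lumen
#'
#' Erodes the closed, hole-filled lumen mask by a disk structuring element
#' of radius 20 px so the initial contour lies strictly inside the lumen
#' (the balloon force `alpha < 0` then unfolds it outward). If fewer than
#' `min_px` pixels survive, fallback radii 15, 10, 5 are tried in order;
#' if even radius 5 fails an initialization error is raised. The result is
#' intersected with the lumen component so containment in the rough
#' segmentation holds by construction.
#'
#' @param lumen logical lumen-component mask.
#' @param radius primary erosion radius (px).
#' @param fallbacks decreasing fallback radii.
#' @param min_px minimum surviving pixel count.
#' @return logical mask with `attr(, "radius")` recording the radius used.
#' @export
initial_contour_mask <- function(lumen, radius = 20,
                                 fallbacks = c(15, 10, 5), min_px = 100L) {
  lumen <- as_mask(lumen)
  filled <- fill_lumen(lumen)
  for (r in c(radius, fallbacks)) {
    er <- erode_mask(filled, disk_kernel(r)) & lumen
    if (sum(er) >= min_px) return(structure(er, radius = r))
  }
  stop(sprintf(
    "initialization failed: lumen too thin for erosion even at radius %g",
    min(fallbacks)), call. = FALSE)
}

#' Approximate lumen centerline
#'
#' For every image column intersecting the lumen, takes the midpoint of the
#' longest vertical run of lumen pixels, then smooths the row profile with
#' a centered moving average (window 15 columns, shrinking at the ends).
#' Rows are clamped back into the column's run so every centerline point
#' lies inside the lumen.
#'
#' @param lumen logical lumen-component mask spanning at least 30 columns.
#' @param window moving-average window (columns).
#' @return data.frame of class `centerline` with integer columns `row`,
#'   `col` (strictly increasing `col`) and the per-column run extent
#'   (`run_top`, `run_bottom`, `run_len`).
#' @export
estimate_centerline <- function(lumen, window = 15L) {
  lumen <- as_mask(lumen)
  cols <- which(colSums(lumen) > 0)
  if (length(cols) < 30L)
    stop("lumen spans fewer than 30 columns; not a longitudinal section?",
         call. = FALSE)
  runs <- vapply(cols, function(cc) {
    r <- rle(lumen[, cc])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    best <- keep[which.max(r$lengths[keep])]  # first longest run
    c(starts[best], ends[best])
  }, numeric(2))
  mid <- (runs[1, ] + runs[2, ]) / 2
  # centered moving average with shrinking window at the ends
  half <- (as.integer(window) - 1L) %/% 2L
  n <- length(mid)
  smoothed <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(mid[j])
  }, numeric(1))
  row_out <- as.integer(round(pmin(pmax(smoothed, runs[1, ]), runs[2, ])))
  structure(
    data.frame(row = row_out, col = as.integer(cols),
               run_top = as.integer(runs[1, ]),
               run_bottom = as.integer(runs[2, ]),
               run_len = as.integer(runs[2, ] - runs[1, ] + 1L)),
    class = c("centerline", "data.frame"))
}

#' Narrowest wall-to-wall half-distance of the lumen
#'
#' Half of the minimum per-column vertical run length of the lumen over the
#' central 90% of the columns the centerline spans (the ends are excluded
#' to avoid end effects from the rough segmentation).
#'
#' @param lumen logical lumen-component mask.
#' @param cl a `centerline` from [estimate_centerline()].
#' @param central_frac fraction of central columns used.
#' @return positive scalar radius in pixels.
#' @export
narrowest_radius <- function(lumen, cl, central_frac = 0.9) {
  stopifnot(inherits(cl, "centerline"), central_frac > 0, central_frac <= 1)
  n <- nrow(cl)
  drop_each <- floor(n * (1 - central_frac) / 2)
  idx <- (1 + drop_each):(n - drop_each)
  radius <- min(cl$run_len[idx]) / 2
  if (radius <= 0) stop("narrowest radius is not positive", call. = FALSE)
  radius
}

#' Adaptive band-shaped prior around the centerline
#'
#' The prior region is the set of pixels whose vertical distance to the
#' centerline row at their column is at most `radius`, over the columns the
#' centerline spans. Because the band follows the estimated centerline it
#' adapts to the vessel's slope and curvature; because it uses the
#' narrowest radius it deliberately under-estimates the lumen, acting as a
#' conservative anchor for the evolving contour.
#'
#' @param cl a `centerline`.
#' @param radius half-thickness of the band (px, `>= 2`).
#' @param dim integer `c(nrow, ncol)` of the target grid (or a matrix whose
#'   `dim` is used).
#' @return list with `band` (logical mask) and `phi0` (its signed distance,
#'   see [signed_distance()]).
#' @export
build_shape_prior <- function(cl, radius, dim) {
  stopifnot(inherits(cl, "centerline"))
  if (radius < 2) stop("prior too thin: radius must be >= 2 px", call. = FALSE)
  if (is.matrix(dim)) dim <- base::dim(dim)
  nr <- dim[1]; nc <- dim[2]
  band <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nrow(cl))
  ctr  <- matrix(cl$row, nr, nrow(cl), byrow = TRUE)
  band[, cl$col] <- abs(rows - ctr) <= radius
  list(band = band, phi0 = signed_distance(band))
}

#' Fully automatic initialization and shape prior from a raw image
#'
#' Chains the whole pipeline: Otsu rough segmentation, largest 8-connected
#' component, wall extraction (kept for diagnostics), disk erosion of the
#' lumen for the initial-contour core, centerline and narrowest radius for
#' the prior band. The initial region is the union of the eroded-lumen core
#' and the prior band (so initialization and prior always overlap), clipped
#' 2 px inside the image border; `phi_init` is its binary step
#' ([binary_step_initial()]) and `phi0` the prior band's signed distance.
#' Any stage failure is re-raised with the stage name prefixed.
#'
#' The step height defaults to `c0 = 6` here (not the generic 2): the
#' distance regularizer rebuilds a slope-1 ramp only up to `|phi| = c0`,
#' so a plateau at 6 keeps the far field well outside the `|phi| < 3`
#' near-contour band in which the level-set field is expected to be
#' distance-like.
#'
#' The rough segmentation stages threshold a Gaussian-smoothed copy of the
#' image (`smooth_sigma`, default 1.5 px): under raw multiplicative
#' speckle a global threshold on unsmoothed intensities lumps dark tissue
#' speckle into the lumen class. The evolution itself always runs on the
#' original intensities.
#'
#' @param img numeric intensity matrix (0-255).
#' @param dark lumen polarity flag, see [otsu_mask()].
#' @param erosion_radius primary erosion radius for the contour core.
#' @param window centerline smoothing window.
#' @param c0 binary-step height for `phi_init`.
#' @param smooth_sigma Gaussian sigma for the rough-segmentation stage
#'   (0 disables pre-smoothing).
#' @return list with `phi_init`, `phi0`, `band`, `init_mask`, `wall`, and a
#'   `report` list of intermediate areas and the radii used.
#' @export
auto_initialize <- function(img, dark = TRUE, erosion_radius = 20,
                            window = 15L, c0 = 6, smooth_sigma = 1.5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  stopifnot(is.matrix(img), nrow(img) >= 8, ncol(img) >= 8)
  img_s <- if (smooth_sigma > 0) gauss_smooth(img, smooth_sigma) else img
  rough  <- stage("otsu", otsu_mask(img_s, dark = dark))
  lumen  <- stage("largest_component", largest_component(rough))
  wall   <- stage("rough_wall", rough_wall(lumen))
  core   <- stage("initial_contour", initial_contour_mask(lumen, erosion_radius))
  cl     <- stage("centerline", estimate_centerline(lumen, window))
  radius <- stage("narrowest_radius", narrowest_radius(lumen, cl))
  prior  <- stage("shape_prior", build_shape_prior(cl, radius, dim(img)))
  init_mask <- core | prior$band
  # keep the zero level set >= 2 px inside the border
  init_mask[c(1L, 2L, nrow(img) - 1L, nrow(img)), ] <- FALSE
  init_mask[, c(1L, 2L, ncol(img) - 1L, ncol(img))] <- FALSE
  if (!any(init_mask))
    stop("[combine] empty initialization after border clipping", call. = FALSE)
  list(
    phi_init = binary_step_initial(init_mask, c0),
    phi0 = prior$phi0,
    band = prior$band,
    init_mask = init_mask,
    wall = wall,
    report = list(
      otsu_threshold = attr(rough, "threshold"),
      otsu_area = sum(rough),
      lumen_area = sum(lumen),
      erosion_radius = attr(core, "radius"),
      core_area = sum(core),
      n_centerline_cols = nrow(cl),
      narrowest_radius = radius,
      band_area = sum(prior$band),
      init_area = sum(init_mask)
    )
  )
}
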