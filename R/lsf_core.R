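#' Smoothed Heaviside function
#'
#' Mollified unit step used to confine level-set forces to a band of width
#' `2*eps` around the zero level set. Equals 0 below `-eps`, 1 above `eps`,
#' and `(1/2)(1 + x/eps + sin(pi*x/eps)/pi)` inside the transition band.
#' Its exact derivative is [smoothed_dirac()].
#'
#' @param x numeric scalar, vector or matrix (level-set values, pixels).
#' @param eps transition half-width (pixels), `> 0`.
#' @return object shaped like `x` with values in `[0, 1]`.
#' @seealso [smoothed_dirac()]
#' @export
smoothed_heaviside <- function(x, eps = 1.5) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive scalar", call. = FALSE)
  out <- 0.5 * (1 + x / eps + sin(pi * x / eps) / pi)
  out[x >  eps] <- 1
  out[x < -eps] <- 0
  out
}

#' Smoothed Dirac delta
#'
#' Derivative of [smoothed_heaviside()]: `(1/(2*eps))(1 + cos(pi*x/eps))` for
#' `|x| <= eps`, zero outside. Nonnegative, even, and integrates to 1.
#'
#' @inheritParams smoothed_heaviside
#' @return object shaped like `x`, nonnegative.
#' @export
smoothed_dirac <- function(x, eps = 1.5) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive scalar", call. = FALSE)
  out <- (1 + cos(pi * x / eps)) / (2 * eps)
  out[abs(x) > eps] <- 0
  out
}

#' Double-well potential for distance regularization
#'
#' Potential `p(s)` on the gradient magnitude `s = |grad phi|` with minima at
#' `s = 0` and `s = 1`: the level-set field is driven either toward a flat
#' field or toward the signed-distance property `|grad phi| = 1`, which is
#' what makes re-initialization unnecessary in DRLSE.
#'
#' @param s nonnegative gradient magnitudes (negative values are clamped to
#'   their absolute value).
#' @return values `>= 0`, zero exactly at `s` in `{0, 1}`.
#' @export
double_well <- function(s) {
  s <- abs(s)
  out <- ifelse(s <= 1,
                (1 - cos(2 * pi * s)) / (2 * pi)^2,
                0.5 * (s - 1)^2)
  out
}

#' Ratio p'(s)/s of the double-well potential
#'
#' The diffusion-rate factor of the distance-regularization term:
#' `sin(2*pi*s)/(2*pi*s)` on `(0, 1]`, `(s-1)/s` for `s >= 1`, and 1 at
#' `s = 0` (the removable-singularity limit). Continuous on `[0, Inf)`.
#'
#' @inheritParams double_well
#' @return values shaped like `s`.
#' @export
dp_ratio <- function(s) {
  s <- abs(s)
  out <- numeric(length(s))
  lo <- s <= 1
  sl <- s[lo]
  out[lo] <- ifelse(sl == 0, 1, sin(2 * pi * sl) / (2 * pi * sl))
  sh <- s[!lo]
  out[!lo] <- (sh - 1) / sh
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

#' Edge indicator field
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in flat regions, small
#' at intensity edges of the Gaussian-smoothed image. Gradients use central
#' differences with replicated edges; the Gaussian uses the same boundary
#' handling. Intensities are used on their native scale (typically 0-255),
#' so `g` drops steeply at strong B-mode wall echoes.
#'
#' @param img numeric matrix (row, col), scalar intensities.
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return numeric matrix with values in `(0, 1]`.
#' @export
edge_indicator <- function(img, sigma = 4) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a numeric matrix", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar", call. = FALSE)
  sm <- gauss_smooth(img, sigma)
  1 / (1 + grad_row(sm)^2 + grad_col(sm)^2)
}

#' Gradient magnitude of a field
#'
#' Central-difference `|grad phi|` with replicated edges.
#'
#' @param phi numeric matrix.
#' @return nonnegative numeric matrix.
#' @export
grad_mag <- function(phi) {
  sqrt(grad_row(phi)^2 + grad_col(phi)^2)
}

#' Divergence of a 2-D vector field
#'
#' Central-difference divergence `d(vr)/d(row) + d(vc)/d(col)` with
#' replicated edges.
#'
#' @param vr,vc numeric matrices: row- and column-components of the field.
#' @return numeric matrix.
#' @export
divergence <- function(vr, vc) {
  check_same_grid(vr, vc, "vector components")
  grad_row(vr) + grad_col(vc)
}

#' Edge-weighted curvature flow term
#'
#' Computes `div(g * grad(phi) / |grad(phi)|)`, the delta-free part of the
#' weighted-length gradient flow. `|grad phi|` is floored at 1e-10 before
#' division.
#'
#' @param phi level-set matrix.
#' @param g edge-indicator matrix on the same grid (use `g = 1` via a matrix
#'   of ones for pure mean-curvature flow).
#' @return numeric matrix.
#' @export
curvature_flow <- function(phi, g) {
  check_same_grid(phi, g, "phi and g")
  pr <- grad_row(phi); pc <- grad_col(phi)
  s <- pmax(sqrt(pr^2 + pc^2), 1e-10)
  divergence(g * pr / s, g * pc / s)
}

#' Signed Euclidean distance field of a binary mask
#'
#' Exact Euclidean distance transform, negative inside the mask and positive
#' outside (the package-wide convention: the object interior is
#' `{phi < 0}`). Mask boundary pixels have `|phi| <= 1`; away from the
#' boundary and medial axis `|grad phi| ~ 1`.
#'
#' @param mask logical matrix with at least one `TRUE` and one `FALSE` pixel.
#' @return numeric matrix (pixel units).
#' @export
signed_distance <- function(mask) {
  mask <- as_mask(mask)
  n_in <- sum(mask)
  if (n_in == 0L || n_in == length(mask))
    stop("degenerate mask: needs at least one inside and one outside pixel",
         call. = FALSE)
  d_in  <- EBImage::distmap(mask * 1, metric = "euclidean")
  d_out <- EBImage::distmap((!mask) * 1, metric = "euclidean")
  out <- as.matrix(d_out) - as.matrix(d_in)
  dim(out) <- dim(mask)
  out
}

#' Binary-step initial level-set field
#'
#' Standard DRLSE initialization: `-c0` inside the mask, `+c0` outside. The
#' distance-regularization term of the evolution repairs this step into an
#' approximate signed distance within a few iterations, so no distance
#' transform is needed for the evolving field.
#'
#' @param mask logical matrix (initial region).
#' @param c0 positive step height (default 2).
#' @return numeric matrix with values in `{-c0, +c0}`.
#' @export
binary_step_initial <- function(mask, c0 = 2) {
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop("'c0' must be a positive scalar", call. = FALSE)
  mask <- as_mask(mask)
  out <- matrix(c0, nrow(mask), ncol(mask))
  out[mask] <- -c0
  out
}
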