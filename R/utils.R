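# Internal matrix helpers shared across the package.
#
# Convention: images, level-set fields and masks are plain R matrices indexed
# [row, col] with row = y increasing downward, unit pixel spacing. All finite
# differences use replicated-edge (Neumann) boundary handling.

# shift a matrix by (dr, dc) with replicated edges
shift_rep <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# central differences, replicated edges
grad_row <- function(m) (shift_rep(m, 1L, 0L) - shift_rep(m, -1L, 0L)) / 2
grad_col <- function(m) (shift_rep(m, 0L, 1L) - shift_rep(m, 0L, -1L)) / 2

# 5-point Laplacian, replicated edges
laplacian <- function(m) {
  shift_rep(m, 1L, 0L) + shift_rep(m, -1L, 0L) +
    shift_rep(m, 0L, 1L) + shift_rep(m, 0L, -1L) - 4 * m
}

# separable Gaussian convolution with replicated edges
gauss_smooth <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_rep(m, dr = i - r - 1L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_rep(m2, dc = i - r - 1L)
  out
}

check_same_grid <- function(a, b, what = "fields") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

as_mask <- function(m) {
  if (is.logical(m)) {
    storage.mode(m) <- "logical"
    return(m)
  }
  m > 0
}

# disk structuring element: pixels with dx^2 + dy^2 <= r^2
disk_kernel <- function(r) {
  stopifnot(r >= 1)
  d <- (-floor(r)):floor(r)
  outer(d^2, d^2, "+") <= r^2
}

# 3x3 cross (4-neighbourhood) structuring element
cross_kernel <- function() {
  k <- matrix(FALSE, 3L, 3L)
  k[2L, ] <- TRUE; k[, 2L] <- TRUE
  k
}

# binary erosion/dilation with explicit out-of-image semantics
# (outside = background for erosion targets of boundary extraction)
erode_mask <- function(mask, kern) {
  mask <- as_mask(mask)
  as_mask(EBImage::erode(mask * 1, kern * 1) > 0.5)
}

dilate_mask <- function(mask, kern) {
  mask <- as_mask(mask)
  as_mask(EBImage::dilate(mask * 1, kern * 1) > 0.5)
}

# boundary pixels: mask minus its erosion by the 3x3 cross, with pixels
# outside the image treated as background (so mask pixels on the image
# border are boundary pixels)
mask_boundary <- function(mask) {
  mask <- as_mask(mask)
  er <- mask
  er <- er & shift_pad_false(mask,  1L, 0L)
  er <- er & shift_pad_false(mask, -1L, 0L)
  er <- er & shift_pad_false(mask, 0L,  1L)
  er <- er & shift_pad_false(mask, 0L, -1L)
  mask & !er
}

# shift with FALSE padding (used for boundary semantics)
shift_pad_false <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

# run body with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(body)
}
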