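# Fixtures and brute-force oracles shared across test files. Oracles are
# deliberately naive (loops, exhaustive search) and independent of the
# package's implementation paths.

disk_mask <- function(n, cy, cx, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

band_mask <- function(nr, nc, top, bottom) {
  m <- matrix(FALSE, nr, nc)
  m[top:bottom, ] <- TRUE
  m
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# a quick, small clean phantom used by several evolution tests
small_clean_phantom <- function(seed = 3L) {
  phantom_generate(phantom_spec(
    height = 96L, width = 144L, lumen_half_thickness = 14,
    speckle_looks = 1e6, inhomogeneity_amp = 0, seed = seed))
}

# ---- oracles ----------------------------------------------------------

# boundary: mask pixel with some 4-neighbour outside the mask (image
# border counts as outside)
oracle_boundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c]) next
    nb <- c(
      if (r > 1) m[r - 1, c] else FALSE,
      if (r < nr) m[r + 1, c] else FALSE,
      if (c > 1) m[r, c - 1] else FALSE,
      if (c < nc) m[r, c + 1] else FALSE)
    out[r, c] <- !all(nb)
  }
  out
}

oracle_hausdorff <- function(x, g) {
  bx <- which(oracle_boundary(x), arr.ind = TRUE)
  bg <- which(oracle_boundary(g), arr.ind = TRUE)
  dmat <- sqrt(outer(bx[, 1], bg[, 1], "-")^2 +
               outer(bx[, 2], bg[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_metrics <- function(x, g) {
  tp <- sum(x & g); fp <- sum(x & !g); fn <- sum(!x & g); tn <- sum(!x & !g)
  list(dice = 2 * tp / (2 * tp + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       iou = tp / (tp + fp + fn))
}

# erosion by an arbitrary structuring element, direct definition
oracle_erode <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- (nrow(kern) - 1L) / 2L; kc <- (ncol(kern) - 1L) / 2L
  off <- which(kern, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + off[, 1] - kr - 1L
    cc <- c + off[, 2] - kc - 1L
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[r, c] <- all(inside) && all(m[cbind(rr, cc)])
  }
  out
}

# exhaustive Otsu: minimize within-class variance over all thresholds
oracle_otsu_threshold <- function(img) {
  bins <- pmin(pmax(floor(as.vector(img)), 0), 255)
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    lo <- bins[bins <= t]; hi <- bins[bins > t]
    if (!length(lo) || !length(hi)) next
    w <- length(lo) * mean((lo - mean(lo))^2) +
      length(hi) * mean((hi - mean(hi))^2)
    if (w < best_w - 1e-9) { best_w <- w; best_t <- t }
  }
  best_t
}

# nearest-opposite-class distance, sign convention: negative inside
oracle_signed_distance_at <- function(mask, r, c) {
  opp <- which(mask != mask[r, c], arr.ind = TRUE)
  d <- min(sqrt((opp[, 1] - r)^2 + (opp[, 2] - c)^2))
  if (mask[r, c]) -d else d
}
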