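# Segmentation evaluation: Dice, Hausdorff distance, sensitivity,
# specificity, IoU, plus per-image reports and cohort aggregation
# (mean +/- sample SD, fractions reported as percentages).

check_metric_masks <- function(x, g, need_g = TRUE) {
  x <- as_mask(x); g <- as_mask(g)
  check_same_grid(x, g, "masks")
  if (need_g && !any(g))
    stop("ground-truth mask is empty: metric undefined", call. = FALSE)
  list(x = x, g = g)
}

#' Dice similarity coefficient
#'
#' `2|X ∩ G| / (|X| + |G|)` between a segmentation `x` and ground truth
#' `g`. Empty `x` against non-empty `g` gives 0.
#'
#' @param x,g logical masks on one grid; `g` must be non-empty.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(x, g) {
  m <- check_metric_masks(x, g)
  2 * sum(m$x & m$g) / (sum(m$x) + sum(m$g))
}

#' Sensitivity (recall)
#'
#' `|X ∩ G| / |G|` = TP / (TP + FN).
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
sensitivity <- function(x, g) {
  m <- check_metric_masks(x, g)
  sum(m$x & m$g) / sum(m$g)
}

#' Specificity (true-negative rate)
#'
#' `TN / (TN + FP)` over the image domain: the fraction of true-background
#' pixels the segmentation also leaves as background.
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
specificity <- function(x, g) {
  m <- check_metric_masks(x, g)
  if (all(m$g))
    stop("ground truth covers the full domain: specificity undefined",
         call. = FALSE)
  sum(!m$x & !m$g) / sum(!m$g)
}

#' Intersection over union (Jaccard index)
#'
#' `|X ∩ G| / |X ∪ G|` = TP / (TP + FP + FN).
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(x, g) {
  m <- check_metric_masks(x, g)
  u <- sum(m$x | m$g)
  if (u == 0L) return(0)
  sum(m$x & m$g) / u
}

#' Symmetric Hausdorff distance between mask boundaries
#'
#' `max(h(X, G), h(G, X))` with `h(A, B) = max_{a in boundary(A)}
#' min_{b in boundary(B)} ||a - b||`, Euclidean, in pixels. Boundaries are
#' each mask minus its erosion by the 3x3 cross (pixels outside the image
#' count as background). Computed exactly via Euclidean distance
#' transforms. An empty mask raises an error: the distance is undefined,
#' not zero.
#'
#' @param x,g non-empty logical masks on one grid.
#' @return scalar `>= 0` (pixels).
#' @export
hausdorff <- function(x, g) {
  x <- as_mask(x); g <- as_mask(g)
  check_same_grid(x, g, "masks")
  if (!any(x) || !any(g))
    stop("empty mask: Hausdorff distance undefined", call. = FALSE)
  bx <- mask_boundary(x); bg <- mask_boundary(g)
  d_to_bg <- as.matrix(EBImage::distmap((!bg) * 1, metric = "euclidean"))
  d_to_bx <- as.matrix(EBImage::distmap((!bx) * 1, metric = "euclidean"))
  max(max(d_to_bg[bx]), max(d_to_bx[bg]))
}

#' Per-image metric report
#'
#' All five metrics for one segmentation/ground-truth pair, as a one-row
#' data.frame (fractions in `[0, 1]`, HD in pixels). If `x` is empty, HD is
#' reported as `NA` rather than 0.
#'
#' @inheritParams dice
#' @param id optional image identifier.
#' @return one-row data.frame with columns `id`, `dice`, `sensitivity`,
#'   `specificity`, `iou`, `hd`.
#' @export
metrics_report <- function(x, g, id = NA_character_) {
  hd <- tryCatch(hausdorff(x, g), error = function(e) NA_real_)
  data.frame(id = id,
             dice = dice(x, g),
             sensitivity = sensitivity(x, g),
             specificity = specificity(x, g),
             iou = iou(x, g),
             hd = hd,
             stringsAsFactors = FALSE)
}

#' Cohort aggregation of metric reports
#'
#' Mean and sample standard deviation (n-1 denominator) per metric over a
#' set of per-image reports, with fraction metrics scaled to percentages
#' and HD left in pixels. With a single report the SD is reported as 0 and
#' flagged.
#'
#' @param reports data.frame of rows from [metrics_report()] (row-bound).
#' @return data.frame with columns `metric`, `mean`, `sd`, `n`; attribute
#'   `n1_flag` is `TRUE` when `n = 1`.
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  frac <- c("dice", "sensitivity", "specificity", "iou")
  out <- lapply(c(frac, "hd"), function(mname) {
    v <- reports[[mname]]
    v <- v[!is.na(v)]
    scale <- if (mname %in% frac) 100 else 1
    data.frame(metric = mname,
               mean = mean(v) * scale,
               sd = if (length(v) > 1L) stats::sd(v) * scale else 0,
               n = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "n1_flag") <- nrow(reports) == 1L
  out
}
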