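# Image/mask/report I-O and the pipeline orchestration behind the CLI:
# crop -> automatic initialization -> evolution -> metrics -> artifacts.

#' Read a grayscale image as a (row, col) intensity matrix
#'
#' PNG/TIFF/JPEG via EBImage. RGB inputs are converted by Rec. 601
#' luminance (0.299 R + 0.587 G + 0.114 B); intensities are rescaled to
#' 0-255 regardless of bit depth.
#'
#' @param path image file path.
#' @return numeric matrix, rows = image rows (y), values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  dat <- EBImage::imageData(img)
  if (length(d) == 3L) {
    nch <- d[3]
    dat <- if (nch >= 3)
      0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    else dat[, , 1]
  }
  t(dat) * 255
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path, type = "png")
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Pixels above half intensity are foreground.
#'
#' @param path mask file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  read_gray_image(path) > 127.5
}

#' Write a contour overlay PNG
#'
#' The original image with the mask's boundary drawn in red, matching the
#' usual presentation of segmentation results.
#'
#' @param img numeric intensity matrix (0-255).
#' @param mask logical matrix on the same grid.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(img, mask, path) {
  check_same_grid(img, as_mask(mask), "img and mask")
  b <- mask_boundary(as_mask(mask))
  base <- pmin(pmax(img / 255, 0), 1)
  r <- base; g <- base; bl <- base
  r[b] <- 1; g[b] <- 0; bl[b] <- 0
  arr <- array(c(t(r), t(g), t(bl)), dim = c(ncol(img), nrow(img), 3))
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path,
                      type = "png")
  invisible(path)
}

#' Crop an image to a region of interest
#'
#' Removes scanner text/annotations before segmentation. The rectangle is
#' given 0-based as `c(top, left, height, width)` (the package-wide
#' coordinate convention for configuration files).
#'
#' @param img numeric matrix.
#' @param rect integer vector `c(top, left, height, width)`, 0-based, or
#'   `NULL` for no crop.
#' @return cropped matrix.
#' @export
crop_image <- function(img, rect) {
  if (is.null(rect)) return(img)
  stopifnot(length(rect) == 4)
  top <- rect[1]; left <- rect[2]; h <- rect[3]; w <- rect[4]
  if (top < 0 || left < 0 || h < 1 || w < 1 ||
      top + h > nrow(img) || left + w > ncol(img))
    stop("crop rectangle outside image bounds", call. = FALSE)
  img[(top + 1):(top + h), (left + 1):(left + w), drop = FALSE]
}

#' Default run configuration
#'
#' Every tunable of the pipeline with its default, so a run report can
#' record exactly what was used. `model` is one of `"cv"`, `"drlse"`,
#' `"proposed"`.
#'
#' @param model segmentation model.
#' @param crop optional 0-based `c(top, left, height, width)` ROI.
#' @param dark lumen polarity flag (dark class = lumen).
#' @param erosion_radius initial-contour erosion radius.
#' @param literal_eq14 unmollified shape-force variant flag.
#' @param evolve an [evolve_params()] object.
#' @param cv a [cv_params()] object.
#' @param debug_artifacts write intermediate masks (wall, band, init).
#' @return list of class `run_config`.
#' @export
run_config <- function(model = "proposed", crop = NULL, dark = TRUE,
                       erosion_radius = 20, literal_eq14 = FALSE,
                       evolve = evolve_params(), cv = cv_params(),
                       debug_artifacts = FALSE) {
  model <- match.arg(model, c("proposed", "drlse", "cv"))
  structure(list(model = model, crop = crop, dark = dark,
                 erosion_radius = erosion_radius,
                 literal_eq14 = isTRUE(literal_eq14), evolve = evolve,
                 cv = cv, debug_artifacts = isTRUE(debug_artifacts)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys (`model`, `crop`, `dark`, `erosion_radius`, `literal_eq14`,
#' `debug_artifacts`) plus optional `evolve:` and `cv:` blocks overriding
#' individual parameters of [evolve_params()] / [cv_params()].
#'
#' @param path YAML file.
#' @return a [run_config()] list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ev <- do.call(evolve_params, y$evolve %||% list())
  cv <- do.call(cv_params, y$cv %||% list())
  run_config(model = y$model %||% "proposed",
             crop = if (!is.null(y$crop)) as.integer(unlist(y$crop)),
             dark = y$dark %||% TRUE,
             erosion_radius = y$erosion_radius %||% 20,
             literal_eq14 = y$literal_eq14 %||% FALSE,
             evolve = ev, cv = cv,
             debug_artifacts = y$debug_artifacts %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment one image in memory
#'
#' Runs crop, automatic initialization and the configured model; returns
#' the evolution result together with the initialization artifacts.
#'
#' @param img numeric intensity matrix (0-255) or path to an image file.
#' @param config a [run_config()].
#' @return list with `result` (a `lumenseg_result`), `init` (the
#'   [auto_initialize()] output) and `image` (the cropped intensity
#'   matrix).
#' @export
segment_image <- function(img, config = run_config()) {
  if (is.character(img)) img <- read_gray_image(img)
  img <- crop_image(img, config$crop)
  init <- auto_initialize(img, dark = config$dark,
                          erosion_radius = config$erosion_radius)
  result <- switch(config$model,
    proposed = proposed_evolve(img, init$phi_init, init$phi0,
                               config$evolve,
                               literal_eq14 = config$literal_eq14),
    drlse = drlse_evolve(img, init$phi_init, config$evolve),
    cv = cv_evolve(img, signed_distance(init$init_mask), config$cv))
  list(result = result, init = init, image = img)
}

# serialize parameter objects for run reports
params_as_list <- function(p) lapply(unclass(p), function(v) unname(v))

#' Segment an image file and write artifacts
#'
#' Writes `<stem>_mask.png` (255 = lumen), `<stem>_overlay.png` and
#' `<stem>_report.json` (every parameter actually used, iteration count,
#' convergence flag, final energy, initialization report, and metric
#' values when a ground-truth mask is supplied) into `out_dir`. No partial
#' outputs are left behind on failure.
#'
#' @param image_path input image.
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @param truth_path optional ground-truth mask for metrics.
#' @return named character vector of the files written, invisibly.
#' @export
cmd_segment <- function(image_path, out_dir, config = run_config(),
                        truth_path = NULL) {
  run <- segment_image(image_path, config)   # fail before any writes
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.[^.]+$", "", basename(image_path))
  files <- c(mask = file.path(out_dir, paste0(stem, "_mask.png")),
             overlay = file.path(out_dir, paste0(stem, "_overlay.png")),
             report = file.path(out_dir, paste0(stem, "_report.json")))
  write_mask_png(run$result$mask, files[["mask"]])
  write_overlay_png(run$image, run$result$mask, files[["overlay"]])
  report <- list(
    image = image_path, model = config$model,
    params = params_as_list(if (config$model == "cv") config$cv
                            else config$evolve),
    crop = config$crop, dark = config$dark,
    erosion_radius = config$erosion_radius,
    literal_eq14 = config$literal_eq14,
    n_iter = run$result$n_iter, converged = run$result$converged,
    final_energy = if (length(run$result$energy_trace))
      run$result$energy_trace[run$result$n_iter] else NULL,
    grad_band_mean = run$result$grad_band_mean,
    init = run$init$report)
  if (!is.null(truth_path)) {
    truth <- crop_image(read_mask(truth_path), config$crop)
    report$metrics <- as.list(metrics_report(run$result$mask, truth)[
      , c("dice", "sensitivity", "specificity", "iou", "hd")])
  }
  jsonlite::write_json(report, files[["report"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (config$debug_artifacts) {
    write_mask_png(run$init$wall, file.path(out_dir, paste0(stem, "_wall.png")))
    write_mask_png(run$init$band, file.path(out_dir, paste0(stem, "_band.png")))
    write_mask_png(run$init$init_mask,
                   file.path(out_dir, paste0(stem, "_init.png")))
  }
  invisible(files)
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs files by name across the two directories, computes the five
#' metrics per image and writes `metrics.csv` (per image) and
#' `summary.json` (cohort mean ± SD, Table-style column order: Dice,
#' sensitivity, specificity, IoU as percentages, HD in pixels). Unmatched
#' files are listed in a warning and skipped.
#'
#' @param pred_dir,truth_dir directories of mask images with matching
#'   filenames.
#' @param out_dir output directory.
#' @return list with `per_image` and `summary` data.frames, invisibly.
#' @export
cmd_evaluate <- function(pred_dir, truth_dir, out_dir) {
  preds <- list.files(pred_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE)
  truths <- list.files(truth_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                       ignore.case = TRUE)
  common <- intersect(preds, truths)
  unmatched <- union(setdiff(preds, truths), setdiff(truths, preds))
  if (length(unmatched))
    warning("unmatched files skipped: ", paste(unmatched, collapse = ", "),
            call. = FALSE)
  if (!length(common)) stop("no matching mask pairs found", call. = FALSE)
  rows <- do.call(rbind, lapply(common, function(f)
    metrics_report(read_mask(file.path(pred_dir, f)),
                   read_mask(file.path(truth_dir, f)), id = f)))
  summ <- aggregate_metrics(rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rows, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(per_image = rows, summary = summ))
}

#' Write a phantom suite to disk
#'
#' One `img_###.png`, `truth_###.png` and `spec_###.json` per sample.
#'
#' @param out_dir output directory.
#' @param n,level,seed,height,width passed to [degradation_suite()].
#' @return the generated sample list, invisibly.
#' @export
cmd_phantom <- function(out_dir, n = 10L, level = "moderate", seed = 1L,
                        height = 128L, width = 192L) {
  samples <- degradation_suite(n, level, seed, height, width)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(samples)) {
    tag <- sprintf("%03d", i)
    EBImage::writeImage(EBImage::Image(t(samples[[i]]$image) / 255),
                        file.path(out_dir, sprintf("img_%s.png", tag)),
                        type = "png")
    write_mask_png(samples[[i]]$truth,
                   file.path(out_dir, sprintf("truth_%s.png", tag)))
    jsonlite::write_json(unclass(samples[[i]]$spec),
                         file.path(out_dir, sprintf("spec_%s.json", tag)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(samples)
}

#' Run all three models over a phantom suite
#'
#' Every sample is auto-initialized once; DRLSE and the shape-prior model
#' share the binary-step initialization, the Chan-Vese baseline gets the
#' signed distance of the same initial mask. Per-image failures are
#' recorded and skipped.
#'
#' @param samples list of `phantom_sample` objects (or a directory written
#'   by [cmd_phantom()]).
#' @param models subset of `c("cv", "drlse", "proposed")`.
#' @param evolve,cv parameter objects for the respective models.
#' @return list with `per_image` (metrics per sample x model, plus
#'   `n_iter`, `converged`, `grad_band_mean`) and `summary` (one
#'   aggregated table per model).
#' @export
compare_models <- function(samples, models = c("cv", "drlse", "proposed"),
                           evolve = evolve_params(), cv = cv_params()) {
  if (is.character(samples)) samples <- read_suite_dir(samples)
  models <- match.arg(models, c("cv", "drlse", "proposed"),
                      several.ok = TRUE)
  rows <- list()
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    init <- tryCatch(auto_initialize(sm$image), error = function(e) e)
    if (inherits(init, "error")) {
      warning(sprintf("sample %d: initialization failed (%s)", i,
                      conditionMessage(init)), call. = FALSE)
      next
    }
    for (model in models) {
      res <- tryCatch(switch(model,
        proposed = proposed_evolve(sm$image, init$phi_init, init$phi0,
                                   evolve),
        drlse = drlse_evolve(sm$image, init$phi_init, evolve),
        cv = cv_evolve(sm$image, signed_distance(init$init_mask), cv)),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("sample %d, %s: %s", i, model,
                        conditionMessage(res)), call. = FALSE)
        next
      }
      mr <- metrics_report(res$mask, sm$truth, id = sprintf("%03d", i))
      mr$model <- model
      mr$n_iter <- res$n_iter
      mr$converged <- res$converged
      mr$grad_band_mean <- res$grad_band_mean
      rows[[length(rows) + 1L]] <- mr
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- lapply(split(per_image, per_image$model), aggregate_metrics)
  list(per_image = per_image, summary = summary)
}

read_suite_dir <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^img_.*\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no img_*.png files in ", dir, call. = FALSE)
  lapply(imgs, function(f) {
    tf <- file.path(dirname(f), sub("^img_", "truth_", basename(f)))
    structure(list(image = read_gray_image(f), truth = read_mask(tf),
                   spec = NULL), class = "phantom_sample")
  })
}

#' Parameter sweep of the shape-prior model
#'
#' Re-runs the shape-prior model over a grid of `(dt, lam, alpha, beta)`
#' rows on the same suite and reports one aggregated metric table per row.
#'
#' @param samples list of `phantom_sample` objects.
#' @param grid data.frame with columns `dt`, `lam`, `alpha`, `beta`.
#' @return data.frame: one row per parameter set with mean Dice/HD and the
#'   parameter values.
#' @export
sweep_parameters <- function(samples, grid) {
  stopifnot(all(c("dt", "lam", "alpha", "beta") %in% names(grid)))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- evolve_params(dt = grid$dt[i], lam = grid$lam[i],
                       alpha = grid$alpha[i], beta = grid$beta[i])
    cmp <- compare_models(samples, models = "proposed", evolve = p)
    s <- cmp$summary$proposed
    data.frame(dt = grid$dt[i], lam = grid$lam[i], alpha = grid$alpha[i],
               beta = grid$beta[i],
               dice = s$mean[s$metric == "dice"],
               sensitivity = s$mean[s$metric == "sensitivity"],
               specificity = s$mean[s$metric == "specificity"],
               iou = s$mean[s$metric == "iou"],
               hd = s$mean[s$metric == "hd"])
  })
  do.call(rbind, out)
}

#' Compare models on a suite directory and write the report
#'
#' Writes `per_image.csv` and `summary.json` (per-model mean ± SD tables).
#' With a `sweep` grid, additionally writes `sweep.csv`.
#'
#' @param suite_dir directory written by [cmd_phantom()] (or a sample
#'   list).
#' @param out_dir output directory.
#' @param models models to run.
#' @param sweep optional parameter grid for [sweep_parameters()].
#' @param evolve,cv parameter objects.
#' @return list of the computed tables, invisibly.
#' @export
cmd_compare <- function(suite_dir, out_dir,
                        models = c("cv", "drlse", "proposed"),
                        sweep = NULL, evolve = evolve_params(),
                        cv = cv_params()) {
  samples <- if (is.character(suite_dir)) read_suite_dir(suite_dir)
             else suite_dir
  cmp <- compare_models(samples, models, evolve = evolve, cv = cv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$per_image, file.path(out_dir, "per_image.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cmp$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  sw <- NULL
  if (!is.null(sweep)) {
    sw <- sweep_parameters(samples, sweep)
    utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }
  invisible(list(compare = cmp, sweep = sw))
}
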