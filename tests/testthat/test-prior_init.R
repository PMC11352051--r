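test_that("Otsu threshold maximizes between-class variance", {
  # bimodal image: equal counts of 40 and 200
  img <- matrix(rep(c(40, 200), each = 128), 16, 16)
  m <- otsu_mask(img)
  t_star <- attr(m, "threshold")
  expect_true(t_star >= 40 && t_star < 200)
  expect_identical(structure(m, threshold = NULL), img == 40)
  # polarity flag inverts the class
  expect_identical(structure(otsu_mask(img, dark = FALSE), threshold = NULL),
                   img == 200)
  expect_error(otsu_mask(matrix(7, 8, 8)), "constant")
  # exhaustive within-class-variance oracle on rough bimodal images
  set.seed(14)
  for (i in 1:6) {
    img <- matrix(round(c(stats::rnorm(500, 60, 15),
                          stats::rnorm(524, 180, 20))), 32, 32)
    img <- pmin(pmax(img, 0), 255)
    expect_equal(attr(otsu_mask(img), "threshold"),
                 oracle_otsu_threshold(img))
  }
})

test_that("Otsu rough segmentation recovers most of the phantom lumen", {
  ph <- phantom_generate(phantom_spec(seed = 2L))
  m <- otsu_mask(ph$image)
  expect_gte(sum(m & ph$truth) / sum(ph$truth), 0.8)
})

test_that("largest component uses 8-connectivity and breaks ties", {
  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE            # 100 px
  m[25:31, 25:31] <- TRUE          # 49 px
  out <- largest_component(m)
  expect_identical(sum(out), 100L)
  expect_true(all(out[5:14, 5:14]))
  # diagonal touch joins components
  d <- matrix(FALSE, 10, 10)
  d[2:4, 2:4] <- TRUE; d[5, 5] <- TRUE
  expect_identical(sum(largest_component(d)), 10L)
  # single component is preserved
  one <- disk_mask(21, 11, 11, 6)
  expect_identical(largest_component(one), one)
  expect_error(largest_component(matrix(FALSE, 5, 5)), "empty")
  # output is always one 8-connected component
  set.seed(8)
  for (i in 1:100) {
    sp <- random_mask(24, 24, 0.35)
    if (!any(sp)) next
    lab <- lumenseg:::label_components8(largest_component(sp))
    expect_equal(max(lab), 1L)
  }
})

test_that("rough wall traces the lumen boundary", {
  m <- disk_mask(61, 31, 31, 18)
  w <- rough_wall(m)
  idx <- which(w, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 31)^2 + (idx[, 2] - 31)^2)
  expect_true(all(abs(rad - 18) <= 1.6))
  # boundary-only: disjoint from the eroded interior
  interior <- lumenseg:::erode_mask(m, lumenseg:::disk_kernel(2))
  expect_false(any(w & interior))
  # small holes are filled before boundary extraction
  mh <- m; mh[30:31, 30:32] <- FALSE
  expect_identical(rough_wall(mh), w)
  tiny <- matrix(FALSE, 30, 30); tiny[5, 5:14] <- TRUE
  expect_error(rough_wall(tiny), "degenerate")
})

test_that("initial contour erosion matches a brute-force disk erosion", {
  m <- matrix(FALSE, 80, 220)
  m[11:70, 11:210] <- TRUE   # 60 x 200 rectangle
  out <- initial_contour_mask(m)
  expect_equal(attr(out, "radius"), 20)
  oracle <- oracle_erode(m, lumenseg:::disk_kernel(20))
  expect_identical(structure(out, radius = NULL), oracle)
  # a 60x200 rectangle erodes to a 20x160 rectangle
  expect_identical(sum(out), 20L * 160L)
  # margin: eroded mask is >= 20 px from the complement
  d <- EBImage::distmap(m * 1, metric = "euclidean")
  expect_true(all(as.matrix(d)[out] >= 20))
})

test_that("initial contour erosion falls back on thin lumens", {
  thin <- disk_mask(61, 31, 31, 15)
  out <- initial_contour_mask(thin)
  expect_lt(attr(out, "radius"), 20)
  expect_gte(sum(out), 100)
  sliver <- matrix(FALSE, 40, 40); sliver[20:22, 5:35] <- TRUE
  expect_error(initial_contour_mask(sliver), "too thin")
})

test_that("centerline follows straight and sloped bands", {
  m <- band_mask(128, 192, 40, 60)
  cl <- estimate_centerline(m)
  expect_identical(cl$col, 1:192)
  expect_true(all(abs(cl$row - 50) <= 1))
  # sloped band: rows 40+0.2c .. 60+0.2c
  ms <- matrix(FALSE, 128, 192)
  for (cc in 1:192) ms[(40 + round(0.2 * cc)):(60 + round(0.2 * cc)), cc] <- TRUE
  cls <- estimate_centerline(ms)
  expect_true(all(abs(cls$row - (50 + 0.2 * cls$col)) <= 1.6))
  # centerline points lie inside the mask
  expect_true(all(ms[cbind(cls$row, cls$col)]))
  expect_error(estimate_centerline(m[, 1:20]), "30 columns")
})

test_that("narrowest radius measures the thinnest wall-to-wall span", {
  m <- band_mask(96, 160, 40, 60)  # thickness 21
  cl <- estimate_centerline(m)
  expect_equal(narrowest_radius(m, cl), 10.5)
  # thickness tapering from 30 to 16 at the middle column
  mt <- matrix(FALSE, 96, 160)
  for (cc in 1:160) {
    th <- round(30 - 14 * exp(-((cc - 80) / 25)^2))
    half <- (th - 1) / 2
    mt[(48 - floor(half)):(48 + ceiling(half)), cc] <- TRUE
  }
  clt <- estimate_centerline(mt)
  r <- narrowest_radius(mt, clt)
  expect_equal(r, min(colSums(mt)) / 2)
  expect_lt(abs(r - 8), 0.6)
  # unaffected by disconnected speckle outside the main component
  msp <- mt; msp[5, seq(3, 155, by = 9)] <- TRUE
  comp <- largest_component(msp)
  expect_equal(narrowest_radius(comp, estimate_centerline(comp)), r)
})

test_that("shape-prior band hugs the centerline at constant thickness", {
  m <- band_mask(128, 192, 40, 60)
  cl <- estimate_centerline(m)
  pr <- build_shape_prior(cl, 10, c(128L, 192L))
  expect_identical(unname(pr$band), band_mask(128, 192, 40, 60))
  expect_identical(pr$phi0, signed_distance(pr$band))
  # sinusoidal centerline: per-column thickness 2r + 1
  ph <- phantom_generate(phantom_spec(
    curvature_amp = 5, curvature_period = 120,
    speckle_looks = 1e6, inhomogeneity_amp = 0))
  lum <- largest_component(otsu_mask(ph$image))
  cls <- estimate_centerline(lum)
  prs <- build_shape_prior(cls, 8, dim(ph$image))
  expect_true(all(colSums(prs$band)[cls$col] == 17))
  expect_error(build_shape_prior(cl, 1, c(128L, 192L)), "thin")
})

test_that("prior band overlaps the true lumen on a clean phantom", {
  ph <- phantom_generate(phantom_spec(speckle_looks = 1e6,
                                      inhomogeneity_amp = 0))
  init <- auto_initialize(ph$image)
  expect_gte(dice(init$band, ph$truth), 0.8)
})

test_that("automatic initialization is deterministic and well-formed", {
  ph <- phantom_generate(phantom_spec(seed = 4L))
  a <- auto_initialize(ph$image)
  b <- auto_initialize(ph$image)
  expect_identical(a$phi_init, b$phi_init)
  expect_identical(a$phi0, b$phi0)
  # the initial region stays >= 2 px inside the borders
  im <- a$phi_init < 0
  expect_false(any(im[c(1, 2, nrow(im) - 1, nrow(im)), ]))
  expect_false(any(im[, c(1, 2, ncol(im) - 1, ncol(im))]))
  # monotone containment through the pipeline
  sm <- lumenseg:::gauss_smooth(ph$image, 1.5)
  rough <- otsu_mask(sm)
  lumen <- largest_component(rough)
  core <- initial_contour_mask(lumen)
  expect_true(all(!core | lumen))
  expect_true(all(!lumen | rough))
})

test_that("initialization fails loudly with a stage name on non-vessels", {
  expect_error(auto_initialize(matrix(128, 64, 64)), "^\\[otsu\\]")
  set.seed(6)
  dots <- matrix(255, 64, 64)
  dots[sample(64 * 64, 40)] <- 0   # scattered specks, no band structure
  err <- tryCatch(auto_initialize(dots), error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "^\\[")
})

test_that("prior band slope tracks the vessel slope", {
  for (sl in c(-0.3, 0, 0.3)) {
    ph <- phantom_generate(phantom_spec(slope = sl, speckle_looks = 1e6,
                                        inhomogeneity_amp = 0))
    lum <- largest_component(otsu_mask(ph$image))
    cl <- estimate_centerline(lum)
    fit <- stats::lm(row ~ col, data = cl)
    expect_lt(abs(stats::coef(fit)[["col"]] - sl), 0.05)
  }
})

test_that("narrowest radius scales with lumen thickness", {
  r_of <- function(ht) {
    ph <- phantom_generate(phantom_spec(lumen_half_thickness = ht,
                                        speckle_looks = 1e6,
                                        inhomogeneity_amp = 0))
    lum <- largest_component(otsu_mask(ph$image))
    narrowest_radius(lum, estimate_centerline(lum))
  }
  ratio <- r_of(16) / r_of(8)
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
})
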