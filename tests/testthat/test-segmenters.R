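# two-level disk scene used by the Chan-Vese tests
disk_scene <- function(n = 64, r = 15, lo = 50, hi = 200) {
  m <- disk_mask(n, n / 2, n / 2, r)
  img <- matrix(hi, n, n); img[m] <- lo
  list(img = img, m = m)
}

test_that("region means recover piecewise-constant intensities", {
  sc <- disk_scene()
  phi <- signed_distance(sc$m)
  cm <- cv_region_means(sc$img, phi)
  expect_lt(abs(cm[["c1"]] - 50), 2)
  expect_lt(abs(cm[["c2"]] - 200), 2)
  # swapping the sign of phi swaps the means
  cm2 <- cv_region_means(sc$img, -phi)
  expect_equal(unname(cm2[["c1"]]), unname(cm[["c2"]]), tolerance = 1e-10)
  expect_equal(unname(cm2[["c2"]]), unname(cm[["c1"]]), tolerance = 1e-10)
  # constant image: both means equal the constant
  cmc <- cv_region_means(matrix(42, 32, 32), phi[1:32, 1:32])
  expect_equal(as.numeric(cmc), c(42, 42))
  # degenerate side falls back to the global mean with a warning
  expect_warning(
    cmd <- cv_region_means(sc$img, matrix(5, 64, 64)),
    "empty")
  expect_true(attr(cmd, "degenerate"))
})

test_that("Chan-Vese segments a clean two-level disk from a box init", {
  sc <- disk_scene()
  box <- matrix(FALSE, 64, 64); box[27:38, 27:38] <- TRUE
  res <- cv_evolve(sc$img, signed_distance(box))
  expect_s3_class(res, "lumenseg_result")
  expect_gte(dice(res$mask, sc$m), 0.99)
})

test_that("Chan-Vese on a constant image only shrinks by regularization", {
  img <- matrix(90, 64, 64)
  phi <- signed_distance(disk_mask(64, 32, 32, 20))
  res <- cv_evolve(img, phi, cv_params(max_iter = 60L, tol = 0))
  expect_lt(sum(res$mask), sum(phi < 0))
})

test_that("Chan-Vese fragments into many components under speckle", {
  ph <- degradation_suite(1, "moderate", seed = 3)[[1]]
  init <- auto_initialize(ph$image)
  res <- cv_evolve(ph$image, signed_distance(init$init_mask),
                   cv_params(tol = 0, max_iter = 300L))
  ncomp <- max(lumenseg:::label_components8(res$mask))
  expect_gt(ncomp, 1)
})

test_that("shape-prior force is a descent direction confined to the band", {
  ph <- small_clean_phantom()
  init <- auto_initialize(ph$image)
  phi0 <- init$phi0
  # identical shapes: zero force; beta = 0: zero force
  expect_equal(shape_prior_force(phi0, phi0, 0.5), matrix(0, 96, 144))
  phi <- signed_distance(lumenseg:::dilate_mask(
    init$band, lumenseg:::disk_kernel(4)))
  expect_equal(shape_prior_force(phi, phi0, 0), matrix(0, 96, 144))
  f <- shape_prior_force(phi, phi0, 0.5)
  # contour outside the prior: force negative wherever the Dirac is active
  outside <- phi > 0 & phi0 < 0 & smoothed_dirac(phi) > 0
  if (any(outside)) expect_true(all(f[outside] <= 0))
  # a small step along the force decreases the shape energy
  e_shape <- function(p) sum((smoothed_heaviside(p) -
                                smoothed_heaviside(phi0))^2)
  expect_lt(e_shape(phi + 0.5 * f / 0.5 / 2), e_shape(phi))
  expect_error(shape_prior_force(phi, phi0[1:50, ], 0.5), "grid")
})

test_that("beta = 0 reduces the shape-prior model to DRLSE bitwise", {
  ph <- small_clean_phantom()
  init <- auto_initialize(ph$image)
  p <- evolve_params(beta = 0, tol = 0, max_iter = 60L)
  a <- drlse_evolve(ph$image, init$phi_init, p)
  b <- proposed_evolve(ph$image, init$phi_init, init$phi0, p)
  expect_identical(a$final_phi, b$final_phi)
  expect_identical(a$energy_trace, b$energy_trace)
  expect_identical(a$n_iter, b$n_iter)
})

test_that("a dominant shape weight forces the mask onto the prior band", {
  ph <- degradation_suite(1, "moderate", seed = 17)[[1]]
  init <- auto_initialize(ph$image)
  res <- proposed_evolve(ph$image, init$phi_init, init$phi0,
                         evolve_params(beta = 50))
  expect_gte(dice(res$mask, init$band), 0.95)
})

test_that("evolution is equivariant under integer translation", {
  ph <- phantom_generate(phantom_spec(
    height = 112L, width = 176L, lumen_half_thickness = 12,
    speckle_looks = 1e6, inhomogeneity_amp = 0, seed = 2L))
  init <- auto_initialize(ph$image)
  p <- evolve_params(tol = 0, max_iter = 40L, track_energy = FALSE)
  crop <- function(m, dr, dc) m[(1 + dr):(96 + dr), (1 + dc):(160 + dc)]
  ra <- proposed_evolve(crop(ph$image, 0, 0), crop(init$phi_init, 0, 0),
                        crop(init$phi0, 0, 0), p)
  rb <- proposed_evolve(crop(ph$image, 4, 8), crop(init$phi_init, 4, 8),
                        crop(init$phi0, 4, 8), p)
  # compare the shared interior away from the differing borders
  ma <- ra$mask[21:76, 31:130]
  mb <- rb$mask[17:72, 23:122]
  expect_gte(mean(ma == mb), 0.98)
})

test_that("evolution stays finite over long runs on severe speckle", {
  ph <- degradation_suite(1, "severe", seed = 23, height = 64L,
                          width = 96L)[[1]]
  init <- auto_initialize(ph$image)
  res <- proposed_evolve(ph$image, init$phi_init, init$phi0,
                         evolve_params(tol = 0, max_iter = 1000L,
                                       track_energy = FALSE))
  expect_true(all(is.finite(res$final_phi)))
  res2 <- drlse_evolve(ph$image, init$phi_init,
                       evolve_params(tol = 0, max_iter = 1000L,
                                     track_energy = FALSE))
  expect_true(all(is.finite(res2$final_phi)))
})

test_that("energy decreases along the evolution after a short transient", {
  ph <- small_clean_phantom()
  init <- auto_initialize(ph$image)
  res <- proposed_evolve(ph$image, init$phi_init, init$phi0)
  tr <- res$energy_trace
  expect_equal(length(tr), res$n_iter)
  late <- tr[5:length(tr)]
  upticks <- diff(late) > 0.01 * abs(late[-length(late)])
  expect_false(any(upticks))
})

test_that("DRLSE expands to the wall on a clean band and stays regular", {
  ph <- small_clean_phantom()
  init <- auto_initialize(ph$image)
  res <- drlse_evolve(ph$image, init$phi_init)
  expect_gte(dice(res$mask, ph$truth), 0.95)
  # regularity of the level-set field is a steady-state property: keep the
  # contour evolving past its settling point so the double-well term has
  # relaxed the interface, then measure |grad phi| near the contour
  res2 <- drlse_evolve(ph$image, init$phi_init,
                       evolve_params(tol = 0, max_iter = 150L,
                                     track_energy = FALSE))
  expect_gte(res2$grad_band_mean, 0.7)
  expect_lte(res2$grad_band_mean, 1.3)
})

test_that("with g = 1 and no balloon force the contour shortens", {
  img <- matrix(120, 64, 64)   # constant image -> g identically 1
  expect_equal(edge_indicator(img), matrix(1, 64, 64))
  phi <- signed_distance(disk_mask(64, 32, 32, 22))
  p0 <- evolve_params(alpha = 0, tol = 0, max_iter = 20L,
                      track_energy = FALSE)
  p1 <- evolve_params(alpha = 0, tol = 0, max_iter = 60L,
                      track_energy = FALSE)
  a20 <- sum(drlse_evolve(img, phi, p0)$mask)
  a60 <- sum(drlse_evolve(img, phi, p1)$mask)
  expect_lt(a60, a20)
  expect_lt(a20, sum(phi < 0))
})

test_that("energy of a disk contour is dominated by lambda times length", {
  # analytic signed distance (non-integer radius avoids grid alignment of
  # the zero level set, which would undersample the Dirac mass)
  n <- 96; r <- 20.3
  rows <- matrix(seq_len(n), n, n)
  phi <- sqrt((rows - 48.2)^2 + (t(rows) - 48.2)^2) - r
  img <- matrix(100, n, n)
  p <- evolve_params(alpha = 0, beta = 0.5)
  e <- energy_total(img, phi, phi0 = phi, params = p)
  expect_lt(abs(e - p$lam * 2 * pi * r) / (p$lam * 2 * pi * r), 0.05)
})

test_that("a vanishing contour is reported, not crashed on", {
  img <- matrix(100, 48, 48)
  phi <- signed_distance(disk_mask(48, 24, 24, 5))
  # strong positive balloon force shrinks the disk to nothing
  res <- drlse_evolve(img, phi, evolve_params(alpha = 8, tol = 0,
                                              max_iter = 400L,
                                              track_energy = FALSE))
  expect_false(res$converged)
  expect_match(res$diagnostic, "vanished")
  expect_gt(sum(res$mask), 0)
})

test_that("parameter validation enforces the stability bound", {
  expect_error(evolve_params(mu = 0.2, dt = 5), "stability")
  expect_error(evolve_params(dt = -1), "dt")
  expect_silent(evolve_params())
  expect_error(cv_params(lam1 = 0), "lam1")
})
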