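#' Evolution parameters for DRLSE and the shape-prior model
#'
#' Bundles every scalar knob of the level-set evolution. Defaults follow the
#' model's reference setting: time step `dt = 5`, edge-length weight
#' `lam = 6`, balloon (weighted-area) weight `alpha = -3.5` (negative: the
#' contour starts inside the lumen and unfolds outward), shape-prior weight
#' `beta = 0.5`. The distance-regularization weight defaults to
#' `mu = 0.2/dt` so that `mu*dt = 0.2` saturates the stability bound
#' `mu*dt < 1/4`; `eps = 1.5` is the usual Heaviside/Dirac half-width and
#' `sigma` the Gaussian scale of the edge indicator.
#'
#' @param dt explicit time step (CFL-limited: `mu*dt < 0.25`).
#' @param lam weight of the edge-weighted contour-length term, `>= 0`.
#' @param alpha signed weight of the edge-weighted area term (negative
#'   expands a contour initialized inside the object).
#' @param beta shape-prior weight, `>= 0` (`0` reduces the model to DRLSE).
#' @param mu distance-regularization weight, `mu*dt < 0.25`.
#' @param eps Heaviside/Dirac transition half-width (pixels), `> 0`.
#' @param sigma Gaussian sigma of the edge indicator (pixels), `> 0`.
#' @param max_iter iteration budget.
#' @param tol relative symmetric-difference stopping tolerance on the mask.
#' @param tol_patience consecutive below-`tol` iterations required to stop.
#' @param refine_iters zero-balloon refinement iterations appended after
#'   the main evolution (standard DRLSE practice): the balloon force
#'   inflates the interface slope while it drives the contour, and a short
#'   tail with `alpha = 0` lets the distance regularizer settle the field
#'   without moving the converged contour materially.
#' @param track_energy record the discretized energy at every iteration.
#' @return object of class `evolve_params`.
#' @export
evolve_params <- function(dt = 5, lam = 6, alpha = -3.5, beta = 0.5,
                          mu = 0.2 / dt, eps = 1.5, sigma = 4,
                          max_iter = 500L, tol = 1e-3, tol_patience = 10L,
                          refine_iters = 10L, track_energy = TRUE) {
  p <- list(dt = dt, lam = lam, alpha = alpha, beta = beta, mu = mu,
            eps = eps, sigma = sigma, max_iter = as.integer(max_iter),
            tol = tol, tol_patience = as.integer(tol_patience),
            refine_iters = as.integer(refine_iters),
            track_energy = isTRUE(track_energy))
  validate_evolve_params(p)
  structure(p, class = "evolve_params")
}

validate_evolve_params <- function(p) {
  stopifnot(is.numeric(p$dt), p$dt > 0, is.numeric(p$eps), p$eps > 0,
            p$lam >= 0, p$beta >= 0, p$sigma > 0, p$max_iter >= 1,
            p$tol >= 0)
  if (!(p$mu * p$dt < 0.25))
    stop(sprintf("stability bound violated: mu*dt = %.4g must be < 0.25",
                 p$mu * p$dt), call. = FALSE)
  invisible(p)
}

#' Chan-Vese parameters
#'
#' Defaults for the piecewise-constant (Chan-Vese) baseline on intensities
#' in their native 0-255 scale: unit data weights, no area penalty, length
#' weight `0.2 * 255^2` (the conventional 0.2 scaled to squared-intensity
#' units), small explicit step `dt = 0.1`.
#'
#' @param lam1,lam2 data-term weights for the inside/outside regions, `> 0`.
#' @param mu_len contour-length weight, `>= 0`.
#' @param nu_area area weight, `>= 0`.
#' @param dt explicit time step.
#' @param eps width of the Chan-Vese (arctan/Cauchy) Heaviside and Dirac.
#' @param max_iter iteration budget.
#' @param tol,tol_patience stopping rule as in [evolve_params()]. The
#'   patience default is longer than for the edge-based models: the
#'   Cauchy Dirac moves far-from-contour pixels slowly, so the mask can
#'   sit still for tens of iterations while pixels are in transit toward
#'   a sign change, and a short patience would stop the model before its
#'   region competition has played out.
#' @param track_energy record the discretized energy per iteration.
#' @return object of class `cv_params`.
#' @export
cv_params <- function(lam1 = 1, lam2 = 1, mu_len = 0.2 * 255^2,
                      nu_area = 0, dt = 0.1, eps = 1.5, max_iter = 200L,
                      tol = 1e-3, tol_patience = 30L, track_energy = TRUE) {
  stopifnot(lam1 > 0, lam2 > 0, mu_len >= 0, nu_area >= 0, dt > 0, eps > 0,
            max_iter >= 1)
  structure(list(lam1 = lam1, lam2 = lam2, mu_len = mu_len,
                 nu_area = nu_area, dt = dt, eps = eps,
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_patience = as.integer(tol_patience),
                 track_energy = isTRUE(track_energy)),
            class = "cv_params")
}
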