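# The three evolution models: Chan-Vese (region-based baseline), DRLSE
# (edge-based baseline), and the shape-prior-guided model that adds an
# adaptive-band prior penalty to the DRLSE energy.
#
# Sign convention throughout: the segmented object (lumen) is {phi < 0}.

#' Chan-Vese smoothed Heaviside (arctan form)
#'
#' The mollifier used by the Chan-Vese model:
#' `H_eps(x) = (1/2)(1 + (2/pi) atan(x/eps))`. Unlike the compact cosine
#' Heaviside of DRLSE, its derivative [cv_dirac()] has unbounded support, so
#' the region-competition force acts (weakly) on every level curve — the
#' property that lets Chan-Vese detect contours far from the initial one.
#'
#' @param x numeric scalar/vector/matrix.
#' @param eps width parameter, `> 0`.
#' @return values in `(0, 1)` shaped like `x`.
#' @export
cv_heaviside <- function(x, eps = 1.5) {
  stopifnot(eps > 0)
  0.5 * (1 + (2 / pi) * atan(x / eps))
}

#' Chan-Vese smoothed Dirac (Cauchy kernel)
#'
#' Derivative of [cv_heaviside()]: `eps / (pi (eps^2 + x^2))`.
#'
#' @inheritParams cv_heaviside
#' @return positive values shaped like `x`.
#' @export
cv_dirac <- function(x, eps = 1.5) {
  stopifnot(eps > 0)
  eps / (pi * (eps^2 + x^2))
}

#' Inside/outside region means of the Chan-Vese model
#'
#' Smoothed region averages `c1` (inside, `{phi < 0}`) and `c2` (outside)
#' with weights `H_eps(-phi)` and `H_eps(phi)` (compact cosine Heaviside, so
#' the means are effectively hard region means up to the `2*eps` transition
#' band). If one region is (numerically) empty its mean falls back to the
#' global image mean and the result carries `attr(, "degenerate") = TRUE`.
#'
#' @param img numeric intensity matrix.
#' @param phi level-set matrix on the same grid.
#' @param eps Heaviside width.
#' @return named numeric vector `c(c1 = , c2 = )`.
#' @export
cv_region_means <- function(img, phi, eps = 1.5) {
  check_same_grid(img, phi, "img and phi")
  w_in  <- smoothed_heaviside(-phi, eps)
  w_out <- smoothed_heaviside(phi, eps)
  s_in <- sum(w_in); s_out <- sum(w_out)
  degenerate <- FALSE
  if (s_in < 1e-8) {
    c1 <- mean(img); degenerate <- TRUE
    warning("inside region is empty; c1 set to the global mean", call. = FALSE)
  } else c1 <- sum(img * w_in) / s_in
  if (s_out < 1e-8) {
    c2 <- mean(img); degenerate <- TRUE
    warning("outside region is empty; c2 set to the global mean", call. = FALSE)
  } else c2 <- sum(img * w_out) / s_out
  structure(c(c1 = c1, c2 = c2), degenerate = degenerate)
}

new_segmentation_result <- function(phi, n_iter, energy_trace, converged,
                                    model, params, diagnostic = NULL) {
  gm <- grad_mag(phi)
  band <- abs(phi) < 3
  structure(list(
    final_phi = phi,
    mask = phi < 0,
    n_iter = n_iter,
    energy_trace = energy_trace,
    converged = converged,
    model = model,
    params = params,
    diagnostic = diagnostic,
    grad_band_mean = if (any(band)) mean(gm[band]) else NA_real_
  ), class = "lumenseg_result")
}

#' @export
print.lumenseg_result <- function(x, ...) {
  cat(sprintf("<lumenseg_result: %s>\n", x$model))
  cat(sprintf("  iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  mask area : %d px\n", sum(x$mask)))
  if (length(x$energy_trace))
    cat(sprintf("  energy    : %.4g -> %.4g\n",
                x$energy_trace[1], x$energy_trace[length(x$energy_trace)]))
  if (!is.na(x$grad_band_mean))
    cat(sprintf("  mean |grad phi| near contour: %.3f\n", x$grad_band_mean))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

# shared stopping rule: relative symmetric difference of consecutive masks
# below tol for tol_patience consecutive iterations. The counter only arms
# once the mask has changed at least once: a binary-step initialization
# leaves the contour static for the first few iterations while the
# distance regularizer builds a ramp into the Dirac band, and that
# warm-up must not be mistaken for convergence.
.stop_tracker <- function(tol, patience) {
  streak <- 0L
  engaged <- FALSE
  function(mask, prev_mask) {
    sd_area <- sum(xor(mask, prev_mask))
    engaged <<- engaged || sd_area > 0L
    if (!engaged) return(FALSE)
    rel <- sd_area / max(sum(mask), 1L)
    streak <<- if (rel < tol) streak + 1L else 0L
    streak >= patience
  }
}

#' Chan-Vese evolution
#'
#' Piecewise-constant region-based active contour. Each iteration refreshes
#' the region means and performs the explicit descent step
#' `phi <- phi + dt * delta(phi) * (mu_len*curv(phi) + nu_area +
#' lam1*(I-c1)^2 - lam2*(I-c2)^2)` (inside = `{phi < 0}`, so pixels closer
#' to `c1` are pushed inward). `phi_init` should be a signed distance (see
#' [signed_distance()]); the Chan-Vese model has no distance regularizer to
#' repair a binary step.
#'
#' @param img numeric intensity matrix.
#' @param phi_init initial level-set matrix on the same grid.
#' @param params a [cv_params()] object.
#' @return a `lumenseg_result`.
#' @export
cv_evolve <- function(img, phi_init, params = cv_params()) {
  check_same_grid(img, phi_init, "img and phi_init")
  stopifnot(inherits(params, "cv_params"))
  nrow(img) >= 8 && ncol(img) >= 8 ||
    stop("image too small for evolution (min 8x8)", call. = FALSE)
  phi <- phi_init
  ones <- matrix(1, nrow(img), ncol(img))
  trace <- if (params$track_energy) numeric(params$max_iter) else numeric(0)
  should_stop <- .stop_tracker(params$tol, params$tol_patience)
  prev_mask <- phi < 0
  converged <- FALSE; diagnostic <- NULL; k <- 0L
  while (k < params$max_iter) {
    k <- k + 1L
    cm <- suppressWarnings(cv_region_means(img, phi, params$eps))
    dd <- cv_dirac(phi, params$eps)
    force <- dd * (params$mu_len * curvature_flow(phi, ones) +
                   params$nu_area +
                   params$lam1 * (img - cm[["c1"]])^2 -
                   params$lam2 * (img - cm[["c2"]])^2)
    phi_new <- phi + params$dt * force
    mask <- phi_new < 0
    if (!any(mask) || all(mask)) {
      diagnostic <- sprintf("zero level set vanished at iteration %d", k)
      k <- k - 1L
      break
    }
    phi <- phi_new
    if (params$track_energy) trace[k] <- cv_energy(img, phi, cm, params)
    if (should_stop(mask, prev_mask)) { converged <- TRUE; prev_mask <- mask; break }
    prev_mask <- mask
  }
  new_segmentation_result(phi, k, trace[seq_len(k)], converged, "cv", params,
                          diagnostic)
}

cv_energy <- function(img, phi, cm, params) {
  dd <- cv_dirac(phi, params$eps)
  h_in <- cv_heaviside(-phi, params$eps)
  params$mu_len * sum(dd * grad_mag(phi)) +
    params$nu_area * sum(h_in) +
    params$lam1 * sum((img - cm[["c1"]])^2 * h_in) +
    params$lam2 * sum((img - cm[["c2"]])^2 * (1 - h_in))
}

#' Shape-prior force
#'
#' Descent direction of the shape energy
#' `beta * sum((H_eps(phi) - H_eps(phi0))^2)`:
#' `-2*beta*delta_eps(phi)*(H_eps(phi)-H_eps(phi0))`. The Dirac factor
#' confines the pull toward the prior to the contour's narrow band and
#' guarantees energy descent. With `literal = TRUE` the force is instead the
#' unmollified `+2*beta*(H_eps(phi)-H_eps(phi0))` variant (kept for
#' comparison; it is not a descent direction of the shape energy).
#'
#' @param phi evolving level-set matrix.
#' @param phi0 prior level-set matrix (signed distance of the prior band).
#' @param beta shape weight, `>= 0`.
#' @param eps Heaviside/Dirac width.
#' @param literal use the unmollified force variant.
#' @return numeric force matrix (zero wherever `H(phi) = H(phi0)`).
#' @export
shape_prior_force <- function(phi, phi0, beta, eps = 1.5, literal = FALSE) {
  check_same_grid(phi, phi0, "phi and phi0")
  stopifnot(beta >= 0)
  dh <- smoothed_heaviside(phi, eps) - smoothed_heaviside(phi0, eps)
  if (literal) 2 * beta * dh
  else -2 * beta * smoothed_dirac(phi, eps) * dh
}

# shared DRLSE / shape-prior iteration engine; phi0 = NULL gives plain DRLSE
ls_evolve_engine <- function(img, phi_init, phi0, params, literal_eq14,
                             model) {
  check_same_grid(img, phi_init, "img and phi_init")
  if (!is.null(phi0)) check_same_grid(img, phi0, "img and phi0")
  stopifnot(inherits(params, "evolve_params"))
  validate_evolve_params(params)
  nrow(img) >= 8 && ncol(img) >= 8 ||
    stop("image too small for evolution (min 8x8)", call. = FALSE)
  g <- edge_indicator(img, params$sigma)
  phi <- phi_init
  trace <- if (params$track_energy) numeric(params$max_iter) else numeric(0)
  should_stop <- .stop_tracker(params$tol, params$tol_patience)
  prev_mask <- phi < 0
  converged <- FALSE; diagnostic <- NULL; k <- 0L

  step <- function(phi, alpha) {
    pr <- grad_row(phi); pc <- grad_col(phi)
    s <- sqrt(pr^2 + pc^2)
    dpv <- dp_ratio(s)
    # div(dp * grad phi) split as div((dp-1) grad phi) + laplacian(phi):
    # the 5-point Laplacian damps the checkerboard modes that the
    # composition of central-difference divergence and gradient leaves
    # untouched (the standard DRLSE discretization)
    reg <- divergence((dpv - 1) * pr, (dpv - 1) * pc) + laplacian(phi)
    sf <- pmax(s, 1e-10)
    edge <- divergence(g * pr / sf, g * pc / sf)
    dd <- smoothed_dirac(phi, params$eps)
    force <- params$mu * reg + params$lam * (dd * edge) + alpha * (g * dd)
    if (!is.null(phi0))
      force <- force + shape_prior_force(phi, phi0, params$beta, params$eps,
                                         literal = literal_eq14)
    phi + params$dt * force
  }

  while (k < params$max_iter) {
    k <- k + 1L
    phi_new <- step(phi, params$alpha)
    mask <- phi_new < 0
    if (!any(mask) || all(mask)) {
      diagnostic <- sprintf("zero level set vanished at iteration %d", k)
      k <- k - 1L
      break
    }
    phi <- phi_new
    if (params$track_energy)
      trace[k] <- energy_total(img, phi, phi0, params, g = g)
    if (should_stop(mask, prev_mask)) { converged <- TRUE; prev_mask <- mask; break }
    prev_mask <- mask
  }
  # zero-balloon tail: settle the field without the inflationary force
  for (j in seq_len(params$refine_iters)) {
    phi_new <- step(phi, 0)
    mask <- phi_new < 0
    if (!any(mask) || all(mask)) break
    phi <- phi_new
  }
  new_segmentation_result(phi, k, trace[seq_len(k)], converged, model,
                          params, diagnostic)
}

#' Distance-regularized level-set evolution (DRLSE)
#'
#' Edge-based evolution
#' `phi <- phi + dt*(mu*div(dp(|grad phi|) grad phi) +
#' lam*delta(phi)*div(g grad phi / |grad phi|) + alpha*g*delta(phi))`.
#' The double-well regularization keeps `|grad phi| ~ 1` near the contour,
#' so a binary-step initialization (see [binary_step_initial()]) needs no
#' re-initialization. The edge field `g` is computed once from `img`.
#'
#' @param img numeric intensity matrix.
#' @param phi_init initial level-set matrix.
#' @param params an [evolve_params()] object (`beta` is ignored).
#' @return a `lumenseg_result`.
#' @export
drlse_evolve <- function(img, phi_init, params = evolve_params()) {
  ls_evolve_engine(img, phi_init, NULL, params, FALSE, "drlse")
}

#' Shape-prior-guided level-set evolution
#'
#' The DRLSE flow of [drlse_evolve()] plus the shape-prior descent force of
#' [shape_prior_force()], which penalizes deviation of the evolving region
#' from the prior band's region (`beta * sum((H(phi)-H(phi0))^2)`). With
#' `beta = 0` the update is identical, iterate for iterate, to
#' [drlse_evolve()].
#'
#' @inheritParams drlse_evolve
#' @param phi0 prior level-set matrix (signed distance of the prior band,
#'   as produced by [build_shape_prior()] or [auto_initialize()]).
#' @param literal_eq14 use the unmollified shape-force variant (see
#'   [shape_prior_force()]).
#' @return a `lumenseg_result`.
#' @export
proposed_evolve <- function(img, phi_init, phi0, params = evolve_params(),
                            literal_eq14 = FALSE) {
  ls_evolve_engine(img, phi_init, phi0, params, literal_eq14, "proposed")
}

#' Total discretized energy of the shape-prior model
#'
#' `mu*Rp + lam*Lg + alpha*Ag + beta*sum((H(phi)-H(phi0))^2)` where
#' `Rp = sum(p(|grad phi|))` (double-well), `Lg = sum(g delta(phi)
#' |grad phi|)` (edge-weighted length), `Ag = sum(g H(-phi))`
#' (edge-weighted inside area). Used for monitoring descent, not for line
#' search. With `phi0 = NULL` the shape term is omitted (plain DRLSE
#' energy).
#'
#' @param img numeric intensity matrix.
#' @param phi level-set matrix.
#' @param phi0 prior level-set matrix or `NULL`.
#' @param params an [evolve_params()] object.
#' @param g optional precomputed edge field (recomputed from `img` if
#'   `NULL`).
#' @return scalar energy.
#' @export
energy_total <- function(img, phi, phi0 = NULL, params = evolve_params(),
                         g = NULL) {
  check_same_grid(img, phi, "img and phi")
  if (is.null(g)) g <- edge_indicator(img, params$sigma)
  gm <- grad_mag(phi)
  dd <- smoothed_dirac(phi, params$eps)
  e <- params$mu * sum(double_well(gm)) +
    params$lam * sum(g * dd * gm) +
    params$alpha * sum(g * smoothed_heaviside(-phi, params$eps))
  if (!is.null(phi0)) {
    dh <- smoothed_heaviside(phi, params$eps) -
      smoothed_heaviside(phi0, params$eps)
    e <- e + params$beta * sum(dh^2)
  }
  e
}
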