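#' KLK5 production rate
#'
#' Input function for KLK5 production: basal production plus direct
#' stimulus-driven production plus linear positive feedback from activated
#' PAR2, `f_K = bK + kappaK * mu + alphaK * Pact`. Identical in both model
#' variants.
#'
#' @param mu External stimulus level (basal PAR2 activation), >= 0.
#' @param Pact Activated PAR2 concentration, >= 0.
#' @param params A [klk_parameters()] object; its own `mu` entry is ignored
#'   in favour of the `mu` argument.
#' @return Non-negative production rate.
#' @export
klk5_production <- function(mu, Pact, params) {
  .check_nonneg(mu, Pact)
  params$bK + params$kappaK * mu + params$alphaK * Pact
}

#' LEKTI production rate
#'
#' Input function for LEKTI production, scaled by the production capability
#' `rhoL`. Model 1 uses linear positive feedback,
#' `f_L = rhoL * (bL + kappaL * mu + alphaL * Pact)`; Model 2 uses
#' saturating negative feedback,
#' `f_L = rhoL * (bL + kappaL * mu) * kI / (kI + alphaL * Pact)`.
#'
#' @inheritParams klk5_production
#' @return Non-negative production rate; non-decreasing in `Pact` for
#'   variant 1, non-increasing for variant 2.
#' @export
lekti_production <- function(mu, Pact, params) {
  .check_nonneg(mu, Pact)
  base <- params$bL + params$kappaL * mu
  if (params$variant == 1) {
    params$rhoL * (base + params$alphaL * Pact)
  } else {
    params$rhoL * base * params$kI / (params$kI + params$alphaL * Pact)
  }
}

.check_nonneg <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("inputs must be finite and non-negative",
          class = "klk_validation_error")
  }
  invisible(NULL)
}

#' Time derivatives of the six-species network
#'
#' Right-hand side of the ODE system. KLK5 self-activation and PAR2
#' activation by KLK5* follow Michaelis-Menten kinetics (the catalyst KLK5*
#' is not consumed); LEKTI binds KLK5* reversibly into an inert complex;
#' every species degrades first-order. Production enters as `f_L` into
#' LEKTI, `f_K` into KLK5, a constant `bP` into PAR2, and the stimulus `mu`
#' as constitutive basal activation of PAR2.
#'
#' @param state Named state vector from [klk_state()] (order
#'   `L, K, Kact, C, P, Pact`).
#' @param params A [klk_parameters()] object (carries `mu`).
#' @return Named numeric vector of the six time derivatives.
#' @export
#' @examples
#' p <- klk_parameters("HC", 1)
#' klk_rhs(klk_state(), p)  # only production terms survive at the origin
klk_rhs <- function(state, params) {
  d <- as.numeric(.rhs_cpp(as.numeric(state[.state_order()]),
                           .par_vec(params), params$variant))
  setNames(d, .state_order())
}

#' Analytic Jacobian of the network
#'
#' Partial derivatives of [klk_rhs()] with respect to the six state
#' components, evaluated exactly from the closed-form kinetics.
#'
#' @inheritParams klk_rhs
#' @return 6 x 6 numeric matrix with rows/columns in state order.
#' @export
klk_jacobian <- function(state, params) {
  J <- .jac_cpp(as.numeric(state[.state_order()]), .par_vec(params),
                params$variant)
  dimnames(J) <- list(.state_order(), .state_order())
  J
}

#' Integrate the network in time
#'
#' Stiff-safe integration (lsoda) of [klk_rhs()] over a strictly increasing
#' time grid, with tight tolerances so trajectories can verify steady
#' states.
#'
#' @inheritParams klk_rhs
#' @param initial Initial state from [klk_state()].
#' @param times Strictly increasing numeric time grid.
#' @param atol,rtol Absolute / relative integration tolerances.
#' @return A tibble with columns `time`, `L`, `K`, `Kact`, `C`, `P`, `Pact`.
#' @export
simulate_klk <- function(params, initial, times, atol = 1e-10, rtol = 1e-8) {
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "klk_validation_error")
  }
  pv <- .par_vec(params)
  variant <- params$variant
  fn <- function(t, y, parms) list(as.numeric(.rhs_cpp(y, pv, variant)))
  out <- deSolve::ode(y = as.numeric(initial[.state_order()]), times = times,
                      func = fn, parms = NULL, method = "lsoda",
                      atol = atol, rtol = rtol, maxsteps = 50000)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(paste0("integration failed (istate = ", diagn[1], ")"),
          class = "klk_integration_error")
  }
  out <- as_tibble(as.data.frame(out))
  names(out) <- c("time", .state_order())
  # clamp integrator-level negative round-off
  out[.state_order()] <- lapply(out[.state_order()], function(v) pmax(v, 0))
  out
}
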