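# Independent plain-R implementation of the network right-hand side, used
# as the oracle against the compiled core. Kept deliberately separate from
# the package code path.
rhs_oracle <- function(state, p) {
  L <- state[["L"]]; K <- state[["K"]]; Ka <- state[["Kact"]]
  C <- state[["C"]]; P <- state[["P"]]; Pa <- state[["Pact"]]
  fK <- p$bK + p$kappaK * p$mu + p$alphaK * Pa
  base <- p$bL + p$kappaL * p$mu
  fL <- if (p$variant == 1) p$rhoL * (base + p$alphaL * Pa)
        else p$rhoL * base * p$kI / (p$kI + p$alphaL * Pa)
  act <- p$kA * Ka * K / (p$mK + K)
  assoc <- p$kon * L * Ka
  dis <- p$koff * C
  pflux <- p$kP * Ka * P / (p$mP + P)
  c(L = fL - assoc + dis - p$deltaL * L,
    K = fK - act - p$deltaK * K,
    Kact = act - assoc + dis - p$deltaKact * Ka,
    C = assoc - dis - p$deltaC * C,
    P = p$bP - pflux - p$deltaP * P,
    Pact = pflux - p$deltaPact * Pa)
}

# Random non-negative state on mixed scales.
random_state <- function() {
  klk_state(L = runif(1, 0, 20), K = runif(1, 0, 80),
            Kact = runif(1, 0, 30), C = runif(1, 0, 30),
            P = runif(1, 0, 40), Pact = runif(1, 0, 40))
}

# Monic polynomial coefficients (highest degree first) from its roots.
poly_from_roots <- function(roots) {
  co <- 1
  for (r in roots) co <- c(co, 0) - c(0, co * r)
  co
}

# Toy bifurcation object for classifier fixtures: `branches` is a list of
# tibbles with columns mu, Pact, stability.
toy_bifurcation <- function(branches, mu_grid) {
  d <- dplyr::bind_rows(branches)
  d <- dplyr::arrange(d, mu, Pact)
  d <- dplyr::mutate(d, L = 0, K = 0, Kact = 0, C = 0, P = 0,
                     leading_re = ifelse(stability == "stable", -1, 1),
                     residual = 0)
  d <- dplyr::group_by(d, mu)
  d <- dplyr::ungroup(dplyr::mutate(d, branch = dplyr::row_number()))
  structure(list(diagram = d, params = NULL, mu_grid = mu_grid),
            class = "klk_bifurcation")
}
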