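#' Analytic zero-activation steady state
#'
#' The subspace `Kact = 0, C = 0` is invariant: with no active KLK5 the
#' remaining balances are linear and solve in closed form. This
#' "low branch" exists for every stimulus level and carries zero
#' inflammation (`Pact = 0`): the stimulus only raises the inactive KLK5
#' and LEKTI pools through their production terms.
#'
#' @param params A [klk_parameters()] object.
#' @return Named state vector (a steady state for any `mu`).
#' @export
low_branch_state <- function(params) {
  klk_state(
    L = lekti_production(params$mu, 0, params) / params$deltaL,
    K = klk5_production(params$mu, 0, params) / params$deltaK,
    Kact = 0, C = 0,
    P = params$bP / params$deltaP,
    Pact = 0
  )
}

# Deterministic multi-start set: the analytic low branch, a
# saturated-activation heuristic (all KLK5 active, PAR2 activation near
# saturation), and a fixed log-spaced grid. No RNG involved.
.default_starts <- function(params, extra = NULL) {
  low <- low_branch_state(params)
  fK_hi <- klk5_production(params$mu, 10 * params$bP / params$deltaP, params)
  high <- klk_state(
    L = low[["L"]] * 0.1,
    K = params$mK * 0.2,
    Kact = max(fK_hi, 1) / params$deltaKact,
    C = low[["L"]] * 0.5,
    P = params$bP / (params$deltaP + params$kP / 2),
    Pact = (params$mu + params$bP) / params$deltaPact
  )
  scales <- pmax(low, 1)
  grid <- as.matrix(expand.grid(f = c(0.05, 0.5, 5),
                                g = c(0.02, 0.2, 2, 20)))
  lattice <- t(apply(grid, 1, function(r) {
    s <- scales * r[["f"]]
    s[c("Kact", "C")] <- r[["g"]]
    s
  }))
  starts <- rbind(matrix(low, nrow = 1), matrix(high, nrow = 1), lattice)
  if (!is.null(extra) && length(extra)) {
    starts <- rbind(starts, do.call(rbind, lapply(extra, as.numeric)))
  }
  starts
}

#' Enumerate steady states by multi-start Newton iteration
#'
#' Damped Newton iteration with the analytic Jacobian is run from a
#' deterministic start set (the analytic low branch, a high-activation
#' heuristic, and a fixed log-spaced lattice); converged roots are merged
#' within a relative dedup tolerance, keeping the lowest-residual
#' representative, and classified via [classify_stability()].
#'
#' @param params A [klk_parameters()] object.
#' @param extra_starts Optional list of additional start states (used for
#'   warm-starting continuation scans).
#' @param residual_tol Maximum allowed `max |rhs|` at a reported root.
#' @param dedup_tol Relative state-space tolerance for merging duplicates.
#' @param maxit Newton iteration cap per start.
#' @return A tibble sorted by `Pact` with columns `L` .. `Pact`, `residual`,
#'   `stability` (`stable` / `unstable` / `marginal`) and
#'   `leading_re` (largest eigenvalue real part, diagnostic). Zero rows (with
#'   a warning) if no start converges.
#' @export
find_steady_states <- function(params, extra_starts = NULL,
                               residual_tol = 1e-9, dedup_tol = 1e-5,
                               maxit = 400L) {
  res <- .enumerate_states(params, extra_starts, dedup_tol, maxit)
  if (nrow(res$roots) == 0L) {
    warn("no steady state found from any start")
  }
  .states_tibble(res)
}

# Lean enumeration used by the scan/sweep hot path: returns a list with the
# roots matrix (sorted by Pact), residuals, stability verdicts and leading
# eigenvalue real parts. Newton is converged well below the reported
# residual tolerance so slow-manifold stall points never masquerade as
# extra roots.
.enumerate_states <- function(params, extra_starts = NULL,
                              dedup_tol = 1e-5, maxit = 400L,
                              newton_tol = 1e-12) {
  starts <- .default_starts(params, extra_starts)
  pv <- .par_vec(params)
  roots <- .enumerate_cpp(starts, pv, params$variant, newton_tol,
                          dedup_tol, maxit)
  if (nrow(roots) > 0L) roots <- roots[order(roots[, 6]), , drop = FALSE]
  n <- nrow(roots)
  stability <- character(n)
  leading <- numeric(n)
  for (i in seq_len(n)) {
    J <- .jac_cpp(roots[i, 1:6], pv, params$variant)
    stability[i] <- routh_hurwitz_verdict(characteristic_polynomial(J))
    leading[i] <- max(Re(eigen(J, only.values = TRUE)$values))
  }
  list(roots = roots[, 1:6, drop = FALSE],
       residual = if (n) roots[, 7] else numeric(),
       stability = stability, leading_re = leading)
}

.states_tibble <- function(res) {
  m <- res$roots
  colnames(m) <- .state_order()
  out <- as_tibble(m)
  out$stability <- res$stability
  out$leading_re <- res$leading_re
  out$residual <- res$residual
  out
}

#' Characteristic polynomial of a square matrix
#'
#' Coefficients of `det(lambda * I - A)` computed by the
#' Faddeev-LeVerrier trace recursion (no eigenvalue solve involved).
#'
#' @param A Square numeric matrix.
#' @return Numeric vector of length `n + 1`, monic, highest degree first.
#' @export
#' @examples
#' characteristic_polynomial(diag(6))  # (lambda - 1)^6
characteristic_polynomial <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A)) {
    abort("A must be a square numeric matrix", class = "klk_validation_error")
  }
  n <- nrow(A)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    ck <- -sum(diag(M)) / k
    coefs[k + 1] <- ck
    M <- M + diag(ck, n)
  }
  coefs
}

#' Routh-Hurwitz stability verdict from polynomial coefficients
#'
#' Builds the Routh array for a real polynomial (highest degree first) and
#' reads stability off the first column: all entries strictly positive
#' (after normalising to a positive leading coefficient) means every root
#' has negative real part; a sign change means some root lies in the right
#' half plane; a first-column entry at zero within tolerance (relative to
#' its row scale) is reported as marginal rather than silently resolved.
#'
#' @param coefs Numeric coefficient vector, leading coefficient nonzero.
#' @param tol Relative tolerance of the marginal band.
#' @return `"stable"`, `"unstable"`, or `"marginal"`.
#' @export
#' @examples
#' routh_hurwitz_verdict(c(1, 3, 3, 1))  # (lambda + 1)^3
routh_hurwitz_verdict <- function(coefs, tol = 1e-9) {
  coefs <- as.numeric(coefs)
  if (length(coefs) < 1L || coefs[1] == 0) {
    abort("leading coefficient must be nonzero",
          class = "klk_validation_error")
  }
  if (coefs[1] < 0) coefs <- -coefs
  n <- length(coefs) - 1L
  if (n == 0L) return("stable")
  ncol_r <- ceiling((n + 1) / 2)
  rows <- matrix(0, nrow = n + 1, ncol = ncol_r + 1)
  r1 <- coefs[seq(1, n + 1, by = 2)]
  r2 <- coefs[seq(2, n + 1, by = 2)]
  rows[1, seq_along(r1)] <- r1
  if (length(r2)) rows[2, seq_along(r2)] <- r2
  overall <- max(abs(coefs))
  special <- FALSE  # any zero pivot / zero row encountered
  first_sig <- c()  # significant first-column entries for sign counting
  for (i in seq_len(n + 1)) {
    if (i > 2L) {
      prev <- rows[i - 1, ]
      prev2 <- rows[i - 2, ]
      piv <- prev[1]
      for (j in seq_len(ncol_r)) {
        rows[i, j] <- (piv * prev2[j + 1] - prev2[1] * prev[j + 1]) / piv
      }
    }
    if (i < n + 1L) {
      scale <- max(abs(rows[i, ]), tol * overall)
      if (all(abs(rows[i, ]) <= tol * overall)) {
        # entire row vanished: replace by the derivative of the auxiliary
        # polynomial formed from the previous row (degree n - i + 2)
        special <- TRUE
        degs <- seq(n - i + 2L, 0L, by = -2L)
        aux <- rows[i - 1L, seq_along(degs)]
        rows[i, ] <- 0
        rows[i, seq_along(degs)] <- aux * degs
      } else if (abs(rows[i, 1]) <= tol * scale) {
        # zero pivot with nonzero row: epsilon substitution
        special <- TRUE
        rows[i, 1] <- tol * scale
      }
      first_sig <- c(first_sig, rows[i, 1])
    } else {
      first_sig <- c(first_sig, rows[i, 1])
    }
  }
  sig <- first_sig[abs(first_sig) > tol * overall]
  sign_changes <- sum(diff(sign(sig)) != 0)
  if (sign_changes > 0L) return("unstable")
  if (special || length(sig) < n + 1L) return("marginal")
  "stable"
}

#' Stability of a steady state
#'
#' Evaluates the analytic Jacobian at a verified steady state, forms its
#' characteristic polynomial, and applies the Routh-Hurwitz criterion. The
#' largest eigenvalue real part is recorded as an independent diagnostic;
#' marginal verdicts are reported as such, never coerced.
#'
#' @param state Steady state vector (order `L, K, Kact, C, P, Pact`).
#' @param params A [klk_parameters()] object.
#' @return One-row tibble: the state components, `stability`, `leading_re`.
#' @export
classify_stability <- function(state, params) {
  J <- klk_jacobian(state, params)
  verdict <- routh_hurwitz_verdict(characteristic_polynomial(J))
  lead <- max(Re(eigen(J, only.values = TRUE)$values))
  tibble(L = state[["L"]], K = state[["K"]], Kact = state[["Kact"]],
         C = state[["C"]], P = state[["P"]], Pact = state[["Pact"]],
         stability = verdict, leading_re = lead)
}
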