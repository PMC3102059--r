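#' Scan steady states over the external stimulus
#'
#' Enumerates and classifies steady states at every point of a stimulus
#' grid, warm-starting each enumeration from the roots found at the
#' previous grid point so branches are followed through folds.
#'
#' @param params A [klk_parameters()] object; its `mu` entry is replaced by
#'   each grid value in turn.
#' @param mu Strictly increasing stimulus grid in `[0, mu_max]`; at least
#'   100 points for publication-style diagrams (not enforced for toy grids).
#' @param ... Passed to [find_steady_states()].
#' @return An object of class `klk_bifurcation`: list with `diagram` (tibble
#'   of `mu`, `branch` (per-mu index by ascending `Pact`), the six state
#'   components, `stability`, `leading_re`, `residual`) and `params`.
#' @export
#' @examples
#' \donttest{
#' p <- klk_parameters("AD-LEKTI/pH", 1, overrides = list(alphaK = 0.5))
#' bd <- scan_mu(p, mu = seq(0, 20, length.out = 101))
#' classify_pattern(bd)
#' }
scan_mu <- function(params, mu = seq(0, 60, length.out = 121), ...) {
  if (any(diff(mu) <= 0) || any(mu < 0)) {
    abort("mu grid must be non-negative and strictly increasing",
          class = "klk_validation_error")
  }
  prev <- NULL
  acc <- vector("list", length(mu))
  for (gi in seq_along(mu)) {
    p <- .with_mu(params, mu[gi])
    res <- .enumerate_states(p, extra_starts = prev, ...)
    n <- nrow(res$roots)
    if (n == 0L) {
      warn(paste0("no steady state found at mu = ", mu[gi]))
      prev <- NULL
      next
    }
    prev <- lapply(seq_len(n), function(i) res$roots[i, ])
    acc[[gi]] <- cbind(mu = mu[gi], branch = seq_len(n), res$roots,
                       leading_re = res$leading_re,
                       residual = res$residual)
    attr(acc[[gi]], "stability") <- res$stability
  }
  keep <- !vapply(acc, is.null, logical(1))
  rows <- if (any(keep)) {
    m <- do.call(rbind, acc[keep])
    colnames(m) <- c("mu", "branch", .state_order(), "leading_re",
                     "residual")
    d <- as_tibble(m)
    d$stability <- unlist(lapply(acc[keep], attr, "stability"))
    select(d, "mu", "branch", dplyr::all_of(.state_order()), "stability",
           "leading_re", "residual")
  } else {
    tibble()
  }
  structure(list(diagram = rows, params = params, mu_grid = mu),
            class = "klk_bifurcation")
}

.with_mu <- function(params, mu) {
  params$mu <- as.numeric(mu)
  params
}

#' @export
print.klk_bifurcation <- function(x, ...) {
  cat("<klk_bifurcation> Model ", x$params$variant, ", ",
      x$params$condition, "; mu in [", min(x$mu_grid), ", ",
      max(x$mu_grid), "], ", length(x$mu_grid), " points\n", sep = "")
  print(x$diagram, ...)
  invisible(x)
}

# Stability of the analytic zero-activation branch at stimulus mu:
# TRUE if stable. Used for bisection refinement of mu_on.
.low_branch_stable <- function(params, mu) {
  p <- .with_mu(params, mu)
  cs <- classify_stability(low_branch_state(p), p)
  cs$stability == "stable"
}

# Does a stable steady state distinct from the zero-activation branch exist
# at stimulus mu? `seed` (a state) warm-starts the search in addition to the
# default start set. Returns the state or NULL.
.high_state_at <- function(params, mu, seed = NULL, pact_gap = 1e-3) {
  p <- .with_mu(params, mu)
  res <- .enumerate_states(p, extra_starts = if (is.null(seed)) NULL
                                             else list(seed))
  ok <- res$stability == "stable" & res$roots[, 6] > pact_gap
  if (!any(ok)) return(NULL)
  setNames(res$roots[max(which(ok)), ], .state_order())
}

.bisect <- function(f, lo, hi, rel_tol = 1e-4) {
  # f(lo) and f(hi) differ; returns the crossing location
  flo <- f(lo)
  while ((hi - lo) > rel_tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (f(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify the bifurcation pattern of a stimulus scan
#'
#' Assigns one of the four canonical patterns and extracts the inflammation
#' threshold `mu_on` (where the zero-activation branch loses stability), the
#' deactivation threshold `mu_off` (smallest stimulus at which a distinct
#' stable inflamed state exists), and the bistability range
#' `delta_mu = mu_on - mu_off` (reported for reversible bistability only):
#'
#' * `reversible_bistable`: bistable window with `0 < mu_off < mu_on`;
#' * `irreversible_bistable`: the inflamed branch persists to `mu = 0`, so
#'   the deactivation threshold lies outside the feasible region;
#' * `continuous_monostable`: a single stable state everywhere, inflammation
#'   growing continuously with stimulus;
#' * `discontinuous_monostable`: monostable at low and high stimulus with an
#'   interior window where no stable state exists.
#'
#' Diagrams that fit none of the templates (this happens in narrow parameter
#' slivers at the boundary between the monostable and bistable regimes) are
#' labelled `unclassified` rather than silently forced into a class.
#'
#' @param x A `klk_bifurcation` from [scan_mu()].
#' @param refine Bisection-refine thresholds between grid points (relative
#'   precision `rel_tol`)? Default `TRUE` when the scan's parameters are
#'   available.
#' @param rel_tol Relative precision of threshold refinement.
#' @param pact_gap Minimum `Pact` for a state to count as inflamed.
#' @return One-row tibble: `pattern`, `mu_on`, `mu_off`, `delta_mu`
#'   (class `klk_bifurcation_summary`).
#' @export
classify_pattern <- function(x, refine = TRUE, rel_tol = 1e-4,
                             pact_gap = 1e-3) {
  stopifnot(inherits(x, "klk_bifurcation"))
  d <- x$diagram
  mu <- x$mu_grid
  if (nrow(d) == 0L) {
    return(.summary_row("unclassified", NA, NA))
  }
  per_mu <- d |>
    group_by(.data$mu) |>
    summarise(
      n_states = n(),
      n_stable = sum(.data$stability == "stable"),
      low_stable = any(.data$Pact <= pact_gap &
                         .data$stability == "stable"),
      high_stable = any(.data$stability == "stable" & .data$Pact > pact_gap),
      stable_pact = if (any(.data$stability == "stable"))
        max(.data$Pact[.data$stability == "stable"]) else NA_real_,
      .groups = "drop"
    ) |>
    arrange(.data$mu)
  # grid points missing from the diagram had no steady state at all
  missing_mu <- setdiff(mu, per_mu$mu)
  no_stable <- length(missing_mu) > 0 || any(per_mu$n_stable == 0L)
  bistable <- per_mu$n_stable >= 2L
  low_unstable_idx <- which(!per_mu$low_stable)

  mu_on <- NA_real_
  if (length(low_unstable_idx)) {
    i <- low_unstable_idx[1]
    mu_on <- per_mu$mu[i]
    if (refine && i > 1L) {
      mu_on <- .bisect(function(m) .low_branch_stable(x$params, m),
                       per_mu$mu[i - 1L], per_mu$mu[i], rel_tol)
    }
  }

  mu_off <- NA_real_
  irreversible <- FALSE
  if (any(bistable)) {
    j <- which(bistable)[1]
    if (j == 1L && mu[1] == 0) {
      irreversible <- TRUE
    } else {
      mu_off <- per_mu$mu[j]
      if (refine && j > 1L) {
        seed_row <- d |> filter(.data$mu == per_mu$mu[j],
                                .data$stability == "stable") |>
          arrange(.data$Pact)
        seed <- unlist(seed_row[nrow(seed_row), .state_order()])
        mu_off <- .bisect(function(m)
          !is.null(.high_state_at(x$params, m, seed, pact_gap)),
          per_mu$mu[j - 1L], per_mu$mu[j], rel_tol)
      }
    }
  }

  pattern <- if (irreversible) {
    "irreversible_bistable"
  } else if (any(bistable) && !is.na(mu_off) && mu_off > 0 &&
             !is.na(mu_on) && mu_off < mu_on) {
    "reversible_bistable"
  } else if (!any(bistable) && no_stable) {
    "discontinuous_monostable"
  } else if (!any(bistable) && all(per_mu$n_stable == 1L)) {
    "continuous_monostable"
  } else {
    "unclassified"
  }
  if (pattern %in% c("continuous_monostable", "discontinuous_monostable")) {
    mu_on <- if (pattern == "continuous_monostable") NA_real_ else mu_on
    mu_off <- NA_real_
  }
  if (pattern == "irreversible_bistable") mu_off <- NA_real_
  .summary_row(pattern, mu_on, mu_off)
}

.summary_row <- function(pattern, mu_on, mu_off) {
  out <- tibble(
    pattern = pattern,
    mu_on = as.numeric(mu_on),
    mu_off = as.numeric(mu_off),
    delta_mu = if (identical(pattern, "reversible_bistable"))
      as.numeric(mu_on) - as.numeric(mu_off) else NA_real_
  )
  class(out) <- c("klk_bifurcation_summary", class(out))
  out
}

#' Sweep bifurcation patterns over feedback-strength pairs
#'
#' Runs [scan_mu()] + [classify_pattern()] on a grid of
#' (`alphaK`, `alphaL`) feedback strengths, producing the pattern map,
#' inflammation-threshold map and bistability-range map for one condition
#' and model variant. Printed parameter ranges are `alphaK` in `[0, 1]` and
#' `alphaL` in `[0, 0.5]` (Model 1) or `[0, 10]` (Model 2).
#'
#' @param condition,variant Passed to [klk_parameters()].
#' @param alphaK,alphaL Numeric ranges (length-2) or explicit grids; default
#'   the printed ranges at `resolution` points.
#' @param resolution Grid points per axis when a range is given.
#' @param mu Stimulus grid handed to [scan_mu()].
#' @param overrides Extra parameter overrides applied to every cell.
#' @param refine Refine thresholds by bisection (slower; default `TRUE`).
#' @return Long-format tibble: `condition`, `variant`, `alphaK`, `alphaL`,
#'   `pattern`, `mu_on`, `mu_off`, `delta_mu`, `max_states` (largest number
#'   of coexisting steady states seen along the cell's scan).
#' @export
sweep_feedback_grid <- function(condition = "HC", variant = 1,
                                alphaK = c(0, 1),
                                alphaL = if (variant == 1) c(0, 0.5)
                                         else c(0, 10),
                                resolution = 21,
                                mu = seq(0, 60, length.out = 121),
                                overrides = list(), refine = TRUE) {
  grid_of <- function(r) {
    if (length(r) == 2L) seq(r[1], r[2], length.out = resolution) else r
  }
  aks <- grid_of(alphaK)
  als <- grid_of(alphaL)
  cells <- tidyr::expand_grid(alphaK = aks, alphaL = als)
  purrr::pmap_dfr(cells, function(alphaK, alphaL) {
    ov <- utils::modifyList(as.list(overrides),
                            list(alphaK = alphaK, alphaL = alphaL))
    p <- klk_parameters(condition, variant, overrides = ov)
    bd <- scan_mu(p, mu = mu)
    sm <- classify_pattern(bd, refine = refine)
    n_per_mu <- dplyr::count(bd$diagram, .data$mu)
    tibble(condition = condition, variant = variant,
           alphaK = alphaK, alphaL = alphaL,
           pattern = sm$pattern, mu_on = sm$mu_on, mu_off = sm$mu_off,
           delta_mu = sm$delta_mu,
           max_states = if (nrow(n_per_mu)) max(n_per_mu$n) else 0L)
  })
}

#' Realized production rates along bifurcation branches
#'
#' For every steady state of a stimulus scan, reports the realized KLK5 and
#' LEKTI production rates `f_K(mu, Pact)` and `f_L(mu, Pact)` paired with
#' the inflammation level, the axes on which model branches are compared
#' with expression data (KLK5 / SPINK5 transcription against the PAR2
#' score).
#'
#' @inheritParams classify_pattern
#' @return Tibble: `mu`, `branch`, `Pact`, `stability`, `f_K`, `f_L`.
#' @export
production_curves <- function(x) {
  stopifnot(inherits(x, "klk_bifurcation"))
  x$diagram |>
    mutate(
      f_K = klk5_production(.data$mu, .data$Pact, x$params),
      f_L = purrr::map2_dbl(.data$mu, .data$Pact,
                            function(m, pa) lekti_production(m, pa,
                                                             x$params))
    ) |>
    select("mu", "branch", "Pact", "stability", "f_K", "f_L")
}

#' Total KLK5-lineage concentration along bifurcation branches
#'
#' Sums inactive KLK5, active KLK5* and the LEKTI-bound complex per branch,
#' the quantity an ELISA against total KLK5 protein would report. On the
#' inflamed branch the total exceeds the zero-activation branch total at the
#' same stimulus.
#'
#' @inheritParams classify_pattern
#' @return Tibble: `mu`, `branch`, `Pact`, `stability`, `total_klk5`.
#' @export
total_klk5_curve <- function(x) {
  stopifnot(inherits(x, "klk_bifurcation"))
  x$diagram |>
    mutate(total_klk5 = .data$K + .data$Kact + .data$C) |>
    select("mu", "branch", "Pact", "stability", "total_klk5")
}
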