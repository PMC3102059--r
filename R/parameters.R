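#' @useDynLib klkbarrier, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by ungroup
#'   summarise across left_join n
#' @importFrom stats median cor quantile prcomp rnorm runif setNames fft
#'   t.test sd approx
"_PACKAGE"

# Fixed ordering of the parameter vector handed to the compiled core.
.param_order <- function() {
  c("kon", "koff", "kA", "kP", "deltaL", "deltaK", "deltaKact", "deltaC",
    "deltaP", "deltaPact", "rhoL", "mK", "mP", "kI", "bP", "bL", "bK",
    "kappaK", "kappaL", "alphaK", "alphaL", "mu")
}

# Fixed ordering of the six state components.
.state_order <- function() c("L", "K", "Kact", "C", "P", "Pact")

# pH-dependent kinetic triple (association, dissociation, KLK5 activation).
# Rates are non-dimensionalised against the pH 4.5 association/dissociation
# rates; near-neutral pH accelerates association and KLK5(*) activation and
# stabilises the LEKTI-KLK5* complex.
.ph_rates <- list(
  "4.5" = c(kon = 1, koff = 1, kA = 10),
  "6.5" = c(kon = 3, koff = 2.5e-1, kA = 50)
)

.conditions <- list(
  "HC"          = list(rhoL = 1,   ph = "4.5"),
  "AD-LEKTI"    = list(rhoL = 0.5, ph = "4.5"),
  "AD-pH"       = list(rhoL = 1,   ph = "6.5"),
  "AD-LEKTI/pH" = list(rhoL = 0.5, ph = "6.5")
)

#' Condition presets for the skin-barrier model
#'
#' The four experimental conditions compare full versus limited (50%) LEKTI
#' production capability and skin-surface pH 4.5 versus 6.5. The pH level
#' sets the LEKTI-KLK5* association/dissociation rates and the KLK5
#' activation rate.
#'
#' @return A tibble with one row per condition: name, LEKTI production
#'   capability `rhoL`, pH label, and the pH-dependent rates `kon`, `koff`,
#'   `kA`.
#' @export
#' @examples
#' condition_presets()
condition_presets <- function() {
  purrr::map_dfr(names(.conditions), function(nm) {
    cn <- .conditions[[nm]]
    ph <- .ph_rates[[cn$ph]]
    tibble(condition = nm, rhoL = cn$rhoL, pH = cn$ph,
           kon = ph[["kon"]], koff = ph[["koff"]], kA = ph[["kA"]])
  })
}

# Nominal parameter values (non-dimensional), before condition and pH
# adjustments. Ties kP = kA, mP = mK, deltaKact = deltaK, deltaPact = deltaP
# are applied in klk_parameters() unless explicitly overridden.
.nominal <- function(variant) {
  p <- list(
    kon = 1, koff = 1, kA = 10, kP = NA_real_,
    deltaL = 0.5, deltaK = 1, deltaKact = NA_real_, deltaC = 0.5,
    deltaP = 0.5, deltaPact = NA_real_,
    rhoL = 1, mK = 50, mP = NA_real_, kI = 5,
    bP = 10, bL = 1, bK = 0,
    kappaK = 0.5, kappaL = if (variant == 1) 0.05 else 0,
    alphaK = 0.5, alphaL = if (variant == 1) 0.25 else 5,
    mu = 0
  )
  p
}

.tied <- c(kP = "kA", mP = "mK", deltaKact = "deltaK", deltaPact = "deltaP")

#' Build a parameter set for one model variant and condition
#'
#' Assembles the nominal rate constants with the condition-specific LEKTI
#' production capability and pH-dependent kinetics, applies the equality
#' ties between KLK5 and PAR2 activation kinetics (`kP = kA`, `mP = mK`) and
#' between active and inactive degradation rates (`deltaKact = deltaK`,
#' `deltaPact = deltaP`), then applies user overrides. An override of a tied
#' name breaks that tie explicitly; overriding only the base name (e.g.
#' `deltaK`) moves the tied partner with it, which is how the degradation
#' rate experiments vary the pairs jointly.
#'
#' @param condition One of `"HC"`, `"AD-LEKTI"`, `"AD-pH"`, `"AD-LEKTI/pH"`.
#' @param variant Model variant: `1` (positive feedback from PAR2* to LEKTI
#'   production) or `2` (negative feedback).
#' @param overrides Named list or vector of parameter values replacing the
#'   defaults (including `mu`, the external stimulus level).
#' @return An object of class `klk_params`: a named list of non-negative
#'   parameter values plus the variant and condition.
#' @export
#' @examples
#' p <- klk_parameters("HC", 1, overrides = list(mu = 2, alphaK = 1))
#' p$kA
klk_parameters <- function(condition = "HC", variant = 1, overrides = list()) {
  if (!condition %in% names(.conditions)) {
    abort(paste0("unknown condition '", condition, "'; expected one of ",
                 paste(names(.conditions), collapse = ", ")),
          class = "klk_config_error")
  }
  if (!variant %in% c(1, 2)) {
    abort("variant must be 1 or 2", class = "klk_config_error")
  }
  overrides <- as.list(overrides)
  bad <- setdiff(names(overrides), .param_order())
  if (length(bad)) {
    abort(paste0("unknown parameter name(s): ", paste(bad, collapse = ", ")),
          class = "klk_config_error")
  }
  p <- .nominal(variant)
  cn <- .conditions[[condition]]
  p$rhoL <- cn$rhoL
  ph <- .ph_rates[[cn$ph]]
  p[c("kon", "koff", "kA")] <- as.list(unname(ph))
  # equality ties, then overrides, then re-tie pairs whose tied member was
  # not itself overridden
  for (nm in names(.tied)) p[[nm]] <- p[[.tied[[nm]]]]
  for (nm in names(overrides)) p[[nm]] <- as.numeric(overrides[[nm]])
  for (nm in names(.tied)) {
    if (!nm %in% names(overrides)) p[[nm]] <- p[[.tied[[nm]]]]
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all parameters must be finite and non-negative",
          class = "klk_validation_error")
  }
  structure(c(p, list(variant = as.integer(variant), condition = condition)),
            class = "klk_params")
}

#' @export
print.klk_params <- function(x, ...) {
  cat("<klk_params> Model ", x$variant, ", ", x$condition,
      " (mu = ", format(x$mu), ")\n", sep = "")
  print(unlist(x[.param_order()]))
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled core.
.par_vec <- function(params) {
  stopifnot(inherits(params, "klk_params"))
  unlist(params[.param_order()], use.names = FALSE)
}

#' Construct a model state vector
#'
#' @param L,K,Kact,C,P,Pact Non-negative concentrations of LEKTI, inactive
#'   KLK5, active KLK5 (KLK5*), the LEKTI-KLK5* complex, inactive PAR2 and
#'   activated PAR2 (PAR2*, the inflammation level).
#' @return A named numeric vector in the fixed component order
#'   `(L, K, Kact, C, P, Pact)`.
#' @export
klk_state <- function(L = 0, K = 0, Kact = 0, C = 0, P = 0, Pact = 0) {
  x <- c(L = unname(L)[1], K = unname(K)[1], Kact = unname(Kact)[1],
         C = unname(C)[1], P = unname(P)[1], Pact = unname(Pact)[1])
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("state components must be finite and non-negative",
          class = "klk_validation_error")
  }
  x
}

#' Convert a degradation rate to a protein half-life in minutes
#'
#' Non-dimensional degradation rates are anchored to physical time through
#' the calibration that a rate of 1 corresponds to a 15-minute half-life
#' (the KLK5 nominal). Exponential decay gives
#' `minutes = reference_minutes * reference_rate / rate`.
#'
#' @param rate Positive degradation rate (non-dimensional units).
#' @param reference_rate,reference_minutes Calibration pair; defaults 1 rate
#'   unit == 15 minutes.
#' @return Half-life in minutes.
#' @export
#' @examples
#' half_life_minutes(c(1, 0.5, 0.2))
half_life_minutes <- function(rate, reference_rate = 1,
                              reference_minutes = 15) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    abort("rate must be positive", class = "klk_validation_error")
  }
  reference_minutes * reference_rate / rate
}
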