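#' The 13-probe inflammatory gene panel
#'
#' Affymetrix hgu133a probes for the seven PAR2 downstream genes used by the
#' PAR2 score: ICAM1 (3 probes), IL8 (2), TNFa (1), CSF2 (2), IL1a (2),
#' IL1b (2) and CCL17 (1).
#'
#' @return Tibble with columns `probe` (13 IDs) and `gene` (7 distinct
#'   labels).
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  tibble(
    probe = c("202637_s_at", "202638_s_at", "215845_s_at",
              "202859_x_at", "211506_s_at",
              "207113_s_at",
              "210228_at", "210229_s_at",
              "208200_at", "210118_s_at",
              "205067_at", "39402_at",
              "207900_at"),
    gene = c("ICAM1", "ICAM1", "ICAM1",
             "IL8", "IL8",
             "TNFa",
             "CSF2", "CSF2",
             "IL1a", "IL1a",
             "IL1b", "IL1b",
             "CCL17")
  )
}

#' Specification of a synthetic expression cohort
#'
#' Defines a cohort whose expression follows a one-dimensional latent
#' "inflammation level": panel and marker probes load linearly on the latent
#' with independent Gaussian noise; background probes are pure noise. Group
#' latent distributions place HC lowest, LAD highest, and NLAD overlapping
#' both. Marker genes encode the reported relationships: SPINK5 loads
#' negatively, KLK7 positively, and KLK5 non-monotonically (mildly positive
#' at low latent, suppressed above a threshold, so high-score samples show
#' low KLK5 without a global negative correlation).
#'
#' @param n_hc,n_lad,n_nlad Group sizes.
#' @param latent Named list of `c(location, scale)` per group.
#' @param panel_loading Loadings of the 13 panel probes on the latent, in
#'   [default_panel()] order (CCL17 largest by default).
#' @param marker_loading Loadings for `SPINK5` and `KLK7`.
#' @param klk5 List with `slope`, `drop_slope`, `threshold` defining the
#'   non-monotone KLK5 response
#'   `slope * z - drop_slope * max(z - threshold, 0)`.
#' @param n_background Background (noise-only) probe count.
#' @param noise_sd Residual standard deviation on every probe.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(
    n_hc = 10, n_lad = 10, n_nlad = 8,
    latent = list(HC = c(0, 0.3), LAD = c(2.5, 0.7), NLAD = c(0.8, 0.8)),
    panel_loading = c(1.0, 0.9, 0.7, 1.1, 1.0, 0.8, 0.7, 0.8, 0.9, 0.8,
                      1.0, 0.9, 1.5),
    marker_loading = c(SPINK5 = -0.8, KLK7 = 0.7),
    klk5 = list(slope = 0.3, drop_slope = 1.2, threshold = 1.5),
    n_background = 2000, noise_sd = 0.5) {
  if (n_hc < 2 || (n_lad + n_nlad) < 2) {
    abort("need >= 2 HC and >= 2 AD samples for axis selection",
          class = "klk_validation_error")
  }
  if (n_background < 1) {
    abort("need at least one background probe",
          class = "klk_validation_error")
  }
  if (length(panel_loading) != 13L) {
    abort("panel_loading must have 13 entries",
          class = "klk_validation_error")
  }
  structure(list(n_hc = n_hc, n_lad = n_lad, n_nlad = n_nlad,
                 latent = latent, panel_loading = panel_loading,
                 marker_loading = marker_loading, klk5 = klk5,
                 n_background = n_background, noise_sd = noise_sd),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic expression cohort
#'
#' Draws per-sample latent inflammation levels by group and builds the
#' expression matrix `loading x latent + noise` for the panel and marker
#' probes plus pure-noise background probes. The latent truth is returned
#' for recovery testing.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param seed Integer seed; the output is fully determined by it.
#' @return List: `data` (an [expr_matrix()]), `truth` (tibble `sample`,
#'   `group`, `latent`), `panel` (the probe panel used).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' dim(cohort$data)
generate_cohort <- function(spec = synthetic_cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  groups <- rep(c("HC", "LAD", "NLAD"),
                c(spec$n_hc, spec$n_lad, spec$n_nlad))
  n <- length(groups)
  z <- vapply(groups, function(g) {
    rnorm(1, spec$latent[[g]][1], spec$latent[[g]][2])
  }, numeric(1))
  samples <- sprintf("S%02d_%s", seq_len(n), groups)
  panel <- default_panel()
  expr_panel <- outer(z, spec$panel_loading) +
    matrix(rnorm(n * 13, 0, spec$noise_sd), n, 13)
  spink5 <- spec$marker_loading[["SPINK5"]] * z +
    rnorm(n, 0, spec$noise_sd)
  klk7 <- spec$marker_loading[["KLK7"]] * z + rnorm(n, 0, spec$noise_sd)
  klk5 <- spec$klk5$slope * z -
    spec$klk5$drop_slope * pmax(z - spec$klk5$threshold, 0) +
    rnorm(n, 0, spec$noise_sd)
  bg <- matrix(rnorm(n * spec$n_background, 0, spec$noise_sd),
               n, spec$n_background)
  m <- cbind(expr_panel, spink5, klk7, klk5, bg)
  colnames(m) <- c(panel$probe, "SPINK5_probe", "KLK7_probe", "KLK5_probe",
                   sprintf("bg_%04d_at", seq_len(spec$n_background)))
  rownames(m) <- samples
  list(data = expr_matrix(m, groups),
       truth = tibble(sample = samples, group = groups, latent = unname(z)),
       panel = panel)
}
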