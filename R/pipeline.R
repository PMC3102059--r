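#' Run an analysis command from a configuration
#'
#' Programmatic equivalent of the command-line interface: dispatches one of
#' the pipeline commands, writes its CSV outputs plus a JSON manifest
#' capturing the fully resolved configuration and seed into `out_dir`, and
#' returns the result invisibly. Commands:
#'
#' * `simulate` — time course from a configured initial state;
#' * `bifurcate` — stimulus scan + pattern summary;
#' * `sweep` — feedback-strength sweep;
#' * `sensitivity` — eFAST of steady-state inflammation;
#' * `synth` — synthetic cohort files;
#' * `score` — bootstrap-PCA PAR2 score of an expression table.
#'
#' @param command One of the command names above.
#' @param config Named list or path to a YAML/JSON file. Recognised keys:
#'   `variant`, `condition`, `parameters` (named overrides), `mu` (scalar
#'   for `simulate`, `c(min, max)` or vector for scans), `times`, `initial`,
#'   `alphaK`, `alphaL`, `resolution`, `n_total`, `B`, `n_background`,
#'   `expression_file`, `label_file`, `orientation`, `cohort` (spec
#'   overrides for `synth`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for stochastic stages.
#' @return The computed object, invisibly.
#' @export
run_pipeline <- function(command, config = list(), out_dir, seed = 1) {
  commands <- c("simulate", "bifurcate", "sweep", "sensitivity", "synth",
                "score")
  if (!command %in% commands) {
    abort(paste0("unknown command '", command, "'; expected one of ",
                 paste(commands, collapse = ", ")),
          class = "klk_config_error")
  }
  cfg <- .read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(command,
    simulate = .cmd_simulate(cfg, out_dir),
    bifurcate = .cmd_bifurcate(cfg, out_dir),
    sweep = .cmd_sweep(cfg, out_dir),
    sensitivity = .cmd_sensitivity(cfg, out_dir, seed),
    synth = .cmd_synth(cfg, out_dir, seed),
    score = .cmd_score(cfg, out_dir, seed)
  )
  manifest <- list(command = command, config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion(
                     "klkbarrier")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "klk_config_error")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML/JSON path",
          class = "klk_config_error")
  }
  known <- c("variant", "condition", "parameters", "mu", "times", "initial",
             "alphaK", "alphaL", "resolution", "n_total", "B",
             "n_background", "expression_file", "label_file", "orientation",
             "cohort", "mu_points", "refine")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "klk_config_error")
  }
  config
}

.cfg_params <- function(cfg) {
  ov <- as.list(cfg$parameters %||% list())
  if (!is.null(cfg$mu) && length(cfg$mu) == 1L) ov$mu <- cfg$mu
  klk_parameters(cfg$condition %||% "HC", cfg$variant %||% 1,
                 overrides = ov)
}

.cfg_mu_grid <- function(cfg) {
  mu <- cfg$mu %||% c(0, 60)
  if (length(mu) == 2L) {
    seq(mu[1], mu[2], length.out = cfg$mu_points %||% 121)
  } else {
    as.numeric(mu)
  }
}

.cmd_simulate <- function(cfg, out_dir) {
  p <- .cfg_params(cfg)
  init <- if (is.null(cfg$initial)) low_branch_state(p)
          else do.call(klk_state, as.list(cfg$initial))
  times <- cfg$times %||% seq(0, 100, by = 0.5)
  tr <- simulate_klk(p, init, times)
  readr::write_csv(tr, file.path(out_dir, "trajectory.csv"))
  tr
}

.cmd_bifurcate <- function(cfg, out_dir) {
  p <- .cfg_params(cfg)
  bd <- scan_mu(p, mu = .cfg_mu_grid(cfg))
  readr::write_csv(bd$diagram, file.path(out_dir, "diagram.csv"))
  readr::write_csv(classify_pattern(bd), file.path(out_dir, "summary.csv"))
  bd
}

.cmd_sweep <- function(cfg, out_dir) {
  variant <- cfg$variant %||% 1
  sw <- sweep_feedback_grid(
    condition = cfg$condition %||% "HC", variant = variant,
    alphaK = cfg$alphaK %||% c(0, 1),
    alphaL = cfg$alphaL %||% if (variant == 1) c(0, 0.5) else c(0, 10),
    resolution = cfg$resolution %||% 21,
    mu = .cfg_mu_grid(cfg),
    overrides = as.list(cfg$parameters %||% list()),
    refine = cfg$refine %||% TRUE
  )
  readr::write_csv(sw, file.path(out_dir, "sweep.csv"))
  sw
}

.cmd_sensitivity <- function(cfg, out_dir, seed) {
  sens <- run_model_sensitivity(
    variant = cfg$variant %||% 1, condition = cfg$condition %||% "HC",
    n_total = cfg$n_total %||% 2000, seed = seed
  )
  readr::write_csv(tidy(sens), file.path(out_dir, "sensitivity.csv"))
  sens
}

.cmd_synth <- function(cfg, out_dir, seed) {
  spec <- do.call(synthetic_cohort_spec, as.list(cfg$cohort %||% list()))
  cohort <- generate_cohort(spec, seed = seed)
  expr <- as_tibble(cohort$data$x, rownames = "sample")
  readr::write_tsv(expr, file.path(out_dir, "expression.tsv"))
  readr::write_csv(tibble(sample = cohort$truth$sample,
                          group = cohort$truth$group),
                   file.path(out_dir, "labels.csv"))
  readr::write_csv(cohort$truth, file.path(out_dir, "latent_truth.csv"))
  cohort
}

.cmd_score <- function(cfg, out_dir, seed) {
  X <- load_expression(cfg$expression_file, cfg$label_file,
                       orientation = cfg$orientation %||% "samples")
  res <- bootstrap_par2_score(X, n_background = cfg$n_background %||% 200,
                              B = cfg$B %||% 200, seed = seed)
  scored <- scale_to_model(res$scores)
  readr::write_csv(scored, file.path(out_dir, "scores.csv"))
  readr::write_csv(res$weights, file.path(out_dir, "weights.csv"))
  res
}
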