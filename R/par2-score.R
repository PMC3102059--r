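#' Construct an expression matrix object
#'
#' Container for a samples-by-probes numeric expression matrix with
#' HC / LAD / NLAD group labels (healthy control, lesional and non-lesional
#' atopic dermatitis).
#'
#' @param x Numeric matrix, samples in rows, probes in columns, both named.
#' @param groups Character vector (or factor) of group labels per sample,
#'   values in `HC`, `LAD`, `NLAD`.
#' @param centered Logical flag: have columns been mean-centred?
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(x, groups, centered = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("x must be a numeric matrix", class = "klk_load_error")
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    abort(paste0("missing value at sample '", rownames(x)[bad[1]],
                 "', probe '", colnames(x)[bad[2]], "'"),
          class = "klk_load_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("x needs sample rownames and probe colnames",
          class = "klk_load_error")
  }
  if (anyDuplicated(colnames(x))) {
    abort(paste0("duplicate probe ID(s): ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]),
                       collapse = ", ")), class = "klk_load_error")
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) {
    abort("one group label per sample required", class = "klk_load_error")
  }
  bad <- setdiff(unique(groups), c("HC", "LAD", "NLAD"))
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")),
          class = "klk_load_error")
  }
  structure(list(x = x, groups = setNames(groups, rownames(x)),
                 centered = isTRUE(centered)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$x), " samples x ", ncol(x$x), " probes (",
      paste(names(table(x$groups)), table(x$groups), sep = ":",
            collapse = ", "), ")",
      if (x$centered) ", centred" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$x)

#' Load an expression matrix and sample labels from tabular files
#'
#' Reads a TSV/CSV expression table (numeric, with an ID column) and a label
#' table mapping every sample to its group. The expression table may be
#' oriented either way; `orientation` states what the rows are.
#'
#' @param expression_file Path to a TSV or CSV (delimiter inferred from the
#'   extension) whose first column holds row IDs.
#' @param label_file CSV/TSV with columns `sample` and `group`.
#' @param orientation `"samples"` if expression rows are samples,
#'   `"probes"` if rows are probes (the matrix is then transposed).
#' @return An [expr_matrix()].
#' @export
load_expression <- function(expression_file, label_file,
                            orientation = c("samples", "probes")) {
  orientation <- match.arg(orientation)
  reader <- function(f) {
    if (grepl("\\.csv$", f, ignore.case = TRUE)) {
      readr::read_csv(f, show_col_types = FALSE)
    } else {
      readr::read_tsv(f, show_col_types = FALSE)
    }
  }
  tab <- reader(expression_file)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(as.data.frame(m), is.numeric, logical(1))]
    abort(paste0("non-numeric expression column(s): ",
                 paste(utils::head(bad, 3), collapse = ", ")),
          class = "klk_load_error")
  }
  rownames(m) <- ids
  if (orientation == "probes") m <- t(m)
  labs <- reader(label_file)
  if (!all(c("sample", "group") %in% names(labs))) {
    abort("label file needs 'sample' and 'group' columns",
          class = "klk_load_error")
  }
  missing <- setdiff(rownames(m), labs$sample)
  if (length(missing)) {
    abort(paste0("unlabelled sample(s): ", paste(missing, collapse = ", ")),
          class = "klk_load_error")
  }
  groups <- labs$group[match(rownames(m), labs$sample)]
  expr_matrix(m, groups)
}

#' Centre expression columns to zero mean
#'
#' Subtracts each probe's mean across samples, the normalisation under which
#' PCA decomposes between-sample variance. Idempotent.
#'
#' @param X An [expr_matrix()].
#' @return The centred [expr_matrix()] (flag set).
#' @export
center_columns <- function(X) {
  stopifnot(inherits(X, "expr_matrix"))
  X$x <- scale(X$x, center = TRUE, scale = FALSE)
  attr(X$x, "scaled:center") <- NULL
  X$centered <- TRUE
  X
}

#' Select the principal component separating AD from HC
#'
#' Among the leading principal components (those jointly explaining at least
#' `var_cap` of the variance, at most `max_k`), picks the axis whose sample
#' scores best separate the AD group (LAD and NLAD pooled) from HC by the
#' absolute Welch t statistic, oriented so the AD mean exceeds the HC mean.
#'
#' @param scores Numeric matrix of PC scores, samples x components.
#' @param groups Group labels per sample (`HC`, `LAD`, `NLAD`).
#' @param sdev Component standard deviations (for the variance cap); if
#'   omitted, taken as the column standard deviations of `scores`.
#' @param var_cap Cumulative-variance cap defining "leading" components.
#' @param max_k Hard cap on the number of components searched.
#' @return List: `index` (selected component), `sign` (+1/-1 orientation),
#'   `statistic` (absolute separation statistic).
#' @export
discriminant_pc <- function(scores, groups, sdev = NULL, var_cap = 0.95,
                            max_k = 10) {
  groups <- as.character(groups)
  is_ad <- groups %in% c("LAD", "NLAD")
  if (sum(is_ad) < 2 || sum(!is_ad) < 2) {
    abort("need at least 2 AD and 2 HC samples", class = "klk_config_error")
  }
  if (is.null(sdev)) sdev <- apply(scores, 2, sd)
  keep <- which(sdev > 1e-12)
  if (!length(keep)) abort("all components degenerate",
                           class = "klk_validation_error")
  cum <- cumsum(sdev[keep]^2) / sum(sdev[keep]^2)
  k <- min(max(which(cum <= var_cap), 1L) + 1L, length(keep), max_k)
  cand <- keep[seq_len(k)]
  stat <- vapply(cand, function(j) {
    abs(t.test(scores[is_ad, j], scores[!is_ad, j])$statistic)
  }, numeric(1))
  j <- as.integer(unname(cand[which.max(stat)]))
  sgn <- if (mean(scores[is_ad, j]) >= mean(scores[!is_ad, j])) 1 else -1
  list(index = j, sign = sgn, statistic = unname(max(stat)))
}

#' Bootstrap-PCA PAR2 score
#'
#' Per-sample inflammation indicator. Each bootstrap repetition draws
#' `n_background` non-panel probes without replacement, joins them with the
#' 13-probe inflammatory panel, runs PCA on the centred submatrix, selects
#' the AD-versus-HC discriminant axis via [discriminant_pc()], and projects
#' samples onto the panel-restricted axis weights. The PAR2 score is the
#' average projection over `B` repetitions; panel weight distributions are
#' summarised per probe.
#'
#' @param X An [expr_matrix()] containing all panel probes.
#' @param panel Probe panel tibble from [default_panel()] (columns `probe`,
#'   `gene`).
#' @param n_background Non-panel probes resampled per repetition.
#' @param B Bootstrap repetitions (desk scale 200; full scale 10000).
#' @param seed Integer seed.
#' @param var_cap,max_k Passed to [discriminant_pc()].
#' @return An object of class `klk_par2_score`: list with `scores` (tibble
#'   `sample`, `group`, `score`), `weights` (tibble `probe`, `gene`,
#'   `median`, `q25`, `q75` over repetitions), and metadata (`B`,
#'   `n_background`, `seed`).
#' @export
bootstrap_par2_score <- function(X, panel = default_panel(),
                                 n_background = 200, B = 200, seed = 1,
                                 var_cap = 0.95, max_k = 10) {
  stopifnot(inherits(X, "expr_matrix"))
  if (B < 1) abort("B must be >= 1", class = "klk_config_error")
  if (nrow(panel) < 1) abort("panel is empty", class = "klk_config_error")
  missing <- setdiff(panel$probe, colnames(X$x))
  if (length(missing)) {
    abort(paste0("panel probe(s) absent: ", paste(missing, collapse = ", ")),
          class = "klk_config_error")
  }
  bg_pool <- setdiff(colnames(X$x), panel$probe)
  if (n_background > length(bg_pool)) {
    abort("n_background exceeds available non-panel probes",
          class = "klk_config_error")
  }
  Xc <- center_columns(X)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  n <- nrow(Xc$x)
  scores_mat <- matrix(0, n, B)
  weights_mat <- matrix(0, nrow(panel), B,
                        dimnames = list(panel$probe, NULL))
  for (b in seq_len(B)) {
    bg <- sample(bg_pool, n_background, replace = FALSE)
    sub <- Xc$x[, c(bg, panel$probe), drop = FALSE]
    pc <- prcomp(sub, center = FALSE, scale. = FALSE)
    sel <- discriminant_pc(pc$x, Xc$groups, sdev = pc$sdev,
                           var_cap = var_cap, max_k = max_k)
    w <- sel$sign * pc$rotation[panel$probe, sel$index]
    weights_mat[, b] <- w
    scores_mat[, b] <- Xc$x[, panel$probe, drop = FALSE] %*% w
  }
  wsum <- tibble(
    probe = panel$probe, gene = panel$gene,
    median = apply(weights_mat, 1, median),
    q25 = apply(weights_mat, 1, quantile, 0.25),
    q75 = apply(weights_mat, 1, quantile, 0.75)
  )
  structure(list(
    scores = tibble(sample = rownames(Xc$x),
                    group = unname(Xc$groups),
                    score = rowMeans(scores_mat)),
    weights = wsum,
    B = B, n_background = n_background, seed = seed
  ), class = "klk_par2_score")
}

#' @export
print.klk_par2_score <- function(x, ...) {
  cat("<klk_par2_score> ", nrow(x$scores), " samples, B = ", x$B,
      ", n_background = ", x$n_background, "\n", sep = "")
  print(x$scores, ...)
  invisible(x)
}

#' Scale PAR2 scores against a reference group
#'
#' Subtracts the reference-group median (HC by default) and applies an
#' optional multiplicative factor, so the reference group centres at zero —
#' the model's zero-inflammation baseline — for overlaying data on model
#' bifurcation curves.
#'
#' @param scores Tibble with columns `sample`, `group`, `score` (e.g.
#'   `$scores` of [bootstrap_par2_score()]).
#' @param reference Reference group label (default `"HC"`).
#' @param factor Multiplicative scale applied after centring.
#' @return The input tibble with an added `scaled_score` column.
#' @export
scale_to_model <- function(scores, reference = "HC", factor = 1) {
  ref <- scores$score[scores$group == reference]
  if (!length(ref)) {
    abort(paste0("no samples in reference group '", reference, "'"),
          class = "klk_config_error")
  }
  mutate(scores, scaled_score = (.data$score - median(ref)) * factor)
}

#' Association between PAR2 score and a gene's expression
#'
#' Spearman rank correlation between per-sample scores and one expression
#' column, with a sign verdict — the check behind the reported negative
#' SPINK5 and positive KLK7 relationships.
#'
#' @param scores Numeric vector of PAR2 scores.
#' @param expression Numeric vector, same samples, same order.
#' @return One-row tibble: `rho`, `sign` (`"positive"`, `"negative"`, or
#'   `"undefined"` for constant input).
#' @export
score_gene_association <- function(scores, expression) {
  if (length(scores) != length(expression)) {
    abort("inputs must align", class = "klk_validation_error")
  }
  if (sd(expression) == 0 || sd(scores) == 0) {
    warn("constant input; correlation undefined")
    return(tibble(rho = NA_real_, sign = "undefined"))
  }
  rho <- cor(scores, expression, method = "spearman")
  tibble(rho = rho,
         sign = if (rho > 0) "positive" else if (rho < 0) "negative"
                else "undefined")
}
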