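make_cohort <- function(seed = 11) generate_cohort(seed = seed)

test_that("expression loading round-trips both orientations and validates", {
  co <- make_cohort()
  tmp <- withr::local_tempdir()
  expr_f <- file.path(tmp, "expr.tsv")
  lab_f <- file.path(tmp, "labels.csv")
  readr::write_tsv(tibble::as_tibble(co$data$x, rownames = "sample"),
                   expr_f)
  readr::write_csv(tibble::tibble(sample = rownames(co$data$x),
                                  group = co$data$groups), lab_f)
  X <- load_expression(expr_f, lab_f, orientation = "samples")
  expect_equal(dim(X), dim(co$data$x))
  expect_equal(X$x, co$data$x)
  # transposed file with the probes orientation flag gives the same matrix
  expr_t <- file.path(tmp, "expr_t.tsv")
  readr::write_tsv(tibble::as_tibble(t(co$data$x), rownames = "probe"),
                   expr_t)
  Xt <- load_expression(expr_t, lab_f, orientation = "probes")
  expect_equal(Xt$x, X$x)
  # an unlabelled sample is named in the error
  labs_bad <- tibble::tibble(sample = rownames(co$data$x)[-1],
                             group = co$data$groups[-1])
  lab_bad_f <- file.path(tmp, "labels_bad.csv")
  readr::write_csv(labs_bad, lab_bad_f)
  expect_error(load_expression(expr_f, lab_bad_f),
               regexp = rownames(co$data$x)[1], class = "klk_load_error")
  # duplicate probes and missing values are load errors
  m <- co$data$x
  expect_error(expr_matrix(cbind(m, m[, 1, drop = FALSE]), co$data$groups),
               class = "klk_load_error")
  m[2, 3] <- NA
  expect_error(expr_matrix(m, co$data$groups), class = "klk_load_error")
})

test_that("column centring is exact and idempotent", {
  co <- make_cohort()
  Xc <- center_columns(co$data)
  expect_lt(max(abs(colMeans(Xc$x))), 1e-10)
  expect_true(Xc$centered)
  Xcc <- center_columns(Xc)
  expect_equal(Xcc$x, Xc$x)
  m <- matrix(c(1, 3, 5, 5), 2, 2,
              dimnames = list(c("a", "b"), c("p1", "p2")))
  cc <- center_columns(expr_matrix(m, c("HC", "HC")))
  expect_equal(unname(cc$x[, "p1"]), c(-1, 1))
  expect_equal(unname(cc$x[, "p2"]), c(0, 0))
})

test_that("discriminant axis finds a known separating direction", {
  set.seed(3)
  groups <- rep(c("HC", "LAD"), each = 10)
  sep <- ifelse(groups == "LAD", 3, 0) + rnorm(20, 0, 0.3)
  scores <- cbind(sep, matrix(rnorm(20 * 4, 0, 0.3), 20, 4))
  sel <- discriminant_pc(scores, groups)
  expect_equal(sel$index, 1L)
  expect_equal(sel$sign, 1)
  flip <- discriminant_pc(-scores, groups)
  expect_equal(flip$sign, -1)
  # permuted labels almost always separate worse than the true labels
  stat_true <- sel$statistic
  worse <- vapply(1:100, function(i) {
    discriminant_pc(scores, sample(groups))$statistic < stat_true
  }, logical(1))
  expect_gte(mean(worse), 0.95)
  expect_error(discriminant_pc(scores, rep("HC", 20)),
               class = "klk_config_error")
})

test_that("bootstrap score recovers the latent inflammation level", {
  co <- make_cohort()
  res <- bootstrap_par2_score(co$data, B = 200, seed = 3)
  expect_equal(nrow(res$scores), nrow(co$data$x))
  rho <- cor(res$scores$score, co$truth$latent, method = "spearman")
  expect_gt(rho, 0.9)
  # HC at background level, most LAD above all HC
  hc <- res$scores$score[res$scores$group == "HC"]
  lad <- res$scores$score[res$scores$group == "LAD"]
  expect_gt(mean(lad > max(hc)), 0.5)
  # determinism and the B = 1 degenerate case
  res2 <- bootstrap_par2_score(co$data, B = 200, seed = 3)
  expect_identical(res$scores, res2$scores)
  res1 <- bootstrap_par2_score(co$data, B = 1, seed = 5)
  expect_equal(nrow(res1$scores), nrow(co$data$x))
  expect_error(bootstrap_par2_score(co$data, B = 0),
               class = "klk_config_error")
  expect_error(bootstrap_par2_score(co$data, n_background = 10^6),
               class = "klk_config_error")
})

test_that("bootstrap scores are stable in the repetition count", {
  co <- make_cohort()
  r200 <- bootstrap_par2_score(co$data, B = 200, seed = 3)
  r400 <- bootstrap_par2_score(co$data, B = 400, seed = 13)
  gap <- median(r200$scores$score[r200$scores$group == "LAD"]) -
    median(r200$scores$score[r200$scores$group == "HC"])
  expect_lt(max(abs(r400$scores$score - r200$scores$score)), 0.05 * gap)
})

test_that("panel weight summaries single out a dominant gene", {
  # CCL17 has the largest loading in the default generator
  co <- make_cohort()
  res <- bootstrap_par2_score(co$data, B = 100, seed = 2)
  expect_equal(nrow(res$weights), 13L)
  top <- res$weights$gene[which.max(abs(res$weights$median))]
  expect_equal(top, "CCL17")
  expect_true(all(res$weights$q25 <= res$weights$median))
  expect_true(all(res$weights$median <= res$weights$q75))
})

test_that("reference scaling centres HC at zero and ignores shifts", {
  co <- make_cohort()
  res <- bootstrap_par2_score(co$data, B = 50, seed = 8)
  sc <- scale_to_model(res$scores)
  expect_equal(median(sc$scaled_score[sc$group == "HC"]), 0)
  shifted <- dplyr::mutate(res$scores, score = score + 42)
  sc2 <- scale_to_model(shifted)
  expect_equal(sc2$scaled_score, sc$scaled_score)
  expect_gt(median(sc$scaled_score[sc$group == "LAD"]), 0)
  expect_error(scale_to_model(res$scores, reference = "XX"),
               class = "klk_config_error")
})

test_that("marker associations carry the reported signs", {
  co <- make_cohort()
  res <- bootstrap_par2_score(co$data, B = 100, seed = 4)
  s <- res$scores$score
  expect_equal(score_gene_association(s, co$data$x[, "SPINK5_probe"])$sign,
               "negative")
  expect_equal(score_gene_association(s, co$data$x[, "KLK7_probe"])$sign,
               "positive")
  self <- score_gene_association(s, s)
  expect_equal(self$rho, 1)
  expect_warning(out <- score_gene_association(s, rep(1, length(s))),
                 "constant")
  expect_equal(out$sign, "undefined")
})
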