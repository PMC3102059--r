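mu_toy <- seq(0, 1, by = 0.05)

test_that("toy diagrams classify into the four canonical patterns", {
  low <- tibble::tibble(mu = mu_toy[mu_toy <= 0.6], Pact = 0,
                        stability = "stable")
  high <- tibble::tibble(mu = mu_toy[mu_toy >= 0.2], Pact = 1,
                         stability = "stable")
  mid <- tibble::tibble(mu = mu_toy[mu_toy >= 0.2 & mu_toy <= 0.6],
                        Pact = 0.5, stability = "unstable")
  rev <- classify_pattern(toy_bifurcation(list(low, mid, high), mu_toy),
                          refine = FALSE)
  expect_equal(rev$pattern, "reversible_bistable")
  expect_equal(rev$mu_on, 0.65, tolerance = 0.11)  # first grid point past 0.6
  expect_equal(rev$mu_off, 0.2, tolerance = 1e-9)
  expect_equal(rev$delta_mu, rev$mu_on - rev$mu_off)

  high0 <- tibble::tibble(mu = mu_toy, Pact = 1, stability = "stable")
  mid0 <- tibble::tibble(mu = mu_toy[mu_toy <= 0.6], Pact = 0.5,
                         stability = "unstable")
  irr <- classify_pattern(toy_bifurcation(list(low, mid0, high0), mu_toy),
                          refine = FALSE)
  expect_equal(irr$pattern, "irreversible_bistable")
  expect_true(is.na(irr$mu_off))
  expect_true(is.na(irr$delta_mu))

  ramp <- tibble::tibble(mu = mu_toy, Pact = mu_toy, stability = "stable")
  mono <- classify_pattern(toy_bifurcation(list(ramp), mu_toy),
                           refine = FALSE)
  expect_equal(mono$pattern, "continuous_monostable")
  expect_true(is.na(mono$mu_on))

  lowgap <- tibble::tibble(mu = mu_toy[mu_toy <= 0.3], Pact = 0,
                           stability = "stable")
  highgap <- tibble::tibble(mu = mu_toy[mu_toy >= 0.7], Pact = 1,
                            stability = "stable")
  disc <- classify_pattern(toy_bifurcation(list(lowgap, highgap), mu_toy),
                           refine = FALSE)
  expect_equal(disc$pattern, "discontinuous_monostable")
})

test_that("stimulus scans meet their structural contracts", {
  p <- klk_parameters("HC", 1)
  grid <- seq(0, 60, length.out = 101)
  bd <- scan_mu(p, mu = grid)
  expect_s3_class(bd, "klk_bifurcation")
  expect_equal(sort(unique(bd$diagram$mu)), grid)
  expect_true(all(bd$diagram$residual < 1e-9))
  by_mu <- dplyr::group_by(bd$diagram, mu)
  expect_true(all(dplyr::summarise(by_mu,
                                   ok = all(diff(Pact) >= 0))$ok))
  expect_error(scan_mu(p, mu = c(1, 0.5)), class = "klk_validation_error")
})

test_that("nominal HC scan is reversibly bistable with ordered thresholds", {
  bd <- scan_mu(klk_parameters("HC", 1), mu = seq(0, 60, length.out = 121))
  sm <- classify_pattern(bd)
  expect_equal(sm$pattern, "reversible_bistable")
  expect_lt(sm$mu_off, sm$mu_on)
  expect_gt(sm$mu_off, 0)
  expect_equal(sm$delta_mu, sm$mu_on - sm$mu_off)
  counts <- dplyr::count(bd$diagram, mu)
  expect_equal(max(counts$n), 3L)
})

test_that("AD conditions lower the inflammation threshold below HC", {
  grids <- seq(0, 60, length.out = 121)
  mu_on <- vapply(c("HC", "AD-LEKTI", "AD-pH", "AD-LEKTI/pH"),
                  function(cn) {
    classify_pattern(scan_mu(klk_parameters(cn, 1), mu = grids))$mu_on
  }, numeric(1))
  expect_lt(mu_on[["AD-LEKTI"]], mu_on[["HC"]])
  expect_lt(mu_on[["AD-pH"]], mu_on[["HC"]])
  expect_lt(mu_on[["AD-LEKTI/pH"]], min(mu_on[["AD-LEKTI"]],
                                        mu_on[["AD-pH"]]))
})

test_that("stronger KLK5 feedback widens the bistable range", {
  grid <- seq(0, 60, length.out = 101)
  sm <- lapply(c(0.4, 0.7, 1), function(ak) {
    classify_pattern(scan_mu(
      klk_parameters("HC", 1, overrides = list(alphaK = ak)), mu = grid))
  })
  d <- vapply(sm, function(s) s$delta_mu, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("pattern labels are stable under doubling the grid resolution", {
  p <- klk_parameters("AD-LEKTI", 1)
  s1 <- classify_pattern(scan_mu(p, mu = seq(0, 40, length.out = 101)))
  s2 <- classify_pattern(scan_mu(p, mu = seq(0, 40, length.out = 201)))
  expect_equal(s1$pattern, s2$pattern)
  expect_equal(s1$mu_on, s2$mu_on, tolerance = 1e-2)
  expect_equal(s1$mu_off, s2$mu_off, tolerance = 1e-2)
})

test_that("production curves respect feedback direction and rhoL scaling", {
  grid <- seq(0, 40, length.out = 81)
  bd1 <- scan_mu(klk_parameters("HC", 1), mu = grid)
  pc1 <- production_curves(bd1)
  # positive feedback: f_K increases with Pact at fixed mu
  ord <- dplyr::summarise(dplyr::group_by(pc1, mu),
                          ok = all(diff(f_K[order(Pact)]) >= 0) || dplyr::n() == 1)
  expect_true(all(ord$ok))
  # AD-LEKTI realizes exactly half the HC LEKTI production at matched input
  adl <- klk_parameters("AD-LEKTI", 1)
  hc <- klk_parameters("HC", 1)
  expect_equal(lekti_production(12, 7, adl), 0.5 * lekti_production(12, 7, hc))
  # Model 2: inflamed branch has lower f_L than the zero branch at same mu
  bd2 <- scan_mu(klk_parameters("HC", 2), mu = grid)
  pc2 <- production_curves(bd2)
  cmp <- dplyr::summarise(
    dplyr::group_by(pc2, mu),
    ok = dplyr::n() == 1 || f_L[which.max(Pact)] < f_L[which.min(Pact)]
  )
  expect_true(all(cmp$ok))
})

test_that("total KLK5 lineage is higher on the inflamed branch", {
  grid <- seq(0, 60, length.out = 101)
  bd <- scan_mu(klk_parameters("HC", 1), mu = grid)
  tot <- total_klk5_curve(bd)
  expect_true(all(tot$total_klk5 >= 0))
  stable2 <- dplyr::filter(tot, stability == "stable")
  bist <- dplyr::filter(dplyr::count(stable2, mu), n >= 2)$mu
  expect_gt(length(bist), 0)
  for (m in bist) {
    rows <- dplyr::filter(stable2, mu == m)
    expect_gt(rows$total_klk5[which.max(rows$Pact)],
              rows$total_klk5[which.min(rows$Pact)])
  }
  # zero state at zero stimulus carries no KLK5 material (bK = 0)
  p0 <- klk_parameters("HC", 1, overrides = list(mu = 0))
  expect_equal(sum(low_branch_state(p0)[c("K", "Kact", "C")]), 0)
})

test_that("feedback sweep returns the full grid with coherent labels", {
  sw <- sweep_feedback_grid("HC", 1, alphaK = c(0.3, 0.9),
                            alphaL = c(0, 0.2), resolution = 3,
                            mu = seq(0, 60, length.out = 61),
                            refine = FALSE)
  expect_equal(nrow(sw), 9L)
  expect_true(all(sw$pattern %in%
    c("reversible_bistable", "irreversible_bistable",
      "continuous_monostable", "discontinuous_monostable", "unclassified")))
  rev <- dplyr::filter(sw, pattern == "reversible_bistable")
  expect_true(all(rev$mu_off < rev$mu_on))
  expect_true(all(rev$delta_mu > 0))
})
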