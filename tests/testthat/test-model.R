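test_that("production functions reproduce their defining values", {
  hc <- klk_parameters("HC", 1)
  expect_equal(klk5_production(0, 0, hc), 0)
  expect_equal(klk5_production(1, 0, hc), 0.5)
  expect_equal(klk5_production(1, 2, hc), 0.5 + hc$alphaK * 2)
  expect_equal(lekti_production(0, 0, hc), 1)
  adl <- klk_parameters("AD-LEKTI", 1)
  expect_equal(lekti_production(0, 0, adl), 0.5)
  # rhoL scaling is exact at any matched input
  for (mu in c(0, 3, 17)) for (pa in c(0, 2, 9)) {
    expect_equal(lekti_production(mu, pa, adl),
                 0.5 * lekti_production(mu, pa, hc))
  }
  expect_error(klk5_production(-1, 0, hc), class = "klk_validation_error")
  expect_error(lekti_production(0, -2, hc), class = "klk_validation_error")
})

test_that("variant feedback contract: Model 1 rises, Model 2 falls in Pact", {
  m1 <- klk_parameters("HC", 1)
  m2 <- klk_parameters("HC", 2)
  pacts <- c(0, 0.5, 2, 10, 100)
  for (mu in c(0, 5, 30)) {
    f1 <- vapply(pacts, function(pa) lekti_production(mu, pa, m1),
                 numeric(1))
    f2 <- vapply(pacts, function(pa) lekti_production(mu, pa, m2),
                 numeric(1))
    expect_true(all(diff(f1) >= 0))
    expect_true(all(diff(f2) <= 0))
    expect_true(all(f1 >= f1[1]))
    expect_true(all(f2 <= f2[1]))
  }
  # Model 2 inhibition floor: large Pact drives production towards zero,
  # strictly below the Pact = 0 level
  expect_lt(lekti_production(0, 1e6, m2), 1e-3)
  expect_lt(lekti_production(0, 1e6, m2), lekti_production(0, 0, m2))
})

test_that("rhs matches the independent oracle and mass-action bookkeeping", {
  p <- klk_parameters("HC", 1, overrides = list(mu = 0))
  expect_equal(klk_rhs(klk_state(), p),
               c(L = 1, K = 0, Kact = 0, C = 0, P = 10, Pact = 0))
  set.seed(21)
  for (i in 1:25) {
    prm <- klk_parameters(sample(c("HC", "AD-pH", "AD-LEKTI"), 1),
                          sample(1:2, 1),
                          overrides = list(mu = runif(1, 0, 40)))
    st <- random_state()
    expect_equal(klk_rhs(st, prm), rhs_oracle(st, prm), tolerance = 1e-12)
    # association flux enters dL and dKact with -1 and dC with +1:
    # isolate it by differencing against the L = 0 state
    st0 <- st; st0[["L"]] <- 0
    d1 <- klk_rhs(st, prm); d0 <- klk_rhs(st0, prm)
    assoc <- prm$kon * st[["L"]] * st[["Kact"]]
    expect_equal(d1[["C"]] - d0[["C"]], assoc)
    expect_equal(d1[["Kact"]] - d0[["Kact"]], -assoc)
    # KLK5-lineage flux balance: d(K + Kact + C)/dt equals production minus
    # the three degradation fluxes (activation/binding only move material)
    fK <- klk5_production(prm$mu, st[["Pact"]], prm)
    expect_equal(d1[["K"]] + d1[["Kact"]] + d1[["C"]],
                 fK - prm$deltaK * st[["K"]] -
                   prm$deltaKact * st[["Kact"]] - prm$deltaC * st[["C"]])
  }
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(4)
  worst <- 0
  for (i in 1:100) {
    prm <- klk_parameters(sample(c("HC", "AD-pH", "AD-LEKTI/pH"), 1),
                          sample(1:2, 1),
                          overrides = list(mu = runif(1, 0, 30)))
    st <- random_state()
    J <- klk_jacobian(st, prm)
    h <- 1e-6
    Jfd <- matrix(0, 6, 6)
    for (j in 1:6) {
      up <- st; up[j] <- up[j] + h * max(1, st[j])
      dn <- st; dn[j] <- dn[j] - h * max(1, st[j])
      Jfd[, j] <- (rhs_oracle(up, prm) - rhs_oracle(dn, prm)) /
        (up[j] - dn[j])
    }
    rel <- max(abs(J - Jfd)) / max(abs(J))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian limits at degenerate states", {
  p <- klk_parameters("HC", 1)
  st <- klk_state(L = 3, K = 20, Kact = 0, C = 1, P = 12, Pact = 2)
  expect_equal(klk_jacobian(st, p)["P", "P"], -p$deltaP)
  st2 <- klk_state(L = 3, K = 0, Kact = 4, C = 1, P = 12, Pact = 2)
  expect_equal(klk_jacobian(st2, p)["Kact", "K"], p$kA * 4 / p$mK)
})

test_that("trajectories stay on fixed points, return after kicks, and stay
           non-negative", {
  p <- klk_parameters("HC", 1, overrides = list(mu = 0))
  low <- low_branch_state(p)
  tr <- simulate_klk(p, low, times = seq(0, 50, by = 1))
  expect_lt(max(abs(t(as.matrix(tr[, -1])) - low)), 1e-6)
  # 1% kick off the stable zero-inflammation state relaxes back
  kicked <- klk_state(L = low[["L"]] * 1.01, K = 0.01, Kact = 0.01,
                      C = 0, P = low[["P"]] * 0.99, Pact = 0.01)
  tr2 <- simulate_klk(p, kicked, times = c(0, 200))
  expect_lt(max(abs(unlist(tr2[nrow(tr2), -1]) - low)), 1e-5)
  # from the origin everything stays non-negative
  tr3 <- simulate_klk(klk_parameters("AD-pH", 1, overrides = list(mu = 10)),
                      klk_state(), times = seq(0, 40, by = 0.5))
  expect_true(all(as.matrix(tr3[, -1]) >= 0))
  expect_error(simulate_klk(p, low, times = c(0, 0)),
               class = "klk_validation_error")
})

test_that("basal PAR2 level scales linearly with its production rate", {
  p1 <- klk_parameters("HC", 1, overrides = list(mu = 0))
  p2 <- klk_parameters("HC", 1, overrides = list(mu = 0, bP = 20))
  expect_equal(low_branch_state(p2)[["P"]],
               2 * low_branch_state(p1)[["P"]])
  expect_equal(low_branch_state(p1)[["P"]], p1$bP / p1$deltaP)
})
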