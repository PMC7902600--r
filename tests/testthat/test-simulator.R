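test_that("event propensities follow the three-channel kinetics", {
  p <- tbl1_params()
  expect_equal(event_rates(0, 0, p), c(selection = 0, division = 0,
                                       mutation = 0))
  r <- event_rates(274, 0, p)
  expect_equal(unname(r["selection"]), 274 / (9 * 365.25 / 12))
  expect_equal(unname(r["selection"]), 1.0002, tolerance = 1e-4)
  expect_equal(unname(event_rates(0, 1000, p)),
               c(0, 2.05, 2.26e-3), tolerance = 1e-12)
  expect_error(event_rates(-1, 0, p), "nonnegative")
  expect_error(simulate_cohort(3, 100, engine = "bogus"))
  expect_error(simulate_cohort(3, 0), "positive")
})

test_that("no del2 cells means no rAML: zero dose and vanishing mutation", {
  co0 <- simulate_cohort(0, 2000, seed = 1)
  expect_equal(co0$n_diagnosed, 0)
  expect_true(all(co0$initial_I == 0))
  p_nomut <- raml_params(mu_sfpi1 = 1e-300)
  co <- simulate_cohort(3, 2000, p_nomut, seed = 2)
  expect_equal(co$n_diagnosed, 0)
})

test_that("exact engine: waiting times are exponential, quiescence is stable", {
  p <- tbl1_params()
  # single active channel (selection from I=1): P(no event by h) = e^{-h/Tp}
  for (h in c(0.5, 1, 2) * p$T_pool) {
    still <- vapply(1:3000, function(i) {
      run_engine(1, 0, h, p, engine = "exact_ssa", seed = 7000 + i)$I == 1
    }, logical(1))
    p0 <- exp(-h / p$T_pool)
    expect_lt(abs(mean(still) - p0), 3 * sqrt(p0 * (1 - p0) / 3000))
  }
  # zero propensities: nothing happens before the horizon
  r <- run_engine(0, 0, 1000, p, engine = "exact_ssa", seed = 1)
  expect_true(is.na(r$t_malignant))
  expect_equal(c(r$I, r$Ip), c(0, 0))
})

test_that("exact engine reproduces the Yule pure-birth expectation", {
  # from one proliferating cell, E[Ip(t)] = e^{bt}; b=2.05e-3, t=700 -> 4.199
  p <- raml_params(mu_sfpi1 = 1e-300)
  ip <- vapply(1:5000, function(i) {
    run_engine(0, 1, 700, p, engine = "exact_ssa", seed = 40000 + i)$Ip
  }, numeric(1))
  expected <- exp(p$b * 700)
  se <- sqrt(expected * (expected - 1) / 5000)
  expect_lt(abs(mean(ip) - expected), 3 * se)
})

test_that("tau-leap engine is accurate on a large pure-birth population", {
  p <- raml_params(mu_sfpi1 = 1e-300)
  expected <- 2000 * exp(p$b * 500)
  ip <- vapply(1:400, function(i) {
    run_engine(0, 2000, 500, p, engine = "adaptive_tau", seed = 90000 + i)$Ip
  }, numeric(1))
  expect_lt(abs(mean(ip) - expected) / expected, 0.01)
})

test_that("tau-leap engine with permanent fallback equals the exact engine", {
  co_t <- simulate_cohort(3, 2000, seed = 31, engine = "adaptive_tau",
                          switch_threshold = .Machine$integer.max)
  co_e <- simulate_cohort(3, 2000, seed = 31, engine = "exact_ssa")
  expect_identical(co_t$n_diagnosed, co_e$n_diagnosed)
  expect_identical(co_t$diagnosis_times, co_e$diagnosis_times)
})

test_that("tau-leap and exact engines agree at cohort level across doses", {
  # epsilon = 0.1 forces genuine leaping for the ~280-cell populations
  for (D in c(1, 3, 6)) {
    ct <- simulate_cohort(D, 1e4, seed = 100 + D, engine = "adaptive_tau",
                          epsilon = 0.1)
    ce <- simulate_cohort(D, 1e4, seed = 100 + D, engine = "exact_ssa")
    expect_true(prop_diff_ok(ct$incidence_pct, ce$incidence_pct, 1e4, 1e4))
    if (ct$n_diagnosed > 50 && ce$n_diagnosed > 50) {
      se <- sqrt(sd(ct$diagnosis_times)^2 / ct$n_diagnosed +
                 sd(ce$diagnosis_times)^2 / ce$n_diagnosed)
      expect_lt(abs(mean(ct$diagnosis_times) - mean(ce$diagnosis_times)),
                4 * se)
    }
  }
})

test_that("stopping at t_s - T_lag is equivalent to the diagnosis inequality", {
  for (seed in c(3, 17)) {
    early <- simulate_cohort(3, 3000, seed = seed, horizon = "early")
    full <- simulate_cohort(3, 3000, seed = seed, horizon = "full")
    expect_identical(early$diagnosed, full$diagnosed)
    expect_identical(early$diagnosis_times, full$diagnosis_times)
  }
})

test_that("incidence is nondecreasing in proliferation and mutation rates", {
  base <- simulate_cohort(3, 1e4, seed = 55)$incidence_pct
  up_b <- simulate_cohort(3, 1e4, raml_params(b = 2.05e-3 * 1.5),
                          seed = 55)$incidence_pct
  up_mu <- simulate_cohort(3, 1e4, raml_params(mu_sfpi1 = 2.26e-6 * 1.5),
                           seed = 55)$incidence_pct
  expect_gte(up_b, base)
  expect_gte(up_mu, base)
})

test_that("low-dose incidence is proportional to the mean del2 number", {
  p <- tbl1_params()
  doses <- c(0.05, 0.1, 0.2)
  n <- 2e5
  ratio <- se <- numeric(3)
  for (i in 1:3) {
    co <- simulate_cohort(doses[i], n, seed = 400 + i)
    ratio[i] <- co$incidence_pct / del2_mean_after_acute(doses[i], p)
    se[i] <- 100 * sqrt(co$incidence_pct / 100 / n) /
      del2_mean_after_acute(doses[i], p)
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(ratio[i] - ratio[j]), 3 * sqrt(se[i]^2 + se[j]^2) +
                0.02 * ratio[i])
})

test_that("cohorts and single mice are reproducible and self-consistent", {
  a <- simulate_cohort(2.6, 3000, seed = 77)
  b <- simulate_cohort(2.6, 3000, seed = 77)
  expect_identical(a$diagnosis_times, b$diagnosis_times)
  expect_identical(a$survival_times, b$survival_times)
  expect_equal(a$incidence_pct, 100 * a$n_diagnosed / a$n)
  expect_equal(length(a$diagnosis_times), a$n_diagnosed)
  expect_true(all(a$diagnosis_times <= a$survival_times[a$diagnosed]))
  mo <- simulate_mouse(2.6, seed = 5)
  expect_identical(mo$diagnosed, !is.na(mo$t_diagnosis))
  if (mo$diagnosed)
    expect_equal(mo$t_diagnosis, mo$t_first_malignant + 154)
})
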