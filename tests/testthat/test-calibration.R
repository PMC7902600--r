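test_that("calibration weights are mouse-count shares", {
  rec <- data.frame(study = 1, dose_Gy = rep(3, 20), incidence_pct = 10,
                    n_mice = 50)
  ds <- raml_dataset(rec, 72)
  expect_equal(incidence_weights(ds), rep(0.05, 20))
  rec2 <- data.frame(study = 1:2, dose_Gy = 3, incidence_pct = 10,
                     n_mice = c(40, 60))
  expect_equal(incidence_weights(raml_dataset(rec2, 72)), c(0.4, 0.6))
  set.seed(1)
  rec3 <- data.frame(study = 1, dose_Gy = 3, incidence_pct = 10,
                     n_mice = sample(30:80, 12))
  expect_equal(sum(incidence_weights(raml_dataset(rec3, 72))), 1)
})

test_that("the weighted cost matches an independent transcription", {
  # perfect fit
  rec <- data.frame(study = 1, dose_Gy = c(1, 3), incidence_pct = c(5, 20),
                    n_mice = c(40, 60))
  ds <- raml_dataset(rec, 72)
  expect_equal(raml_cost(ds, c(5, 20), 72), 0)
  # single record, unit weight: squared residual only
  ds1 <- raml_dataset(data.frame(study = 1, dose_Gy = 3, incidence_pct = 20,
                                 n_mice = 50), 72)
  expect_equal(raml_cost(ds1, 10, 72), 100)
  # onset term alone: n=20, sum(w*A)=10, tau=75, tauhat=70 -> (10/1500*5)^2
  ds2 <- raml_dataset(data.frame(study = 1, dose_Gy = rep(3, 20),
                                 incidence_pct = 10, n_mice = 50), 75)
  expect_equal(raml_cost(ds2, rep(10, 20), 70), (10 / (20 * 75) * 5)^2)
  expect_equal(raml_cost(ds2, rep(10, 20), 70), 1.1111e-3, tolerance = 1e-4)
  expect_error(raml_cost(ds2, rep(10, 20), NA), "tau_hat")
  # oracle: direct second transcription on random inputs
  set.seed(33)
  for (rep in 1:20) {
    k <- sample(5:25, 1)
    rec <- data.frame(study = 1, dose_Gy = runif(k, 0.5, 6),
                      incidence_pct = runif(k, 0, 30),
                      n_mice = sample(30:80, k, replace = TRUE))
    tau <- runif(1, 60, 90); tau_hat <- runif(1, 60, 90)
    A_hat <- runif(k, 0, 30)
    ds <- raml_dataset(rec, tau)
    w <- rec$n_mice / sum(rec$n_mice)
    manual <- 0
    for (i in seq_len(k)) manual <- manual +
        w[i] * (rec$incidence_pct[i] - A_hat[i])^2
    manual <- manual +
      ((sum(w * rec$incidence_pct)) / (k * tau) * (tau - tau_hat))^2
    expect_equal(raml_cost(ds, A_hat, tau_hat), manual, tolerance = 1e-12)
  }
})

test_that("synthetic datasets follow the historical study design", {
  ds <- synthesize_dataset(seed = 3, mice_per_point = 3000)
  expect_s3_class(ds, "raml_dataset")
  expect_equal(nrow(ds$records), 20)
  expect_equal(sort(unique(ds$records$dose_Gy)), c(0.75, 1.5, 3, 4.5, 6))
  expect_equal(unname(table(ds$records$dose_Gy)), rep(4L, 5),
               ignore_attr = TRUE)
  expect_true(all(ds$records$n_mice >= 40 & ds$records$n_mice <= 61))
  expect_gt(ds$tau_ref_weeks, 50)
  expect_lt(ds$tau_ref_weeks, 95)
  # reproducibility
  ds2 <- synthesize_dataset(seed = 3, mice_per_point = 3000)
  expect_identical(ds$records, ds2$records)
  expect_identical(ds$tau_ref_weeks, ds2$tau_ref_weeks)
  # noise off: every study carries the simulated incidence exactly
  ds0 <- synthesize_dataset(seed = 5, mice_per_point = 2000,
                            binomial_noise = FALSE)
  per_dose <- tapply(ds0$records$incidence_pct, ds0$records$dose_Gy,
                     function(x) diff(range(x)))
  expect_true(all(per_dose == 0))
})

test_that("datasets round-trip through the CSV schema", {
  ds <- synthesize_dataset(seed = 3, mice_per_point = 1000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence_csv(ds, path)
  back <- read_incidence_csv(path)
  expect_equal(back$records, ds$records, tolerance = 1e-12)
  expect_equal(back$tau_ref_weeks, ds$tau_ref_weeks, tolerance = 1e-12)
})

test_that("fitting is reproducible and improves on the start values", {
  ds <- synthesize_dataset(seed = 3)
  budget <- list(sa_iters = 30, nm_iters = 30, mice_per_point = 200)
  f1 <- raml_fit(ds, budget = budget, seed = 8)
  f2 <- raml_fit(ds, budget = budget, seed = 8)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$cost, f2$cost)
  # optimizer contract: no worse than the published annealing start values
  ev0 <- ramlsim:::model_eval_dataset(f1$start, ds, raml_params(),
                                      mortality_params(), 200, 8 + 1000L,
                                      "adaptive_tau")
  expect_lte(f1$cost, raml_cost(ds, ev0$A_hat, ev0$tau_hat))
  expect_error(raml_fit(ds, start = rep(NA_real_, 5), budget = budget),
               "finite")
})

test_that("fitting synthetic truth recovers parameters within the CI spans", {
  ds <- synthesize_dataset(seed = 3)  # generated at the best-fit truth
  fit <- raml_fit(ds, seed = 11)      # default desk-scale budget
  est <- coef(fit)
  for (nm in rownames(tbl1_ci)) {
    expect_gte(est[[nm]], tbl1_ci[nm, 1])
    expect_lte(est[[nm]], tbl1_ci[nm, 2])
  }
})

test_that("residual bootstrap yields ordered, reproducible intervals", {
  ds <- synthesize_dataset(seed = 3)
  fit <- raml_fit(ds, budget = list(sa_iters = 50, nm_iters = 50,
                                    mice_per_point = 200), seed = 8)
  bf <- raml_bootstrap(fit, B = 50,
                       budget = list(nm_iters = 20, mice_per_point = 100),
                       seed = 4)
  expect_lte(bf$boot_failures, 10)
  expect_true(all(is.finite(bf$ci95)))
  expect_true(all(bf$ci95[, 1] <= bf$ci95[, 2]))
  expect_equal(dim(bf$boot), c(50L, 5L))
  ci <- confint(bf)
  expect_identical(ci, bf$ci95)
  expect_error(confint(fit), "bootstrap")
})

test_that("zero residuals give degenerate intervals at the point estimate", {
  ds <- synthesize_dataset(seed = 5, mice_per_point = 1000,
                           binomial_noise = FALSE)
  fit <- raml_fit(ds, budget = list(sa_iters = 5, nm_iters = 5,
                                    mice_per_point = 100), seed = 8)
  fit$residuals <- fit$residuals * 0
  fit$tau_residual <- 0
  bf <- raml_bootstrap(fit, B = 50,
                       budget = list(nm_iters = 5, mice_per_point = 100),
                       seed = 4)
  expect_equal(unname(bf$ci95[, 1]), unname(coef(fit)), tolerance = 1e-12)
  expect_equal(unname(bf$ci95[, 2]), unname(coef(fit)), tolerance = 1e-12)
})
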