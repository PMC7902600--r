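#' Incidence dataset container
#'
#' Calibration input: a table of observed rAML incidence records plus one mean
#' onset-time record. The study design mirrors the historical CBA/H
#' experiments: incidence measured after 0.75, 1.5, 3, 4.5 and 6 Gy in several
#' independent studies of 40-61 mice each (20 records in all), and a mean rAML
#' onset time following 4.5 Gy.
#'
#' @param records Data frame with columns `study`, `dose_Gy`,
#'   `incidence_pct`, `n_mice`.
#' @param tau_ref_weeks Mean rAML onset time at `tau_dose_Gy`, weeks.
#' @param tau_dose_Gy Dose of the onset-time record, Gy (default 4.5).
#' @return An object of class `raml_dataset`.
#' @export
raml_dataset <- function(records, tau_ref_weeks, tau_dose_Gy = 4.5) {
  req <- c("study", "dose_Gy", "incidence_pct", "n_mice")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(records$incidence_pct < 0 | records$incidence_pct > 100))
    stop("incidence must be in [0, 100] percent", call. = FALSE)
  if (any(records$n_mice < 1))
    stop("each record needs at least one mouse", call. = FALSE)
  if (!is.numeric(tau_ref_weeks) || length(tau_ref_weeks) != 1L ||
      !is.finite(tau_ref_weeks) || tau_ref_weeks <= 0)
    stop("'tau_ref_weeks' must be a single positive number", call. = FALSE)
  structure(list(records = records[req],
                 tau_ref_weeks = tau_ref_weeks, tau_dose_Gy = tau_dose_Gy),
            class = "raml_dataset")
}

#' @export
print.raml_dataset <- function(x, ...) {
  cat(sprintf("rAML incidence dataset: %d records, doses {%s} Gy\n",
              nrow(x$records),
              paste(sort(unique(x$records$dose_Gy)), collapse = ", ")))
  cat(sprintf("  mean onset %.1f weeks at %.2g Gy\n",
              x$tau_ref_weeks, x$tau_dose_Gy))
  invisible(x)
}

#' Per-record calibration weights
#'
#' Each record's weight is its share of the total number of mice,
#' `w_i = n_i / sum(n_j)`; the weights sum to one.
#'
#' @param dataset A [raml_dataset()] object.
#' @return Numeric weight vector.
#' @export
incidence_weights <- function(dataset) {
  n <- dataset$records$n_mice
  tot <- sum(n)
  if (tot <= 0) stop("dataset has no mice", call. = FALSE)
  n / tot
}

#' Weighted residual-sum-of-squares calibration cost
#'
#' `sum(w_i * (A_i - Ahat_i)^2) + ((sum(w_i * A_i) / (n * tau)) *
#' (tau - tauhat))^2`, where `A` are the observed incidence percentages,
#' `Ahat` the modeled ones, `tau` the observed mean onset time at the
#' reference dose and `tauhat` the modeled one. The onset residual is scaled
#' by the weighted mean incidence and divided by `n * tau` so that both data
#' types enter on comparable scale.
#'
#' @param dataset A [raml_dataset()] object.
#' @param A_hat Modeled incidence percentages, one per record.
#' @param tau_hat Modeled mean onset time at the reference dose, weeks.
#' @return Nonnegative scalar cost.
#' @export
raml_cost <- function(dataset, A_hat, tau_hat) {
  if (length(A_hat) != nrow(dataset$records))
    stop("'A_hat' must have one value per record", call. = FALSE)
  if (is.null(tau_hat) || length(tau_hat) != 1L || is.na(tau_hat))
    stop("a modeled mean onset time 'tau_hat' is required", call. = FALSE)
  w <- incidence_weights(dataset)
  A <- dataset$records$incidence_pct
  tau <- dataset$tau_ref_weeks
  n <- nrow(dataset$records)
  sum(w * (A - A_hat)^2) +
    (sum(w * A) / (n * tau) * (tau - tau_hat))^2
}

## Modeled incidence per record and onset time at the reference dose, with
## common random numbers: the same crn_seed is used for every parameter
## vector, so the stochastic cost surface is a fixed deterministic function.
model_eval_dataset <- function(pvec, dataset, base_params, mortality,
                               mice_per_point, crn_seed, engine, ...) {
  p <- tryCatch(set_fit_params(base_params, pvec), error = function(e) NULL)
  if (is.null(p)) return(NULL)
  doses <- sort(unique(c(dataset$records$dose_Gy, dataset$tau_dose_Gy)))
  inc <- numeric(length(doses))
  tau_hat <- NA_real_
  for (i in seq_along(doses)) {
    co <- simulate_cohort(doses[i], mice_per_point, p, mortality,
                          seed = crn_seed + i, engine = engine, ...)
    inc[i] <- co$incidence_pct
    if (doses[i] == dataset$tau_dose_Gy && co$n_diagnosed >= 2L)
      tau_hat <- onset_stats(co)$mean_weeks
  }
  list(A_hat = inc[match(dataset$records$dose_Gy, doses)], tau_hat = tau_hat)
}

#' Calibrate the five model constants to an incidence dataset
#'
#' Minimises [raml_cost()] over `(alpha, beta, mu_del2, mu_sfpi1, b)` on the
#' log scale (the constants span four orders of magnitude and must stay
#' positive). The parameter space is first explored globally with simulated
#' annealing (`optim(method = "SANN")` with a Gaussian proposal on the log
#' parameters), then refined locally with Nelder-Mead from the annealing
#' optimum. Every cost evaluation simulates the cohorts with common random
#' numbers, so the objective is deterministic given `seed` and the fit is
#' bitwise reproducible.
#'
#' @param dataset A [raml_dataset()] object.
#' @param start Numeric start vector `(alpha, beta, mu_del2, mu_sfpi1, b)`;
#'   the default is the published annealing start
#'   (0.01, 0.01, 0.01, 24e-7, 24e-4).
#' @param budget List with `sa_iters` (annealing cost evaluations),
#'   `nm_iters` (Nelder-Mead iteration cap) and `mice_per_point` (cohort size
#'   per dose per cost evaluation). Defaults are desk-scale; raise towards the
#'   published budgets (10000 annealing iterations, 1e3-1e5 mice per point)
#'   for production fits.
#' @param params Fixed-constant template ([raml_params()]); only `H0`,
#'   `T_pool`, `T_lag` are taken from it.
#' @param mortality A [mortality_params()] object.
#' @param seed Master seed for the common-random-number stream and annealing.
#' @param engine Simulation engine, see [simulate_cohort()].
#' @param proposal_sd SD of the annealing's Gaussian proposal on log
#'   parameters.
#' @param ... Passed to [simulate_cohort()].
#' @return Object of class `raml_fit` with elements `par` (named best-fit
#'   vector), `cost`, `residuals` (per record), `tau_residual`, `A_hat`,
#'   `tau_hat`, `start`, `budget`, `seed` and the dataset.
#' @seealso [raml_bootstrap()] for confidence intervals.
#' @export
raml_fit <- function(dataset,
                     start = c(alpha = 0.01, beta = 0.01, mu_del2 = 0.01,
                               mu_sfpi1 = 24e-7, b = 24e-4),
                     budget = list(sa_iters = 200, nm_iters = 150,
                                   mice_per_point = 500),
                     params = raml_params(), mortality = mortality_params(),
                     seed = 1, engine = "adaptive_tau", proposal_sd = 0.4,
                     ...) {
  stopifnot(inherits(dataset, "raml_dataset"), length(start) == 5L)
  budget <- modifyList(list(sa_iters = 200, nm_iters = 150,
                            mice_per_point = 500), as.list(budget))
  if (budget$sa_iters < 0 || budget$nm_iters <= 0 ||
      budget$mice_per_point <= 0)
    stop("budgets must be positive", call. = FALSE)
  crn_seed <- seed + 1000L

  objective <- function(theta) {
    ev <- model_eval_dataset(exp(theta), dataset, params, mortality,
                             budget$mice_per_point, crn_seed, engine, ...)
    if (is.null(ev) || is.na(ev$tau_hat)) return(1e8)  # infeasible region
    raml_cost(dataset, ev$A_hat, ev$tau_hat)
  }

  theta0 <- log(unname(start))
  if (!is.finite(objective(theta0)))
    stop("cost is not finite at the start values", call. = FALSE)

  theta_best <- with_local_seed(seed, {
    sa <- if (budget$sa_iters > 1)
      optim(theta0, objective, method = "SANN",
            gr = function(th) th + rnorm(5L, 0, proposal_sd),
            control = list(maxit = budget$sa_iters, temp = 1, tmax = 5))
    else list(par = theta0)
    optim(sa$par, objective, method = "Nelder-Mead",
          control = list(maxit = budget$nm_iters))$par
  })

  pbest <- exp(theta_best)
  ev <- model_eval_dataset(pbest, dataset, params, mortality,
                           budget$mice_per_point, crn_seed, engine, ...)
  names(pbest) <- c("alpha", "beta", "mu_del2", "mu_sfpi1", "b")
  structure(list(par = pbest,
                 cost = raml_cost(dataset, ev$A_hat, ev$tau_hat),
                 residuals = dataset$records$incidence_pct - ev$A_hat,
                 tau_residual = dataset$tau_ref_weeks - ev$tau_hat,
                 A_hat = ev$A_hat, tau_hat = ev$tau_hat,
                 start = start, budget = budget, seed = seed,
                 engine = engine, dataset = dataset,
                 params = params, mortality = mortality),
            class = "raml_fit")
}

#' @export
print.raml_fit <- function(x, ...) {
  cat("Calibrated two-hit rAML model\n")
  print(signif(x$par, 4))
  cat(sprintf("cost %.4g over %d records (+ onset term); seed %s\n",
              x$cost, nrow(x$dataset$records), format(x$seed)))
  if (!is.null(x$ci95)) {
    cat("bias-corrected 95% bootstrap CIs:\n")
    print(signif(x$ci95, 4))
  }
  invisible(x)
}

#' @export
coef.raml_fit <- function(object, ...) object$par

#' @export
summary.raml_fit <- function(object, ...) {
  out <- data.frame(estimate = object$par)
  if (!is.null(object$ci95)) {
    out$ci_lo <- object$ci95[, 1L]
    out$ci_hi <- object$ci95[, 2L]
  }
  out
}

#' @export
confint.raml_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci95))
    stop("run raml_bootstrap() first to attach bootstrap intervals",
         call. = FALSE)
  if (level != 0.95)
    stop("only 95% bootstrap intervals are stored", call. = FALSE)
  ci <- object$ci95
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Residual-bootstrap confidence intervals for a calibrated model
#'
#' Nonparametric residual bootstrap: `B` replicate datasets are formed from
#' the best-fit model output plus incidence residuals resampled with
#' replacement (clamped to \[0, 100\]); the onset-time record is perturbed by
#' its own residual with a random sign. Each replicate is refit by Nelder-Mead
#' from the best-fit parameters with a reduced budget, and bias-corrected 95%
#' percentile intervals are computed from the replicate estimates.
#'
#' @param fit A [raml_fit()] object.
#' @param B Number of bootstrap replicates (>= 50).
#' @param budget Refit budget (list as in [raml_fit()]; `sa_iters` is forced
#'   to 0 so replicates use Nelder-Mead only).
#' @param seed Seed for residual resampling.
#' @param ... Passed to [simulate_cohort()] during refits.
#' @return The fit with `ci95` (matrix of lower/upper bounds), `boot`
#'   (replicate parameter matrix) and `boot_failures` attached. More than 20%
#'   failed replicates triggers a warning.
#' @export
raml_bootstrap <- function(fit, B = 200,
                           budget = list(nm_iters = 60, mice_per_point = 200),
                           seed = 1, ...) {
  stopifnot(inherits(fit, "raml_fit"))
  if (B < 50) stop("'B' must be at least 50", call. = FALSE)
  budget <- modifyList(fit$budget, as.list(budget))
  budget$sa_iters <- 0

  nrec <- nrow(fit$dataset$records)
  draws <- with_local_seed(seed, {
    list(idx = matrix(sample.int(nrec, nrec * B, replace = TRUE), nrow = B),
         sgn = sample(c(-1, 1), B, replace = TRUE))
  })

  reps <- matrix(NA_real_, B, 5L,
                 dimnames = list(NULL, names(fit$par)))
  failures <- 0L
  for (b in seq_len(B)) {
    recs <- fit$dataset$records
    recs$incidence_pct <- pmin(pmax(
      fit$A_hat + fit$residuals[draws$idx[b, ]], 0), 100)
    tau_b <- max(fit$tau_hat + draws$sgn[b] * fit$tau_residual, 1e-6)
    ds_b <- raml_dataset(recs, tau_b, fit$dataset$tau_dose_Gy)
    fb <- tryCatch(
      raml_fit(ds_b, start = fit$par, budget = budget, params = fit$params,
               mortality = fit$mortality, seed = fit$seed,
               engine = fit$engine, ...),
      error = function(e) NULL)
    if (is.null(fb)) failures <- failures + 1L else reps[b, ] <- fb$par
  }
  if (failures > 0.2 * B)
    warning(failures, " of ", B, " bootstrap refits failed", call. = FALSE)

  ci <- t(vapply(seq_len(5L), function(j) {
    th <- reps[!is.na(reps[, j]), j]
    bc_percentile_ci(th, fit$par[j])
  }, numeric(2L)))
  dimnames(ci) <- list(names(fit$par), c("lo95", "hi95"))
  fit$ci95 <- ci
  fit$boot <- reps
  fit$boot_failures <- failures
  fit
}

## Bias-corrected (BC, not BCa) percentile interval.
bc_percentile_ci <- function(theta_star, theta_hat, level = 0.95) {
  if (!length(theta_star)) return(c(NA_real_, NA_real_))
  prop <- mean(theta_star < theta_hat)
  prop <- min(max(prop, 1 / (length(theta_star) + 1)),
              length(theta_star) / (length(theta_star) + 1))
  z0 <- qnorm(prop)
  zc <- qnorm(c((1 - level) / 2, (1 + level) / 2))
  unname(quantile(theta_star, pnorm(2 * z0 + zc), type = 6, names = FALSE))
}

#' Generate a synthetic incidence dataset from known parameters
#'
#' Stand-in for the historical CBA/H incidence tables (not publicly bundled):
#' simulates the model at each design dose with `mice_per_point` mice to get
#' the true incidence probability, then draws each study's observed count from
#' `Binomial(n_mice, p)`. Study sizes are drawn uniformly from `n_mice_range`.
#' The onset-time reference is the mean diagnosis time of the 4.5 Gy cohort.
#'
#' @param params True [raml_params()] generating the data.
#' @param mortality A [mortality_params()] object.
#' @param doses Design doses, Gy.
#' @param n_studies Number of replicate studies per dose.
#' @param n_mice_range Inclusive range of mice per record.
#' @param mice_per_point Mice simulated per dose to estimate the true
#'   incidence (and the onset reference).
#' @param seed Master seed.
#' @param binomial_noise If `FALSE`, records carry the simulated incidence
#'   exactly (no sampling noise); useful for optimizer contract tests.
#' @param engine,... Passed to [simulate_cohort()].
#' @return A [raml_dataset()] object.
#' @export
synthesize_dataset <- function(params = raml_params(),
                               mortality = mortality_params(),
                               doses = c(0.75, 1.5, 3, 4.5, 6),
                               n_studies = 4, n_mice_range = c(40, 61),
                               mice_per_point = 1e4, seed = 1,
                               binomial_noise = TRUE,
                               engine = "adaptive_tau", ...) {
  with_local_seed(seed, {
    tau_ref <- NA_real_
    rows <- list()
    for (i in seq_along(doses)) {
      co <- simulate_cohort(doses[i], mice_per_point, params, mortality,
                            engine = engine,
                            seed = sample.int(2^30, 1L), ...)
      if (doses[i] == 4.5) tau_ref <- onset_stats(co)$mean_weeks
      n_mice <- sample(seq(n_mice_range[1L], n_mice_range[2L]), n_studies,
                       replace = TRUE)
      obs <- if (binomial_noise)
        100 * stats::rbinom(n_studies, n_mice, co$incidence_pct / 100) / n_mice
      else rep(co$incidence_pct, n_studies)
      rows[[i]] <- data.frame(study = seq_len(n_studies), dose_Gy = doses[i],
                              incidence_pct = obs, n_mice = n_mice)
    }
    if (is.na(tau_ref))
      tau_ref <- evaluate_onset_poly(4.5)$mean_weeks  # design without 4.5 Gy
    raml_dataset(do.call(rbind, rows), tau_ref)
  })
}

#' Read / write incidence datasets as CSV
#'
#' The records go to `path` (columns `study`, `dose_Gy`, `incidence_pct`,
#' `n_mice`); the onset-time reference goes to a single-row companion CSV
#' (default: `path` with `_tau` before the extension) with columns
#' `tau_ref_weeks`, `tau_dose_Gy`.
#'
#' @param dataset A [raml_dataset()] object.
#' @param path Records CSV path.
#' @param tau_path Companion CSV path.
#' @return `read_incidence_csv` returns the dataset; `write_incidence_csv`
#'   returns `path` invisibly.
#' @export
write_incidence_csv <- function(dataset, path,
                                tau_path = sub("(\\.[^.]*)?$", "_tau\\1",
                                               path)) {
  write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(tau_ref_weeks = dataset$tau_ref_weeks,
                       tau_dose_Gy = dataset$tau_dose_Gy),
            tau_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_incidence_csv
#' @export
read_incidence_csv <- function(path,
                               tau_path = sub("(\\.[^.]*)?$", "_tau\\1",
                                              path)) {
  tau <- read.csv(tau_path)
  raml_dataset(read.csv(path), tau$tau_ref_weeks[1L], tau$tau_dose_Gy[1L])
}
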