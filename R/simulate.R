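#' Propensities of the three post-exposure reaction channels
#'
#' Given current counts of intermediate (`I`) and proliferating (`Ip`) del2
#' cells, returns the per-day rates of pool selection (`I/T_pool`), division
#' (`b*Ip`) and malignant transformation (`mu_sfpi1*Ip`).
#'
#' @param I Integer count of non-proliferating del2 intermediates.
#' @param Ip Integer count of proliferating del2 cells.
#' @param params A [raml_params()] object.
#' @return Named numeric vector `c(selection, division, mutation)`, day^-1.
#' @export
event_rates <- function(I, Ip, params = raml_params()) {
  if (!is.numeric(I) || !is.numeric(Ip) || any(I < 0) || any(Ip < 0))
    stop("cell counts must be nonnegative", call. = FALSE)
  c(selection = I / params$T_pool,
    division = params$b * Ip,
    mutation = params$mu_sfpi1 * Ip)
}

engine_code <- function(engine) {
  engine <- match.arg(engine, c("adaptive_tau", "exact_ssa"))
  if (engine == "exact_ssa") 0L else 1L
}

## Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Low-level run of one jump-process trajectory
#'
#' Runs the selection/division/mutation process from an arbitrary state to a
#' horizon with either engine. Exposed mainly for validation; cohort work goes
#' through [simulate_cohort()].
#'
#' @param I,Ip Initial cell counts.
#' @param horizon Time horizon, days.
#' @param params A [raml_params()] object.
#' @param engine `"exact_ssa"` for the statistically exact next-event
#'   algorithm, `"adaptive_tau"` for tau-leaping with exact fallback.
#' @param epsilon Tau-leap error-control parameter in (0, 0.1].
#' @param switch_threshold Fall back to the exact engine whenever any nonzero
#'   population is below this count (tau-leap engine only).
#' @param seed Integer seed for the trajectory's own random stream.
#' @return List with `t_malignant` (days, or `NA` if the mutation did not fire
#'   before the horizon) and the final `I` and `Ip` counts.
#' @export
run_engine <- function(I, Ip, horizon, params = raml_params(),
                       engine = c("exact_ssa", "adaptive_tau"),
                       epsilon = 0.01, switch_threshold = 10, seed = 1) {
  stopifnot(I >= 0, Ip >= 0, is.finite(horizon))
  if (!(epsilon > 0 && epsilon <= 0.1))
    stop("'epsilon' must be in (0, 0.1]", call. = FALSE)
  .engine_run(as.integer(I), as.integer(Ip), horizon,
              params$T_pool, params$b, params$mu_sfpi1,
              engine_code(engine), epsilon, as.integer(switch_threshold),
              as.double(seed))
}

#' Simulate a cohort of in-silico mice at one dose
#'
#' For each mouse: draw an other-cause survival time `t_s` from the
#' skew-normal mortality model, seed `I(0) ~ Pois(I(D))` del2 intermediates,
#' then run the selection/division/mutation jump process to the horizon
#' `t_s - T_lag` (a malignant cell arising later can never be diagnosed, so
#' stopping there is outcome-equivalent to running to `t_s`; set
#' `horizon = "full"` to do the latter, for validation). A mouse is diagnosed
#' when the first malignant cell arises at `t_M` with `t_M + T_lag <= t_s`;
#' the diagnosis time is then `t_M + T_lag`.
#'
#' Mice whose Poisson draw is zero can never be diagnosed and skip the engine
#' entirely, which makes very low doses cheap. Each mouse runs on its own
#' random substream whose seed is drawn from R's stream, so results are
#' reproducible bit-for-bit given `seed` and identical across horizon modes.
#'
#' @param dose Absorbed dose, Gy.
#' @param n Number of mice (>= 1).
#' @param params A [raml_params()] object.
#' @param mortality A [mortality_params()] object.
#' @param engine,epsilon,switch_threshold See [run_engine()]; the default
#'   engine is the adaptive tau-leap with `epsilon = 0.01`.
#' @param seed Master seed; if `NULL`, continues R's current random stream.
#' @param horizon `"early"` (default) or `"full"`, see above.
#' @return An object of class `raml_cohort`: a list with `dose`, `n`,
#'   `n_diagnosed`, `incidence_pct`, `diagnosis_times` (days, diagnosed mice
#'   only), `survival_times` (days, all mice), `initial_I`, and the engine
#'   settings used.
#' @examples
#' \donttest{
#' simulate_cohort(2.6, 2000, seed = 1)  # incidence near the ~22% peak
#' }
#' @export
simulate_cohort <- function(dose, n, params = raml_params(),
                            mortality = mortality_params(),
                            engine = c("adaptive_tau", "exact_ssa"),
                            seed = NULL, epsilon = 0.01, switch_threshold = 10,
                            horizon = c("early", "full")) {
  check_dose(dose)
  stopifnot(length(dose) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  engine <- match.arg(engine)
  horizon <- match.arg(horizon)
  if (!(epsilon > 0 && epsilon <= 0.1))
    stop("'epsilon' must be in (0, 0.1]", call. = FALSE)

  out <- with_local_seed(seed, {
    I0 <- sample_initial_del2(n, dose, params)
    t_s <- sample_survival_time(n, dose, mortality)
    seeds <- runif(n, 0, 2^52)  # one substream per mouse
    list(I0 = I0, t_s = t_s, seeds = seeds)
  })
  hz <- if (horizon == "early") out$t_s - params$T_lag else out$t_s
  t_mal <- .engine_cohort(out$I0, hz, params$T_pool, params$b, params$mu_sfpi1,
                          engine_code(engine), epsilon,
                          as.integer(switch_threshold), out$seeds)
  t_diag <- t_mal + params$T_lag
  diagnosed <- !is.na(t_mal) & t_diag <= out$t_s
  structure(list(dose = dose, n = n,
                 n_diagnosed = sum(diagnosed),
                 incidence_pct = 100 * sum(diagnosed) / n,
                 diagnosis_times = t_diag[diagnosed],
                 survival_times = out$t_s,
                 initial_I = out$I0,
                 diagnosed = diagnosed,
                 engine = engine, epsilon = epsilon,
                 switch_threshold = switch_threshold, seed = seed),
            class = "raml_cohort")
}

#' Simulate a single in-silico mouse
#'
#' Convenience wrapper around the cohort machinery for `n = 1`.
#'
#' @inheritParams simulate_cohort
#' @return A list describing the mouse: `dose`, `t_s` (other-cause survival,
#'   days), `initial_I`, `t_first_malignant` (days or `NA`), `t_diagnosis`
#'   (days or `NA`) and the `diagnosed` flag.
#' @export
simulate_mouse <- function(dose, params = raml_params(),
                           mortality = mortality_params(),
                           engine = c("adaptive_tau", "exact_ssa"),
                           seed = NULL, epsilon = 0.01, switch_threshold = 10) {
  co <- simulate_cohort(dose, 1L, params, mortality, engine = engine,
                        seed = seed, epsilon = epsilon,
                        switch_threshold = switch_threshold)
  diag <- co$n_diagnosed == 1L
  list(dose = dose,
       t_s = co$survival_times[1L],
       initial_I = co$initial_I[1L],
       t_first_malignant = if (diag) co$diagnosis_times[1L] - params$T_lag
                           else NA_real_,
       t_diagnosis = if (diag) co$diagnosis_times[1L] else NA_real_,
       diagnosed = diag)
}

#' @export
print.raml_cohort <- function(x, ...) {
  cat(sprintf("rAML cohort: %d mice at %.3g Gy (%s engine)\n",
              x$n, x$dose, x$engine))
  cat(sprintf("  diagnosed %d (%.2f%%)\n", x$n_diagnosed, x$incidence_pct))
  if (x$n_diagnosed >= 2L) {
    os <- onset_stats(x)
    cat(sprintf("  onset %.1f +/- %.1f weeks\n", os$mean_weeks, os$sd_weeks))
  }
  cat(sprintf("  mean survival %.1f weeks (other-cause and rAML endpoints)\n",
              mean(endpoint_times(x)) / 7))
  invisible(x)
}

#' @export
summary.raml_cohort <- function(object, ...) {
  data.frame(dose_Gy = object$dose, n = object$n,
             n_diagnosed = object$n_diagnosed,
             incidence_pct = object$incidence_pct,
             mean_onset_wk = if (object$n_diagnosed >= 2L)
               onset_stats(object)$mean_weeks else NA_real_,
             sd_onset_wk = if (object$n_diagnosed >= 2L)
               onset_stats(object)$sd_weeks else NA_real_,
             mean_survival_wk = mean(endpoint_times(object)) / 7)
}

#' Per-mouse endpoint times of a cohort
#'
#' The earlier of rAML diagnosis and other-cause death for every mouse, in
#' days. Diagnosed mice die at diagnosis.
#'
#' @param cohort A `raml_cohort` object.
#' @return Numeric vector of length `n`.
#' @export
endpoint_times <- function(cohort) {
  stopifnot(inherits(cohort, "raml_cohort"))
  tt <- cohort$survival_times
  tt[cohort$diagnosed] <- cohort$diagnosis_times
  tt
}
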