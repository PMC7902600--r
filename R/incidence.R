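#' Onset-time statistics of a simulated cohort
#'
#' Mean and sample SD of the rAML diagnosis times of the diagnosed mice,
#' reported in weeks (days / 7). Undiagnosed mice have no onset and are not
#' included.
#'
#' @param cohort A `raml_cohort` object (or any list with a `diagnosis_times`
#'   element in days).
#' @return List with `mean_weeks` and `sd_weeks`.
#' @export
onset_stats <- function(cohort) {
  tt <- cohort$diagnosis_times
  if (length(tt) < 2L)
    stop("onset statistics require at least 2 diagnosed mice", call. = FALSE)
  list(mean_weeks = mean(tt) / 7, sd_weeks = sd(tt) / 7)
}

#' Cumulative rAML incidence over time
#'
#' Step function of diagnoses at or before each grid time, expressed as a
#' percentage of the whole cohort; its final value equals the cohort's
#' incidence once the grid passes the last diagnosis.
#'
#' @param cohort A `raml_cohort` object.
#' @param t_grid_weeks Nondecreasing vector of times, weeks.
#' @return Data frame with columns `week` and `cum_pct`.
#' @export
cumulative_incidence <- function(cohort, t_grid_weeks) {
  if (is.unsorted(t_grid_weeks))
    stop("'t_grid_weeks' must be sorted", call. = FALSE)
  dt_wk <- sort(cohort$diagnosis_times) / 7
  counts <- findInterval(t_grid_weeks, dt_wk)
  data.frame(week = t_grid_weeks, cum_pct = 100 * counts / cohort$n)
}

#' Cubic dose polynomials for the rAML onset-time surface
#'
#' Container for third-order polynomials in dose describing the mean and SD of
#' rAML onset times in weeks, `sum(c_k * D^k, k = 0..3)`. The defaults are the
#' published fits for the CBA/H model (mean: 80.8, -4.44, 0.801, -0.0553; SD:
#' 25.1, -1.23, 0.206, -0.0143).
#'
#' @param mean_coeffs,sd_coeffs Numeric vectors of 4 coefficients
#'   (weeks, weeks/Gy, weeks/Gy^2, weeks/Gy^3).
#' @return An object of class `onset_polys`.
#' @examples
#' evaluate_onset_poly(6, onset_polynomials())$mean_weeks  # ~71 weeks
#' @export
onset_polynomials <- function(mean_coeffs = c(80.8, -4.44, 0.801, -0.0553),
                              sd_coeffs = c(25.1, -1.23, 0.206, -0.0143)) {
  stopifnot(length(mean_coeffs) == 4L, length(sd_coeffs) == 4L,
            is.numeric(mean_coeffs), is.numeric(sd_coeffs))
  structure(list(mean_coeffs = as.numeric(mean_coeffs),
                 sd_coeffs = as.numeric(sd_coeffs)),
            class = "onset_polys")
}

#' @export
print.onset_polys <- function(x, ...) {
  cat("Cubic onset-time polynomials (weeks as a function of dose in Gy)\n")
  cat("  mean:", paste(signif(x$mean_coeffs, 4), collapse = ", "), "\n")
  cat("  sd:  ", paste(signif(x$sd_coeffs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the onset-time polynomials at given doses
#'
#' @param D Dose, Gy (vectorised).
#' @param poly An [onset_polynomials()] object.
#' @return List with `mean_weeks` and `sd_weeks`.
#' @export
evaluate_onset_poly <- function(D, poly = onset_polynomials()) {
  V <- outer(D, 0:3, `^`)
  list(mean_weeks = drop(V %*% poly$mean_coeffs),
       sd_weeks = drop(V %*% poly$sd_coeffs))
}

#' Fit cubic dose polynomials to onset-time summaries
#'
#' Ordinary (unweighted) least squares of a cubic in dose for the mean and for
#' the SD series.
#'
#' @param doses Doses, Gy (at least 4 distinct values).
#' @param means,sds Mean and SD of onset times at each dose, weeks.
#' @return An [onset_polynomials()] object.
#' @export
fit_onset_polynomials <- function(doses, means, sds) {
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct doses for a cubic fit", call. = FALSE)
  f1 <- lm(means ~ doses + I(doses^2) + I(doses^3))
  f2 <- lm(sds ~ doses + I(doses^2) + I(doses^3))
  if (anyNA(coef(f1)) || anyNA(coef(f2)))
    stop("rank-deficient polynomial fit", call. = FALSE)
  onset_polynomials(unname(coef(f1)), unname(coef(f2)))
}

#' Normal-CDF approximation of the cumulative onset-time surface
#'
#' Cumulative fraction of eventual rAML cases diagnosed by week `t` after a
#' dose `D`: `pnorm((t - mu(D)) / sigma(D))`, with `mu`, `sigma` the cubic
#' polynomials. Multiply by the cohort incidence to express an absolute
#' cumulative percentage.
#'
#' @param D Dose, Gy.
#' @param t Time since exposure, weeks (vectorised with `D`).
#' @param poly An [onset_polynomials()] object.
#' @return Cumulative fraction in \[0, 1\].
#' @export
normal_cdf_onset <- function(D, t, poly = onset_polynomials()) {
  ev <- evaluate_onset_poly(D, poly)
  if (any(ev$sd_weeks <= 0))
    stop("onset-time SD polynomial is nonpositive at a queried dose",
         call. = FALSE)
  pnorm((t - ev$mean_weeks) / ev$sd_weeks)
}

#' Dose-response table over a dose grid
#'
#' Simulates one cohort per dose and assembles the standard summary table.
#'
#' @param doses Vector of doses, Gy.
#' @param n Mice per dose.
#' @param params,mortality,engine,seed Passed to [simulate_cohort()]; per-dose
#'   seeds are derived from `seed`.
#' @param ... Further arguments for [simulate_cohort()].
#' @return Data frame with columns `dose_Gy`, `n`, `n_diagnosed`,
#'   `incidence_pct`, `mean_onset_wk`, `sd_onset_wk`, `mean_survival_wk`.
#' @export
dose_response_table <- function(doses, n, params = raml_params(),
                                mortality = mortality_params(),
                                engine = "adaptive_tau", seed = NULL, ...) {
  rows <- lapply(seq_along(doses), function(i) {
    si <- if (is.null(seed)) NULL else seed + i - 1L
    summary(simulate_cohort(doses[i], n, params, mortality, engine = engine,
                            seed = si, ...))
  })
  do.call(rbind, rows)
}

#' Write / read cohort summary tables
#'
#' Plain RFC-4180 CSV with a header row; doses in Gy, onset times in weeks.
#'
#' @param x Data frame as produced by [dose_response_table()] or
#'   [summary.raml_cohort()].
#' @param path File path.
#' @return `read_cohort_csv` returns the data frame; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path)
}
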