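#' Fit a low-dose response form to incidence data
#'
#' Least-squares fit of one of three no-intercept response forms to incidence
#' percentages:
#' \describe{
#'   \item{`"lq"`}{linear-quadratic in dose, `alpha*D + beta*D^2`;}
#'   \item{`"linear"`}{`alpha_L * D`;}
#'   \item{`"del2"`}{proportional to the expected del2 cell number,
#'     `c * I(D)` with `I` from [del2_mean_after_acute()].}
#' }
#' With `log_transform = TRUE` the residuals are taken on log incidence
#' (which down-weights the larger incidence values); zero incidences cannot
#' enter a log fit and are dropped with a warning. Raw fits and the
#' single-coefficient log fits have closed-form solutions; the log-scale LQ
#' fit is nonlinear and solved with [stats::nls()].
#'
#' @param doses Doses, Gy.
#' @param incidence_pct Incidence percentages (same length).
#' @param form One of `"lq"`, `"linear"`, `"del2"`.
#' @param log_transform Fit on log incidence?
#' @param params [raml_params()] supplying `I(D)` for the del2 form.
#' @return Object of class `raml_drfit` with `coefficients` (named:
#'   `alpha`/`beta`, `alpha_L`, or `c`), `form`, `log_transformed`,
#'   `fit_range` and `rss_log` (in-sample RSS on log incidence).
#' @export
fit_dose_response <- function(doses, incidence_pct,
                              form = c("lq", "linear", "del2"),
                              log_transform = FALSE,
                              params = raml_params()) {
  form <- match.arg(form)
  stopifnot(length(doses) == length(incidence_pct))
  keep <- rep(TRUE, length(doses))
  if (log_transform) {
    keep <- incidence_pct > 0
    if (!any(keep)) stop("all incidences are zero; cannot log-fit",
                         call. = FALSE)
    if (any(!keep))
      warning(sum(!keep), " zero-incidence point(s) dropped from log fit",
              call. = FALSE)
  }
  D <- doses[keep]; y <- incidence_pct[keep]
  basis <- switch(form, lq = cbind(D, D^2), linear = cbind(D),
                  del2 = cbind(del2_mean_after_acute(D, params)))

  cf <- if (!log_transform) {
    unname(coef(lm(y ~ 0 + basis)))
  } else if (form == "lq") {
    st <- pmax(unname(coef(lm(y ~ 0 + basis))), 1e-8)
    fit <- nls(log(y) ~ log(a * D + b * D^2),
               start = list(a = st[1L], b = st[2L]),
               lower = c(1e-12, 1e-12), algorithm = "port",
               control = list(warnOnly = TRUE))
    unname(coef(fit))
  } else {
    exp(mean(log(y) - log(basis[, 1L])))  # scale factor, closed form
  }
  names(cf) <- switch(form, lq = c("alpha", "beta"), linear = "alpha_L",
                      del2 = "c")
  obj <- structure(list(coefficients = cf, form = form,
                        log_transformed = log_transform,
                        fit_range = range(D), params = params),
                   class = "raml_drfit")
  obj$rss_log <- rss_log(predict(obj, D), y)
  obj
}

#' @export
predict.raml_drfit <- function(object, doses, ...) {
  cf <- object$coefficients
  switch(object$form,
         lq = cf[["alpha"]] * doses + cf[["beta"]] * doses^2,
         linear = cf[["alpha_L"]] * doses,
         del2 = cf[["c"]] * del2_mean_after_acute(doses, object$params))
}

#' @export
print.raml_drfit <- function(x, ...) {
  cat(sprintf("%s dose-response fit (%s scale), doses %.3g-%.3g Gy\n",
              x$form, if (x$log_transformed) "log" else "raw",
              x$fit_range[1L], x$fit_range[2L]))
  print(signif(x$coefficients, 4))
  cat(sprintf("in-sample RSS_log %.4g\n", x$rss_log))
  invisible(x)
}

#' @export
coef.raml_drfit <- function(object, ...) object$coefficients

#' Residual sum of squares on log incidence
#'
#' `sum((log(observed) - log(predicted))^2)`, the low-dose fit-quality
#' measure.
#'
#' @param predicted_pct,observed_pct Strictly positive incidence percentages.
#' @return Nonnegative scalar.
#' @export
rss_log <- function(predicted_pct, observed_pct) {
  if (any(predicted_pct <= 0) || any(observed_pct <= 0))
    stop("RSS_log needs strictly positive incidences", call. = FALSE)
  sum((log(observed_pct) - log(predicted_pct))^2)
}

#' Low-dose effectiveness factor
#'
#' `LDEF = 1 + (beta/alpha) * D_x`, evaluated by convention at `D_x = 1` Gy:
#' the factor by which a linear extrapolation from high dose overestimates the
#' low-dose slope of a linear-quadratic response.
#'
#' @param alpha Linear coefficient, Gy^-1 (positive).
#' @param beta Quadratic coefficient, Gy^-2.
#' @param D_x Reference dose, Gy.
#' @return Dimensionless factor >= 1 for nonnegative `beta`.
#' @examples
#' ldef(4.70, 6.51)  # 2.39
#' @export
ldef <- function(alpha, beta, D_x = 1) {
  if (any(alpha <= 0)) stop("'alpha' must be positive", call. = FALSE)
  if (any(D_x <= 0)) stop("'D_x' must be positive", call. = FALSE)
  1 + beta / alpha * D_x
}

#' Correct a linear slope by an LDEF
#'
#' @param alpha_L Linear slope, Gy^-1.
#' @param ldef_value LDEF (>= 1).
#' @return Adjusted slope `alpha_L / LDEF`, Gy^-1.
#' @examples
#' apply_ldef(8.61, 2.39)  # 3.60
#' @export
apply_ldef <- function(alpha_L, ldef_value) {
  if (any(ldef_value < 1)) stop("LDEF must be >= 1", call. = FALSE)
  alpha_L / ldef_value
}

#' High-dose-to-low-dose extrapolation study
#'
#' Reproduces the extrapolation experiment at configurable scale: simulate
#' incidence on a low-dose grid (the evaluation target) and on a high-dose
#' grid (0.25-1 Gy, the only data made available for fitting); fit the LQ,
#' linear and del2-proportional forms to the high-dose points with and
#' without log transform; score every fit by its RSS_log against the
#' simulated low-dose incidence; and evaluate the LDEF correction of the
#' linear fits (predictions divided by the LDEF of the same-transform LQ
#' fit at `D_x = 1` Gy).
#'
#' @param params,mortality Model and mortality parameters.
#' @param ld_grid Low-dose evaluation grid, Gy (within 0-0.2).
#' @param hd_grid High-dose fitting grid, Gy (within 0.25-1).
#' @param n_ld,n_hd Mice per dose on each grid.
#' @param seed Master seed.
#' @param engine,... Passed to [simulate_cohort()].
#' @return List of class `raml_extrap` with `table` (one row per fitted form:
#'   `form`, `log_transform`, `alpha`, `beta_or_c`, `ldef`, `rss_log`,
#'   `rss_log_ldef`), `ld` and `hd` simulated dose-response data frames, and
#'   the fit objects.
#' @export
extrapolation_study <- function(params = raml_params(),
                                mortality = mortality_params(),
                                ld_grid = seq(0.02, 0.20, by = 0.02),
                                hd_grid = c(0.25, 0.50, 0.75, 1.00),
                                n_ld = 2e5, n_hd = 1e5, seed = 1,
                                engine = "adaptive_tau", ...) {
  stopifnot(all(ld_grid > 0), all(ld_grid <= 0.2),
            all(hd_grid >= 0.25), all(hd_grid <= 1))
  ld <- dose_response_table(ld_grid, n_ld, params, mortality, engine = engine,
                            seed = seed, ...)
  hd <- dose_response_table(hd_grid, n_hd, params, mortality, engine = engine,
                            seed = seed + length(ld_grid), ...)

  ok <- ld$incidence_pct > 0
  fits <- list(); rows <- list()
  for (lg in c(TRUE, FALSE)) {
    lq <- fit_dose_response(hd$dose_Gy, hd$incidence_pct, "lq",
                            log_transform = lg, params = params)
    lin <- fit_dose_response(hd$dose_Gy, hd$incidence_pct, "linear",
                             log_transform = lg, params = params)
    dl <- fit_dose_response(hd$dose_Gy, hd$incidence_pct, "del2",
                            log_transform = lg, params = params)
    ld_val <- function(fit) rss_log(predict(fit, ld$dose_Gy[ok]),
                                    ld$incidence_pct[ok])
    lq_ldef <- ldef(coef(lq)[["alpha"]], coef(lq)[["beta"]], 1)
    rows[[length(rows) + 1L]] <- data.frame(
      form = c("lq", "linear", "del2"), log_transform = lg,
      alpha = c(coef(lq)[["alpha"]], coef(lin)[["alpha_L"]], NA),
      beta_or_c = c(coef(lq)[["beta"]], NA, coef(dl)[["c"]]),
      ldef = c(lq_ldef, lq_ldef, NA),
      rss_log = c(ld_val(lq), ld_val(lin), ld_val(dl)),
      rss_log_ldef = c(NA,
                       rss_log(predict(lin, ld$dose_Gy[ok]) / lq_ldef,
                               ld$incidence_pct[ok]),
                       NA))
    fits[[if (lg) "log" else "raw"]] <- list(lq = lq, linear = lin, del2 = dl)
  }
  structure(list(table = do.call(rbind, rows), ld = ld, hd = hd, fits = fits,
                 seed = seed),
            class = "raml_extrap")
}

#' @export
print.raml_extrap <- function(x, ...) {
  cat("High-dose to low-dose extrapolation study\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
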