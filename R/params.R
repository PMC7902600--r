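#' Model parameters for the two-hit rAML model
#'
#' Bundles the five calibrated rate constants of the bone-marrow model with the
#' fixed biological constants. Defaults are the published best-fit values for
#' male CBA/H mice.
#'
#' The two-hit chain is: healthy hematopoietic stem cells (`H0` per mouse) are
#' killed by an acute photon dose according to linear-quadratic lethal-lesion
#' kinetics (`alpha`, `beta`); a fraction `mu_del2` of lethal-lesion production
#' instead yields viable cells carrying the chromosome 2 deletion with Sfpi1
#' copy loss (first hit); surviving del2 cells are selected into a
#' proliferating compartment with mean waiting time `T_pool`; proliferating
#' cells divide at rate `b` and acquire the Sfpi1 R235 point mutation (second
#' hit) at rate `mu_sfpi1` per cell, producing the first malignant cell.
#' Diagnosis follows `T_lag` days later.
#'
#' @param alpha Linear lethal-lesion coefficient, Gy^-1.
#' @param beta Quadratic lethal-lesion coefficient, Gy^-2.
#' @param mu_del2 del2 fraction of lethal-lesion production (dimensionless).
#' @param mu_sfpi1 Sfpi1 point-mutation rate per proliferating cell, day^-1.
#' @param b Proliferation rate of pool-selected del2 cells, day^-1.
#' @param H0 Initial number of healthy target cells (HSCs) per mouse.
#' @param T_pool Mean stem-cell-pool selection time, days (9 months).
#' @param T_lag Lag between first malignant cell and diagnosis, days (22 weeks).
#' @return An object of class `raml_params`.
#' @examples
#' p <- raml_params()
#' del2_mean_after_acute(2.6, p)  # ~ 280 cells
#' @export
raml_params <- function(alpha = 0.0402, beta = 0.122, mu_del2 = 0.0498,
                        mu_sfpi1 = 2.26e-6, b = 2.05e-3,
                        H0 = 15670, T_pool = 9 * 365.25 / 12, T_lag = 22 * 7) {
  p <- list(alpha = alpha, beta = beta, mu_del2 = mu_del2,
            mu_sfpi1 = mu_sfpi1, b = b, H0 = H0,
            T_pool = T_pool, T_lag = T_lag)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (abs(H0 - round(H0)) > 1e-8)
    stop("'H0' must be a positive integer", call. = FALSE)
  p$H0 <- round(p$H0)
  structure(p, class = "raml_params")
}

#' @export
print.raml_params <- function(x, ...) {
  cat("Two-hit rAML model parameters\n")
  cat(sprintf("  alpha    %.4g Gy^-1   beta  %.4g Gy^-2   mu_del2 %.4g\n",
              x$alpha, x$beta, x$mu_del2))
  cat(sprintf("  mu_sfpi1 %.4g /day    b     %.4g /day\n", x$mu_sfpi1, x$b))
  cat(sprintf("  H0 %d cells   T_pool %.1f d   T_lag %.0f d\n",
              x$H0, x$T_pool, x$T_lag))
  invisible(x)
}

#' Replace the five calibrated constants in a parameter object
#'
#' @param params A [raml_params()] object supplying the fixed constants.
#' @param pvec Named or positional numeric vector
#'   `(alpha, beta, mu_del2, mu_sfpi1, b)`.
#' @return A new `raml_params` object.
#' @export
set_fit_params <- function(params, pvec) {
  stopifnot(inherits(params, "raml_params"), length(pvec) == 5L)
  pvec <- as.numeric(pvec)
  raml_params(alpha = pvec[1L], beta = pvec[2L], mu_del2 = pvec[3L],
              mu_sfpi1 = pvec[4L], b = pvec[5L],
              H0 = params$H0, T_pool = params$T_pool, T_lag = params$T_lag)
}

#' Dose-dependent skew-normal mortality parameters
#'
#' Non-leukemic survival times of CBA/H mice are drawn from a skew-normal
#' distribution whose location decreases linearly with dose,
#' `xi(D) = xi0 - xi_slope * D`, with fixed scale `omega` and shape. The
#' defaults reproduce a left-skewed unexposed survival distribution with mean
#' 685 days, SD 147 days and skewness -0.141, and a mean of about 580 days
#' after 6 Gy.
#'
#' @param xi0 Location at zero dose, days.
#' @param xi_slope Decrease of the location per unit dose, days/Gy.
#' @param omega Scale, days.
#' @param shape Skew-normal shape (dimensionless; negative = left skew).
#' @return An object of class `raml_mortality`.
#' @examples
#' sn_moments(0, mortality_params())  # mean ~685 d, sd ~147 d, skew ~-0.141
#' @export
mortality_params <- function(xi0 = 786.43, xi_slope = 17.45,
                             omega = 178.60, shape = -1.013) {
  for (nm in c("xi0", "xi_slope", "omega", "shape")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  if (xi0 <= 0) stop("'xi0' must be positive", call. = FALSE)
  structure(list(xi0 = xi0, xi_slope = xi_slope, omega = omega, shape = shape),
            class = "raml_mortality")
}

#' @export
print.raml_mortality <- function(x, ...) {
  cat("Skew-normal mouse mortality\n")
  cat(sprintf("  location %.2f - %.2f * D days, scale %.2f days, shape %.3f\n",
              x$xi0, x$xi_slope, x$omega, x$shape))
  invisible(x)
}

check_dose <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0))
    stop("dose must be nonnegative and finite", call. = FALSE)
  invisible(D)
}
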