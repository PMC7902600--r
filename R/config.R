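#' Run configuration
#'
#' Assembles and validates the full configuration of a reproducible run:
#' model and mortality parameters, engine settings, dose grids, cohort sizes,
#' optimizer budgets and the mandatory master seed. Any key not listed below
#' is rejected rather than silently ignored.
#'
#' @param ... Overrides for the default configuration; nested lists
#'   (`params`, `mortality`, `engine`, `budget`, `bootstrap`) are merged
#'   key-by-key.
#' @return Object of class `raml_config` (a validated nested list).
#' @section Keys:
#' `params` ([raml_params()] fields), `mortality` ([mortality_params()]
#' fields), `engine` (`engine`, `epsilon`, `switch_threshold`), `doses`,
#' `n_per_dose`, `ld_grid`, `hd_grid`, `n_ld`, `n_hd`, `budget`
#' (`sa_iters`, `nm_iters`, `mice_per_point`), `bootstrap` (`B`, `nm_iters`,
#' `mice_per_point`), `seed`, `out_dir`.
#' @export
raml_config <- function(...) {
  defaults <- list(
    params = unclass(raml_params()),
    mortality = unclass(mortality_params()),
    engine = list(engine = "adaptive_tau", epsilon = 0.01,
                  switch_threshold = 10),
    doses = c(0.75, 1.5, 3, 4.5, 6),
    n_per_dose = 10000,
    ld_grid = seq(0.02, 0.20, by = 0.02),
    hd_grid = c(0.25, 0.50, 0.75, 1.00),
    n_ld = 2e5, n_hd = 1e5,
    budget = list(sa_iters = 200, nm_iters = 150, mice_per_point = 500),
    bootstrap = list(B = 200, nm_iters = 60, mice_per_point = 200),
    seed = 1,
    out_dir = ".")
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  merge_checked(defaults, overrides, path = "")
}

merge_checked <- function(defaults, overrides, path) {
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) || is.null(names(overrides)) ||
        any(names(overrides) == ""))
      stop("unknown configuration key",
           if (length(unknown)) paste0(": '", path, unknown[1L], "'"),
           call. = FALSE)
    for (k in names(overrides)) {
      if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
        ov <- overrides[[k]]
        if (!is.list(ov)) stop("'", path, k, "' must be a list",
                               call. = FALSE)
        defaults[[k]] <- merge_checked(defaults[[k]], ov,
                                       paste0(path, k, "$"))
      } else defaults[[k]] <- overrides[[k]]
    }
  }
  if (path == "") {
    # validate by constructing the typed objects / cross-checking fields
    do.call(raml_params, defaults$params)
    do.call(mortality_params, defaults$mortality)
    if (!defaults$engine$engine %in% c("adaptive_tau", "exact_ssa"))
      stop("unknown engine '", defaults$engine$engine, "'", call. = FALSE)
    if (is.null(defaults$seed) || !is.finite(defaults$seed))
      stop("a finite 'seed' is mandatory", call. = FALSE)
    class(defaults) <- "raml_config"
  }
  defaults
}

#' Load / save a run configuration as YAML
#'
#' Missing keys fall back to the defaults of [raml_config()]; unknown keys
#' are rejected with the offending key named. An empty file yields the full
#' default configuration. `raml_write_config()` followed by
#' `raml_load_config()` is the identity.
#'
#' @param path YAML file path.
#' @param config A [raml_config()] object.
#' @return The validated `raml_config`.
#' @export
raml_load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raml_config(raw)
}

#' @rdname raml_load_config
#' @export
raml_write_config <- function(config, path) {
  stopifnot(inherits(config, "raml_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config) do.call(raml_params, config$params)
config_mortality <- function(config) do.call(mortality_params,
                                             config$mortality)
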