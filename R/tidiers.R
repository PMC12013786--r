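#' Tidy a factor model into a long loading table
#'
#' @param x A `factor_model` from [fit_factor_model()].
#' @param ... Unused.
#' @return A tibble: `unit_id`, `factor`, `loading`, `uniqueness`.
#' @export
tidy.factor_model <- function(x, ...) {
  k <- x$k
  tibble(
    unit_id = rep(x$unit_ids, times = k),
    factor = rep(seq_len(k), each = length(x$unit_ids)),
    loading = as.vector(x$loadings),
    uniqueness = rep(unname(x$uniquenesses), times = k)
  )
}

#' @rdname tidy.factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble(k = x$k, r2 = x$r2, rotation = x$rotation,
         n_units = length(x$unit_ids))
}

#' Tidy a dimensionality report into an R-squared curve table
#'
#' @param x A `dimensionality_report` from [select_dimensionality()].
#' @param ... Unused.
#' @return A tibble: `k`, `r2_data`, `r2_surrogate`.
#' @export
tidy.dimensionality_report <- function(x, ...) {
  tibble(k = seq_along(x$r2_data),
         r2_data = x$r2_data,
         r2_surrogate = x$r2_surrogate)
}

#' @rdname tidy.dimensionality_report
#' @export
glance.dimensionality_report <- function(x, ...) {
  tibble(k_slope = x$k_slope, k_5pct = x$k_5pct, k_mse = x$k_mse,
         r2_at_k_slope = x$r2_data[x$k_slope],
         surrogate_slope = x$surrogate_slope, n_units = x$n_units,
         kmax = x$kmax)
}

#' One-row summary of a simulation scenario run
#'
#' @param x A `scenario_run` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with the scenario id, physiology summaries and selected
#'   factor counts.
#' @export
glance.scenario_run <- function(x, ...) {
  tibble(
    scenario = x$scenario, seed = x$seed,
    n_active = x$n_active, mean_rate_mn = x$mean_rate_mn,
    mean_rate_rc = x$mean_rate_rc, baseline_e = x$baseline_e,
    k_slope = if (!is.null(x$report)) x$report$k_slope else NA_integer_,
    r2_at_k = if (!is.null(x$report))
      x$report$r2_data[x$report$k_slope] else NA_real_
  )
}
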