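#' Maximum-likelihood factor analysis of smoothed firing rates
#'
#' Fits a k-factor maximum-likelihood model to the unit-by-unit correlation
#' matrix of a (detrended) smoothed rate matrix, applies an oblique promax
#' rotation (power 4) to the varimax solution and computes regression
#' (Thomson) factor scores. Working on the correlation rather than the
#' covariance matrix places all units on a common scale, which is the
#' convention implied by detrending.
#'
#' @param rm A detrended `rate_matrix` (see [detrend_concat()]); a warning is
#'   issued otherwise.
#' @param k Number of latent factors. Must not exceed the identifiability
#'   bound `max(1, Ledermann(p))` for `p` units.
#' @param lower Floor on uniquenesses (Heywood-case guard), default 0.005.
#' @param nstart Number of random starts handed to the ML optimizer.
#' @return A `factor_model`: promax-rotated `loadings` (units x k), factor
#'   correlation `phi`, `uniquenesses`, `factor_scores` (k x samples),
#'   `rotation`, `k`, `unit_ids`, and `r2` (pooled reconstruction R-squared,
#'   see [reconstruction_r2()]).
#' @export
fit_factor_model <- function(rm, k, lower = 0.005, nstart = 1) {
  if (!isTRUE(rm$detrended)) {
    warn("fit_factor_model: rate matrix is not detrended; slow drifts will inflate the leading factor.")
  }
  x <- t(rm$rates)
  p <- ncol(x)
  if (k > fa_max_factors(p)) {
    abort(sprintf("k = %d exceeds the identifiability bound (%d) for %d units.",
                  k, fa_max_factors(p), p))
  }
  if (nrow(x) <= p) {
    warn("fit_factor_model: fewer samples than units; estimates will be unstable.")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) abort("Constant-rate unit(s): correlation undefined.")
  z <- scale(x)
  r <- cor(x)
  dof <- ((p - k)^2 - (p + k)) / 2
  if (dof >= 0) {
    fit <- fa_ml_fit(r, k, n_obs = nrow(x), lower = lower, nstart = nstart)
    l0 <- unclass(fit$loadings)
    uniq <- fit$uniquenesses
  } else {
    # too few variables for the ML likelihood-ratio machinery: fall back to
    # iterated principal-axis factoring with the same uniqueness floor
    pa <- fa_principal_axis(r, k, lower = lower)
    l0 <- pa$loadings
    uniq <- pa$uniquenesses
  }
  if (any(uniq <= lower + 1e-12)) {
    warn(sprintf("Heywood case: %d uniqueness(es) clamped to %.3f.",
                 sum(uniq <= lower + 1e-12), lower))
  }
  if (k >= 2) {
    pm <- promax(l0, m = 4)
    lambda <- unclass(pm$loadings)
    phi <- solve(t(pm$rotmat) %*% pm$rotmat)
    rotation <- "promax"
  } else {
    lambda <- l0
    phi <- diag(1)
    rotation <- "none"
  }
  scores <- t(z %*% solve_psd(r, lambda %*% phi)) # k x samples
  zhat <- t(scores) %*% t(lambda)
  r2 <- 1 - sum((z - zhat)^2) / sum(z^2)
  dimnames(lambda) <- list(rm$unit_ids, paste0("F", seq_len(k)))
  structure(
    list(loadings = lambda, phi = phi, uniquenesses = uniq,
         factor_scores = scores, rotation = rotation, k = k,
         unit_ids = rm$unit_ids, r2 = r2),
    class = "factor_model"
  )
}

# Ledermann bound, floored at 1 so a single-factor model is always admissible
fa_max_factors <- function(p) {
  max(1L, floor((2 * p + 1 - sqrt(8 * p + 1)) / 2))
}

fa_ml_fit <- function(r, k, n_obs, lower, nstart) {
  last_err <- NULL
  # escalate multi-starts and the uniqueness floor only on failure
  configs <- unique(list(c(lower, nstart), c(lower, 8), c(0.01, 8),
                         c(0.05, 8)))
  for (cfg in configs) {
    fit <- tryCatch(
      factanal(covmat = r, factors = k, n.obs = n_obs, rotation = "none",
               control = list(lower = cfg[1], nstart = cfg[2])),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) return(fit)
  }
  abort(sprintf("ML factor analysis failed to converge for k = %d (%s).",
                k, conditionMessage(last_err)))
}

fa_principal_axis <- function(r, k, lower, max_iter = 200, tol = 1e-8) {
  p <- ncol(r)
  comm <- rep(0.9, p)
  for (it in seq_len(max_iter)) {
    rr <- r
    diag(rr) <- comm
    e <- eigen(rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    l <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    new_comm <- pmin(rowSums(l^2), 1 - lower)
    if (max(abs(new_comm - comm)) < tol) { comm <- new_comm; break }
    comm <- new_comm
  }
  list(loadings = l, uniquenesses = pmax(1 - comm, lower))
}

solve_psd <- function(a, b) {
  out <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(out)) out <- solve(a + diag(1e-8, nrow(a)), b)
  out
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d units, k = %d (%s rotation), R2 = %.3f\n",
              nrow(x$loadings), x$k, x$rotation, x$r2))
  invisible(x)
}

#' Pooled reconstruction accuracy of a factor model
#'
#' Reconstructs the standardized rates as `scores x loadings'` and returns
#' `R^2 = 1 - SSE/SST` pooled over all units and samples.
#'
#' @param model A `factor_model`.
#' @param rm Optional `rate_matrix` to evaluate against; defaults to the value
#'   computed at fit time.
#' @return A fraction in `[0, 1]`.
#' @export
reconstruction_r2 <- function(model, rm = NULL) {
  if (is.null(rm)) return(model$r2)
  z <- scale(t(rm$rates))
  zhat <- t(model$factor_scores) %*% t(model$loadings)
  1 - sum((z - zhat)^2) / sum(z^2)
}

#' Surrogate population by inter-spike-interval shuffling
#'
#' For each unit, the sequence of inter-spike intervals is randomly permuted
#' and re-accumulated from the unit's original first firing time. The
#' surrogate therefore preserves each unit's spike count, mean firing rate and
#' ISI distribution exactly, while destroying the slow common-rate
#' fluctuations the factor analysis feeds on. Units with fewer than 3 spikes
#' are copied unchanged.
#'
#' @param pop A [population_recording()].
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return A `population_recording` with the same units and metadata.
#' @export
surrogate_population <- function(pop, seed = NULL) {
  with_seed(seed, {
    spk <- pop$spikes |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::group_modify(function(df, key) {
        t <- df$time_s
        if (length(t) >= 3) {
          df$time_s <- t[1] + c(0, cumsum(sample(diff(t))))
        }
        df
      }) |>
      dplyr::ungroup()
    population_recording(spk, duration = pop$duration, fs = pop$fs,
                         torque = pop$torque, segments = pop$segments)
  })
}

# run code under a temporary RNG state (no-op when seed is NULL)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reconstruction R-squared curve over candidate factor counts
#'
#' @param rm A detrended `rate_matrix`.
#' @param kmax Largest factor count to fit.
#' @param warn_failures Emit a warning when the fit fails for some k (that k
#'   and larger are reported as `NA`).
#' @return Numeric vector `r2[1..kmax]`.
#' @export
fa_r2_curve <- function(rm, kmax = 10, warn_failures = TRUE) {
  r2 <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    fit <- tryCatch(suppressWarnings(fit_factor_model(rm, k)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      if (warn_failures) {
        warn(sprintf("Factor analysis failed at k = %d; larger k excluded.", k))
      }
      break
    }
    r2[k] <- fit$r2
  }
  r2
}

#' Select the latent dimensionality of a motor-unit population
#'
#' Runs the full preprocessing and factor-analysis chain on a population
#' recording and selects the number of latent factors by three criteria:
#'
#' * `k_slope` (surrogate-slope, the primary criterion): the R-squared curve
#'   of an ISI-shuffled surrogate population is summarized by the slope of a
#'   least-squares straight line; factors keep being added while the forward
#'   difference of the data curve exceeds that slope. Beyond this point,
#'   additional factors are considered to capture noise.
#' * `k_5pct`: smallest k beyond which the increase in R-squared falls below
#'   0.05.
#' * `k_mse`: smallest k at which the remaining R-squared curve is flat, i.e.
#'   the mean squared error of a straight-line fit through points `k..kmax`
#'   drops below 1e-3.
#'
#' @param pop A [population_recording()]. Continuity filtering, smoothing,
#'   segment concatenation and detrending are applied internally so that the
#'   surrogate goes through the identical chain.
#' @param segments Segments to concatenate (defaults to `pop$segments`).
#' @param kmax Largest candidate factor count (default 10).
#' @param kernel_dur,fs_out,max_pause Passed to [smooth_rates()] and
#'   [filter_continuous()].
#' @param apply_filter Set `FALSE` when `pop` is already continuity-filtered.
#' @param seed Seed for the single surrogate realization (recorded in the
#'   report).
#' @param slope_method `"pointwise"` (default) compares the forward difference
#'   of the data curve against the fitted surrogate slope; `"linefit"`
#'   compares the slope of a straight line fitted through the remaining data
#'   points `k..kmax`.
#' @return A `dimensionality_report` with fields `r2_data`, `r2_surrogate`,
#'   `k_slope`, `k_5pct`, `k_mse`, `surrogate_slope`, `surrogate_seed`,
#'   `n_units`, `kmax`, `slope_method`.
#' @export
select_dimensionality <- function(pop, segments = NULL, kmax = 10,
                                  kernel_dur = 0.4, fs_out = NULL,
                                  max_pause = 0.4, apply_filter = TRUE,
                                  seed = NULL,
                                  slope_method = c("pointwise", "linefit")) {
  slope_method <- match.arg(slope_method)
  stopifnot(kmax >= 2)
  segments <- segments %||% pop$segments
  if (apply_filter) pop <- filter_continuous(pop, max_pause = max_pause)
  prep <- function(p) {
    detrend_concat(smooth_rates(p, kernel_dur = kernel_dur, fs_out = fs_out),
                   segments)
  }
  rm_data <- prep(pop)
  kmax_eff <- min(kmax, fa_max_factors(length(rm_data$unit_ids)))
  surr <- surrogate_population(pop, seed = seed)
  r2_data <- fa_r2_curve(rm_data, kmax_eff)
  r2_surr <- fa_r2_curve(prep(surr), kmax_eff)
  build_dimensionality_report(r2_data, r2_surr, kmax_eff, seed, slope_method,
                              n_units = length(rm_data$unit_ids))
}

build_dimensionality_report <- function(r2_data, r2_surr, kmax, seed,
                                        slope_method, n_units) {
  ks <- which(!is.na(r2_data) & !is.na(r2_surr))
  kk <- if (length(ks)) max(ks) else 0
  if (kk < 2) abort("Factor analysis succeeded for fewer than two factor counts.")
  surr_slope <- unname(coef(lm(r2_surr[1:kk] ~ seq_len(kk)))[2])
  d <- diff(r2_data[1:kk])
  data_slope <- switch(
    slope_method,
    pointwise = d,
    linefit = vapply(seq_len(kk - 1), function(k) {
      xs <- k:kk
      unname(coef(lm(r2_data[xs] ~ xs))[2])
    }, numeric(1))
  )
  failing <- which(data_slope <= surr_slope)
  k_slope <- if (length(failing)) failing[1] else kk - 1L
  k_5 <- which(d < 0.05)
  k_5pct <- if (length(k_5)) k_5[1] else kk - 1L
  k_mse <- kk - 1L
  for (k in seq_len(kk - 1)) {
    xs <- k:kk
    res <- stats::lm.fit(cbind(1, xs), r2_data[xs])$residuals
    if (mean(res^2) < 1e-3) { k_mse <- k; break }
  }
  structure(
    list(r2_data = r2_data, r2_surrogate = r2_surr,
         k_slope = as.integer(k_slope), k_5pct = as.integer(k_5pct),
         k_mse = as.integer(k_mse), surrogate_slope = surr_slope,
         surrogate_seed = seed, n_units = n_units, kmax = kmax,
         slope_method = slope_method),
    class = "dimensionality_report"
  )
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat(sprintf(
    "<dimensionality_report> %d units | k_slope = %d, k_5pct = %d, k_mse = %d\n",
    x$n_units, x$k_slope, x$k_5pct, x$k_mse))
  cat(sprintf("  R2(data) at k_slope: %.3f | surrogate line slope: %.4f\n",
              x$r2_data[x$k_slope], x$surrogate_slope))
  invisible(x)
}

#' Cluster units by their dominant factor
#'
#' Each unit is assigned to the factor on which its loading has the highest
#' magnitude (its position vector in factor space); ties go to the lowest
#' factor index.
#'
#' @param model A `factor_model`.
#' @return A tibble with columns `unit_id`, `factor` (integer label) and
#'   `loading` (the dominant loading, signed).
#' @export
dominant_factor_clusters <- function(model) {
  l <- model$loadings
  fac <- apply(abs(l), 1, which.max) # which.max takes the first on ties
  tibble(unit_id = model$unit_ids,
         factor = as.integer(fac),
         loading = l[cbind(seq_len(nrow(l)), fac)])
}
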