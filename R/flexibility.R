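#' Displacement of a motor-unit pair
#'
#' Displacement quantifies the largest opposite-direction excursion of two
#' smoothed firing-rate traces. For every ordered pair of timestamps `(t, t')`
#' the maximum non-negative rate change across units is
#' `dr(t, t') = max_i(r[i, t] - r[i, t'])`; when all units move in the same
#' direction one of `dr(t, t')`, `dr(t', t)` is zero, so the candidate value
#' for the pair is their minimum. The displacement of the pair is the maximum
#' candidate over all timestamp pairs. Units receiving one common drive
#' (co-monotone rates) therefore score exactly zero.
#'
#' Conduction-velocity differences between motor neurons shift one unit's
#' rate trace relative to the other. By default a constant integer-sample lag
#' per unit, searched over `±max_lag`, is chosen to minimize the metric
#' (`lag_mode = "per_unit"`); `lag_mode = "per_pair"` instead re-optimizes the
#' lags for every timestamp pair.
#'
#' @param rates 2 x T matrix of smoothed, non-detrended rates (pps), or a
#'   `rate_matrix` with exactly two units. Metrics operate on raw smoothed
#'   rates because the normalization uses maximum rates, which detrending
#'   would distort.
#' @param fs Sampling rate of the rate rows (taken from the `rate_matrix` if
#'   one is given).
#' @param max_lag Half-width of the lag search, seconds (default 0.025).
#' @param lag_mode `"per_unit"` (default) or `"per_pair"`, see Details.
#' @return A one-row tibble: `displacement_pps`, `displacement_norm`
#'   (normalized by the summed per-unit maximum rates), `lag_a_s`, `lag_b_s`
#'   (the minimizing per-unit lags; `NA` for `"per_pair"`).
#' @export
pair_displacement <- function(rates, fs = NULL, max_lag = 0.025,
                              lag_mode = c("per_unit", "per_pair")) {
  lag_mode <- match.arg(lag_mode)
  x <- as_rate_pair(rates, fs)
  lags <- lag_grid(max_lag, x$fs, ncol(x$r))
  norm_den <- sum(apply(x$r, 1, max))
  best <- Inf
  best_lag <- c(0L, 0L)
  if (lag_mode == "per_unit") {
    for (la in lags) for (lb in lags) {
      al <- align_pair(x$r, la, lb)
      d <- displacement_core(al[1, ], al[2, ])
      if (d < best) {
        best <- d
        best_lag <- c(la, lb)
      }
    }
  } else {
    # per-timestamp-pair lag optimization: accumulate the elementwise
    # minimum candidate in the unshifted time frame, then take the maximum
    n <- ncol(x$r)
    acc <- matrix(Inf, n, n)
    for (la in lags) for (lb in lags) {
      lo <- 1L - min(la, lb, 0L)
      hi <- n - max(la, lb, 0L)
      w <- lo:hi
      a <- x$r[1, w + la]
      b <- x$r[2, w + lb]
      da <- outer(a, a, "-")
      db <- outer(b, b, "-")
      cand <- pmin(pmax(da, db), pmax(-da, -db))
      acc[w, w] <- pmin(acc[w, w], cand)
    }
    best <- max(acc[is.finite(acc)])
    best_lag <- c(NA_integer_, NA_integer_)
  }
  tibble(displacement_pps = best,
         displacement_norm = if (norm_den > 0) best / norm_den else 0,
         lag_a_s = best_lag[1] / x$fs, lag_b_s = best_lag[2] / x$fs)
}

displacement_core <- function(a, b) {
  da <- outer(a, a, "-")
  db <- outer(b, b, "-")
  max(pmin(pmax(da, db), pmax(-da, -db)))
}

#' Dispersion of a motor-unit pair
#'
#' Dispersion quantifies how far the population state departs from a
#' one-dimensional manifold: under a single common drive, the summed firing
#' rate (L1 norm) of the population indexes a unique distribution of rates
#' across units, so two timestamps with equal norm must hold identical rate
#' vectors. Timestamps are grouped into norm bins of width `norm_tol`; the
#' dispersion is the largest L1 distance `||r(t1) - r(t2)||_1` between two
#' timestamps sharing a bin, maximized over bins and minimized over the
#' per-unit lag grid.
#'
#' Lags are always one constant integer shift per unit (the `"per_unit"`
#' convention of [pair_displacement()]); a lag whose alignment leaves every
#' bin with a single timestamp contributes no candidate.
#'
#' @inheritParams pair_displacement
#' @param norm_tol Width of the norm-matching bins in pps. `NULL` (default)
#'   uses 0.5% of the norm range; `0` requires exact norm equality (useful
#'   for analytic test cases, but exact ties rarely occur in floating point).
#' @return A one-row tibble: `dispersion_pps`, `dispersion_norm`, `lag_a_s`,
#'   `lag_b_s`. When no two timestamps share a norm bin under any lag the
#'   dispersion is 0 with a warning.
#' @export
pair_dispersion <- function(rates, fs = NULL, max_lag = 0.025,
                            norm_tol = NULL) {
  x <- as_rate_pair(rates, fs)
  lags <- lag_grid(max_lag, x$fs, ncol(x$r))
  norm_den <- sum(apply(x$r, 1, max))
  best <- Inf
  best_lag <- c(0L, 0L)
  matched_any <- FALSE
  for (la in lags) for (lb in lags) {
    al <- align_pair(x$r, la, lb)
    d <- dispersion_core(al[1, ], al[2, ], norm_tol)
    if (is.na(d)) next
    matched_any <- TRUE
    if (d < best) {
      best <- d
      best_lag <- c(la, lb)
    }
  }
  if (!matched_any) {
    warn("pair_dispersion: no two timestamps share a norm bin; dispersion 0.")
    best <- 0
  }
  tibble(dispersion_pps = best,
         dispersion_norm = if (norm_den > 0) best / norm_den else 0,
         lag_a_s = best_lag[1] / x$fs, lag_b_s = best_lag[2] / x$fs)
}

# max within-bin L1 distance; NA when every bin is a singleton
dispersion_core <- function(a, b, norm_tol) {
  nrm <- abs(a) + abs(b)
  if (is.null(norm_tol)) norm_tol <- 0.005 * diff(range(nrm))
  bin <- if (norm_tol > 0) floor((nrm - min(nrm)) / norm_tol) else nrm
  groups <- split(seq_along(a), bin)
  out <- NA_real_
  for (g in groups) {
    if (length(g) < 2) next
    d <- outer(a[g], a[g], "-")
    e <- outer(b[g], b[g], "-")
    out <- max(out, max(abs(d) + abs(e)), na.rm = TRUE)
  }
  out
}

as_rate_pair <- function(rates, fs) {
  if (inherits(rates, "rate_matrix")) {
    if (nrow(rates$rates) != 2) abort("Expected a rate_matrix with exactly 2 units.")
    list(r = rates$rates, fs = rates$fs)
  } else {
    r <- as.matrix(rates)
    if (nrow(r) != 2) abort("`rates` must be a 2 x T matrix.")
    if (is.null(fs)) abort("`fs` is required when `rates` is a bare matrix.")
    list(r = r, fs = fs)
  }
}

lag_grid <- function(max_lag, fs, n) {
  l <- round(max_lag * fs)
  if (2 * l >= n) abort("Lag grid exceeds the series length.")
  seq.int(-l, l)
}

# constant per-unit shifts; rows truncated to the common valid window
align_pair <- function(r, la, lb) {
  n <- ncol(r)
  lo <- 1L - min(la, lb, 0L)
  hi <- n - max(la, lb, 0L)
  rbind(r[1, (lo + la):(hi + la)], r[2, (lo + lb):(hi + lb)])
}

#' Displacement and dispersion for all unit pairs
#'
#' @param rm A `rate_matrix` of smoothed (non-detrended) rates with at least
#'   two units.
#' @param pairs `"all"` (default) for every unordered pair, or a two-column
#'   data frame / matrix of unit-id pairs.
#' @param max_lag,norm_tol,lag_mode Passed to [pair_displacement()] and
#'   [pair_dispersion()].
#' @param decimate Optional integer: keep every `decimate`-th sample before
#'   the quadratic-in-T pair search. The default 1 is exact; decimation for
#'   long series is reported via a message.
#' @return A tibble with one row per unordered pair (lexicographic order):
#'   `unit_a`, `unit_b`, `displacement_pps`, `dispersion_pps`,
#'   `displacement_norm`, `dispersion_norm`.
#' @export
flex_pairwise <- function(rm, pairs = "all", max_lag = 0.025,
                          norm_tol = NULL, lag_mode = "per_unit",
                          decimate = 1L) {
  stopifnot(inherits(rm, "rate_matrix"))
  ids <- rm$unit_ids
  if (length(ids) < 2) abort("Need at least two units.")
  if (identical(pairs, "all")) {
    idx <- utils::combn(order(ids), 2)
    pairs <- cbind(ids[idx[1, ]], ids[idx[2, ]])
  } else {
    pairs <- as.matrix(pairs)
  }
  r <- rm$rates
  fs <- rm$fs
  if (decimate > 1L) {
    inform(sprintf("flex_pairwise: decimating rate series by %d.", decimate))
    r <- r[, seq.int(1L, ncol(r), by = decimate), drop = FALSE]
    fs <- fs / decimate
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- match(pairs[i, 1], ids)
    b <- match(pairs[i, 2], ids)
    sub <- r[c(a, b), , drop = FALSE]
    dis <- pair_displacement(sub, fs, max_lag = max_lag, lag_mode = lag_mode)
    dsp <- suppressWarnings(
      pair_dispersion(sub, fs, max_lag = max_lag, norm_tol = norm_tol))
    tibble(unit_a = pairs[i, 1], unit_b = pairs[i, 2],
           displacement_pps = dis$displacement_pps,
           dispersion_pps = dsp$dispersion_pps,
           displacement_norm = dis$displacement_norm,
           dispersion_norm = dsp$dispersion_norm)
  })
}
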