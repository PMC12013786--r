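#' Build a population recording of motor-unit spike trains
#'
#' The central input container of the package. A population recording bundles
#' the firing times of a set of concurrently active motor units with the
#' recording duration, the sampling rate of the acquisition system, an
#' optional torque trace and an optional set of analysis segments (e.g. force
#' plateaus).
#'
#' @param spikes A data frame with one row per firing and columns `unit_id`,
#'   `time_s` (seconds) and optionally `grid` (label of the electrode grid the
#'   unit was identified on). Times need not be sorted on input; they are
#'   sorted per unit, but ties within a unit are an error.
#' @param duration Recording duration in seconds. Defaults to the last firing
#'   time.
#' @param fs Sampling rate in samples/s used for binarization and smoothing
#'   (2048 Hz for the high-density surface EMG systems this package targets).
#' @param torque Optional torque trace: a data frame with columns `time_s` and
#'   `torque_pct_mvc` (percent of maximal voluntary contraction).
#' @param segments Optional data frame with columns `start`, `end` giving
#'   half-open `[start, end)` windows in seconds (e.g. the force plateaus that
#'   are later concatenated). Must be non-overlapping and inside
#'   `[0, duration)`.
#'
#' @return An object of class `population_recording`.
#' @export
population_recording <- function(spikes, duration = NULL, fs = 2048,
                                 torque = NULL, segments = NULL) {
  spikes <- as_tibble(spikes)
  if (!all(c("unit_id", "time_s") %in% names(spikes))) {
    abort("`spikes` must have columns `unit_id` and `time_s`.")
  }
  spikes$unit_id <- as.character(spikes$unit_id)
  if (nrow(spikes) && any(!is.finite(spikes$time_s))) {
    abort("Non-finite firing times in `spikes`.")
  }
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$time_s)
  dup <- spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(ties = anyDuplicated(.data$time_s) > 0L) |>
    dplyr::filter(.data$ties)
  if (nrow(dup)) {
    abort(paste0("Firing times must be strictly increasing within a unit; ",
                 "ties found for unit(s): ", paste(dup$unit_id, collapse = ", ")))
  }
  if (is.null(duration)) duration <- if (nrow(spikes)) max(spikes$time_s) else 0
  if (nrow(spikes) && any(spikes$time_s < 0 | spikes$time_s > duration)) {
    bad <- unique(spikes$unit_id[spikes$time_s < 0 | spikes$time_s > duration])
    abort(paste0("Firing times outside [0, duration] for unit(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(torque)) {
    torque <- as_tibble(torque)
    if (!all(c("time_s", "torque_pct_mvc") %in% names(torque))) {
      abort("`torque` must have columns `time_s` and `torque_pct_mvc`.")
    }
  }
  if (!is.null(segments)) {
    segments <- as_tibble(segments)
    if (!all(c("start", "end") %in% names(segments))) {
      abort("`segments` must have columns `start` and `end`.")
    }
    segments <- dplyr::arrange(segments, .data$start)
    if (any(segments$end <= segments$start)) {
      abort("Each segment must satisfy start < end.")
    }
    if (any(segments$start < 0) || any(segments$end > duration)) {
      abort("Segments must lie within [0, duration).")
    }
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      abort("Segments must be non-overlapping.")
    }
  }
  structure(
    list(spikes = spikes, duration = duration, fs = fs,
         torque = torque, segments = segments),
    class = "population_recording"
  )
}

#' @export
print.population_recording <- function(x, ...) {
  cat(sprintf("<population_recording> %d units, %.1f s at %g Hz, %d firings\n",
              dplyr::n_distinct(x$spikes$unit_id), x$duration, x$fs,
              nrow(x$spikes)))
  if (!is.null(x$segments)) {
    cat(sprintf("  segments: %s\n",
                paste(sprintf("[%g,%g)", x$segments$start, x$segments$end),
                      collapse = " ")))
  }
  invisible(x)
}

#' @export
as_tibble.population_recording <- function(x, ...) x$spikes

#' Unit identifiers of a population recording
#' @param pop A `population_recording`.
#' @return Character vector of unit ids in sorted order.
#' @export
unit_ids <- function(pop) sort(unique(pop$spikes$unit_id))

#' Firing times of one unit
#' @param pop A `population_recording`.
#' @param unit A unit id.
#' @return Numeric vector of firing times in seconds.
#' @export
spike_times <- function(pop, unit) {
  pop$spikes$time_s[pop$spikes$unit_id == unit]
}

#' Binarize a spike train
#'
#' Converts firing times into a sample-indexed count vector. Sample index
#' `j` (0-based) collects the spikes whose time rounds to sample `j`
#' (round-half-even, the R default). More than one spike per sample is
#' permitted but reported via a message, since it usually indicates a
#' sampling rate that is too low for the train.
#'
#' @param times Numeric vector of strictly increasing firing times (s).
#' @param fs Sampling rate (samples/s).
#' @param duration Duration in seconds; must be at least `max(times)`.
#' @param unit_id Optional label used in error messages.
#' @return Integer vector of length `round(duration * fs)`.
#' @export
binarize <- function(times, fs, duration, unit_id = NULL) {
  stopifnot(fs > 0, duration >= 0)
  n <- round(duration * fs)
  if (length(times) && max(times) > duration) {
    abort(paste0("Spike time ", max(times), " s exceeds duration ", duration,
                 " s", if (!is.null(unit_id)) paste0(" for unit ", unit_id)))
  }
  out <- integer(n)
  if (!length(times)) return(out)
  idx <- pmin(pmax(round(times * fs), 0L) + 1L, n)
  tab <- tabulate(idx, nbins = n)
  if (any(tab > 1L)) {
    inform(paste0("binarize: ", sum(tab > 1L), " sample(s) hold >1 spike",
                  if (!is.null(unit_id)) paste0(" (unit ", unit_id, ")")))
  }
  tab
}

hanning_kernel <- function(kernel_dur, fs) {
  m <- floor(kernel_dur * fs / 2)
  if (2 * m + 1 < 3) abort("Kernel must span at least 3 samples at this fs.")
  j <- 0:(2 * m)
  w <- 0.5 * (1 - cos(2 * pi * j / (2 * m)))
  w * fs / sum(w) # unit time-integral: output in pulses per second
}

#' Smooth firing rates with a zero-phase Hanning kernel
#'
#' Each unit's binarized spike train is convolved with a Hanning (raised
#' cosine) window of duration `kernel_dur`, centred on the spike sample so
#' that no phase shift is introduced. The 400 ms default acts as a 2.5 Hz
#' low-pass filter, retaining the rate fluctuations relevant to force
#' production. The kernel is scaled to unit time-integral, so smoothed values
#' are in pulses per second and the time-integral of each row equals the
#' unit's spike count (up to edge effects).
#'
#' @param pop A [population_recording()].
#' @param kernel_dur Kernel duration in seconds (default 0.4).
#' @param fs_out Optional output sampling rate; must divide `pop$fs`. The
#'   convolution always runs at the acquisition rate, after which rows are
#'   decimated. Because the smoothed signal is band-limited well below any
#'   sensible `fs_out`, decimation is lossless for downstream analyses and
#'   keeps long recordings tractable.
#' @return A `rate_matrix` object: units x samples matrix of rates (pps) plus
#'   `fs`, `unit_ids` and a `detrended` flag.
#' @export
smooth_rates <- function(pop, kernel_dur = 0.4, fs_out = NULL) {
  fs <- pop$fs
  kern <- hanning_kernel(kernel_dur, fs)
  half <- (length(kern) - 1L) / 2L
  n <- round(pop$duration * fs)
  ids <- unit_ids(pop)
  decim <- 1L
  if (!is.null(fs_out)) {
    decim <- fs / fs_out
    if (abs(decim - round(decim)) > 1e-9) {
      abort("`fs_out` must be an integer divisor of the recording fs.")
    }
    decim <- as.integer(round(decim))
  }
  keep <- seq.int(1L, n, by = decim)
  rates <- matrix(0, nrow = length(ids), ncol = length(keep))
  for (u in seq_along(ids)) {
    times <- spike_times(pop, ids[u])
    if (!length(times)) next
    row <- numeric(n + 2L * half)
    idx <- pmin(pmax(round(times * fs), 0L) + 1L, n) # centred placement
    for (i in idx) {
      sl <- i:(i + 2L * half)
      row[sl] <- row[sl] + kern
    }
    rates[u, ] <- row[(half + 1L):(half + n)][keep]
  }
  new_rate_matrix(rates, fs / decim, ids, detrended = FALSE)
}

new_rate_matrix <- function(rates, fs, unit_ids, detrended = FALSE) {
  stopifnot(nrow(rates) == length(unit_ids))
  structure(list(rates = rates, fs = fs, unit_ids = unit_ids,
                 detrended = detrended),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d units x %d samples at %g Hz%s\n",
              nrow(x$rates), ncol(x$rates), x$fs,
              if (x$detrended) " (detrended)" else ""))
  invisible(x)
}

#' @export
as_tibble.rate_matrix <- function(x, ...) {
  tibble(
    unit_id = rep(x$unit_ids, each = ncol(x$rates)),
    time_s = rep((seq_len(ncol(x$rates)) - 1L) / x$fs, times = nrow(x$rates)),
    rate_pps = as.vector(t(x$rates))
  )
}

#' Keep only continuously firing units
#'
#' A unit is continuously active in a window when no inter-spike interval
#' inside the window exceeds `max_pause`, including the implicit gaps between
#' the window edges and the first/last spike: a unit silent for the first
#' second of a plateau is not continuously firing.
#'
#' @param pop A [population_recording()].
#' @param window Length-2 numeric `[start, end)` in seconds. If `NULL`,
#'   continuity is required in every segment of `pop$segments` (or the full
#'   recording when there are none).
#' @param max_pause Maximum tolerated pause in seconds (default 0.4, matching
#'   the smoothing kernel).
#' @return A `population_recording` retaining only continuous units (all of
#'   their spikes are kept). Warns when no unit survives.
#' @export
filter_continuous <- function(pop, window = NULL, max_pause = 0.4) {
  windows <- if (!is.null(window)) {
    list(window)
  } else if (!is.null(pop$segments)) {
    purrr::map2(pop$segments$start, pop$segments$end, c)
  } else {
    list(c(0, pop$duration))
  }
  ids <- unit_ids(pop)
  ok <- vapply(ids, function(u) {
    times <- spike_times(pop, u)
    all(vapply(windows, function(w) {
      tw <- times[times >= w[1] & times < w[2]]
      if (!length(tw)) return(FALSE)
      gaps <- diff(c(w[1], tw, w[2]))
      # edge gaps count against max_pause directly; interior gaps are ISIs
      all(gaps[c(1, length(gaps))] <= max_pause) &&
        (length(tw) < 2 || all(diff(tw) <= max_pause))
    }, logical(1)))
  }, logical(1))
  if (!any(ok)) warn("filter_continuous: no unit passes the continuity rule.")
  population_recording(pop$spikes[pop$spikes$unit_id %in% ids[ok], ],
                       duration = pop$duration, fs = pop$fs,
                       torque = pop$torque, segments = pop$segments)
}

#' Concatenate segments and remove linear trends
#'
#' Extracts the given half-open segments from a smoothed rate matrix,
#' concatenates them in order and removes each unit's least-squares linear
#' trend from the concatenated trace (slow drifts in firing rate would
#' otherwise masquerade as a strong common factor).
#'
#' @param rm A `rate_matrix` as produced by [smooth_rates()].
#' @param segments Data frame with `start`, `end` columns (seconds), or `NULL`
#'   to detrend the full matrix in place.
#' @return A detrended `rate_matrix` (the `fs` is unchanged; the time axis is
#'   the concatenation of the segments).
#' @export
detrend_concat <- function(rm, segments = NULL) {
  x <- rm$rates
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    cols <- unlist(lapply(seq_len(nrow(segments)), function(i) {
      a <- round(segments$start[i] * rm$fs) + 1L
      b <- round(segments$end[i] * rm$fs)
      if (a < 1L || b > ncol(x)) {
        abort(sprintf("Segment [%g, %g) outside the rate matrix.",
                      segments$start[i], segments$end[i]))
      }
      a:b
    }))
    x <- x[, cols, drop = FALSE]
  }
  t_idx <- seq_len(ncol(x))
  tc <- t_idx - mean(t_idx)
  denom <- sum(tc^2)
  slopes <- as.vector(x %*% tc) / denom
  x <- x - outer(slopes, tc) - rowMeans(x)
  new_rate_matrix(x, rm$fs, rm$unit_ids, detrended = TRUE)
}

isi_cov <- function(times) {
  if (length(times) < 3) return(Inf)
  isi <- diff(times)
  sd(isi) / mean(isi)
}

#' Identify duplicate motor units across electrode grids
#'
#' EMG decomposition run independently on several grids can return the same
#' physical unit more than once. Pairs of trains are aligned at the
#' integer-sample lag maximizing their binary cross-correlation (action
#' potentials propagate, so the same unit appears with a conduction delay),
#' then the fraction of shared firing times within `tol` is computed relative
#' to the smaller train. Pairs sharing more than `min_share` are duplicates;
#' groups are the transitive closure and the member with the lowest
#' inter-spike-interval coefficient of variation is retained (ties: more
#' spikes, then lexicographic id).
#'
#' @param pop A [population_recording()] with at least two units.
#' @param tol Match tolerance in seconds (default 0.0005, i.e. one sample at
#'   2048 Hz).
#' @param min_share Duplicate threshold on the shared fraction (default 0.30).
#' @param max_lag Half-width of the alignment lag search in seconds
#'   (default 0.01).
#' @return A tibble with one row per unit: `unit_id`, `group`, `isi_cov`,
#'   `n_spikes`, `retained`.
#' @seealso [remove_duplicates()]
#' @export
find_duplicates <- function(pop, tol = 0.0005, min_share = 0.30,
                            max_lag = 0.01) {
  ids <- unit_ids(pop)
  p <- length(ids)
  if (p < 2) abort("find_duplicates needs at least two units.")
  trains <- lapply(ids, spike_times, pop = pop)
  fs <- pop$fs
  lag_grid <- seq.int(-round(max_lag * fs), round(max_lag * fs)) / fs
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      share <- pair_share(trains[[i]], trains[[j]], lag_grid, tol)
      if (share > min_share) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  group <- match(roots, unique(roots))
  covs <- vapply(trains, isi_cov, numeric(1))
  nsp <- lengths(trains)
  retained <- logical(p)
  for (g in unique(group)) {
    members <- which(group == g)
    ord <- order(covs[members], -nsp[members], ids[members])
    retained[members[ord[1]]] <- TRUE
  }
  tibble(unit_id = ids, group = group, isi_cov = covs,
         n_spikes = nsp, retained = retained)
}

# shared-spike fraction at the best alignment lag
pair_share <- function(a, b, lag_grid, tol) {
  if (!length(a) || !length(b)) return(0)
  best <- 0
  for (lag in lag_grid) {
    sa <- a + lag
    # nearest spike of b for each shifted spike of a
    pos <- findInterval(sa, b)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(b))
    d <- pmin(abs(sa - b[lo]), abs(sa - b[hi]))
    best <- max(best, sum(d <= tol + 1e-12))
  }
  best / min(length(a), length(b))
}

#' Drop duplicate units from a recording
#'
#' @inheritParams find_duplicates
#' @return A `population_recording` keeping one representative per duplicate
#'   group.
#' @export
remove_duplicates <- function(pop, tol = 0.0005, min_share = 0.30,
                              max_lag = 0.01) {
  tab <- find_duplicates(pop, tol = tol, min_share = min_share,
                         max_lag = max_lag)
  population_recording(
    pop$spikes[pop$spikes$unit_id %in% tab$unit_id[tab$retained], ],
    duration = pop$duration, fs = pop$fs,
    torque = pop$torque, segments = pop$segments
  )
}

#' Recruitment threshold of a motor unit
#'
#' Recruitment time is the first firing of a series of three firings occurring
#' within one second; the recruitment threshold is the torque (in %MVC) at
#' that time, linearly interpolated from the torque trace. With several
#' contractions, per-contraction thresholds are averaged.
#'
#' @param times Firing times (s) of one unit, or a list of such vectors (one
#'   per contraction).
#' @param torque Torque data frame (`time_s`, `torque_pct_mvc`), or a list of
#'   such data frames matching `times`.
#' @return Threshold in %MVC, or `NA_real_` when no qualifying series of three
#'   firings exists (such units are excluded downstream).
#' @export
recruitment_threshold <- function(times, torque) {
  if (is.list(times) && !is.data.frame(times)) {
    if (!is.list(torque) || is.data.frame(torque)) {
      torque <- rep(list(torque), length(times))
    }
    th <- purrr::map2_dbl(times, torque, recruitment_threshold)
    return(mean(th, na.rm = TRUE))
  }
  torque <- as.data.frame(torque)
  if (length(times) < 3) return(NA_real_)
  ok <- which(times[-(1:2)] - times[seq_len(length(times) - 2)] <= 1)
  if (!length(ok)) return(NA_real_)
  t_rec <- times[ok[1]]
  stats::approx(torque$time_s, torque$torque_pct_mvc, xout = t_rec,
                rule = 2)$y
}

#' Read and write spike-train CSV files
#'
#' The on-disk dialect is a plain CSV with header `unit_id,time_s` and an
#' optional `grid` column, one row per firing, UTF-8, `.` decimal separator
#' and `\n` line endings. Torque files carry `time_s,torque_pct_mvc`.
#'
#' @param path File path.
#' @return `read_spike_csv` returns a spikes tibble suitable for
#'   [population_recording()]; `read_torque_csv` a torque tibble.
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("unit_id", "time_s") %in% names(df))) {
    abort("Spike CSV must have columns `unit_id,time_s[,grid]`.")
  }
  df$unit_id <- as.character(df$unit_id)
  as_tibble(df)
}

#' @rdname read_spike_csv
#' @param spikes Spikes tibble (`unit_id`, `time_s`, optional `grid`).
#' @export
write_spike_csv <- function(spikes, path) {
  utils::write.csv(as.data.frame(spikes), path, row.names = FALSE,
                   quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_spike_csv
#' @export
read_torque_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("time_s", "torque_pct_mvc") %in% names(df))) {
    abort("Torque CSV must have columns `time_s,torque_pct_mvc`.")
  }
  as_tibble(df)
}

#' @rdname read_spike_csv
#' @param torque Torque tibble.
#' @export
write_torque_csv <- function(torque, path) {
  utils::write.csv(as.data.frame(torque), path, row.names = FALSE,
                   quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
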