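#' Synthetic motor-unit population with known latent structure
#'
#' Generates spike trains whose smoothed rates are driven by `k_true`
#' band-limited (<= 2.5 Hz) latent signals mixed across units either
#' homogeneously (every unit weights every latent equally - the statistical
#' signature of a single effective common input) or heterogeneously (softmax
#' weights with temperature 0.1, concentrating each unit on one latent), plus
#' independent band-limited noise. Spikes are drawn from an inhomogeneous
#' gamma-renewal process by time rescaling. The default shape 16 gives an
#' ISI coefficient of variation of 0.25, inside the 0.1-0.3 range of real
#' motor units firing steadily - far more regular than a Poisson process,
#' which matters both for the realism of the surrogate criterion (it
#' shuffles ISIs) and for the signal-to-noise ratio of the smoothed rates.
#'
#' The returned ground truth makes the generator usable as an oracle for the
#' whole analysis chain: factor scores recovered from the smoothed rates
#' should correlate with the injected latents, and the surrogate-slope
#' criterion should recover `k_true`.
#'
#' @param n_units Number of units (default 30, the scale of a typical
#'   decomposed vastus lateralis sample).
#' @param duration Recording duration in seconds (default 80, i.e. four 20 s
#'   plateaus worth of data).
#' @param k_true Number of latent signals (>= 1).
#' @param mixing `"homogeneous"` or `"heterogeneous"`.
#' @param base_rate Mean firing rate in pps (default 12).
#' @param depth Modulation depth: the common+noise mixture has unit variance,
#'   so the instantaneous rate is `base_rate * (1 + depth * s(t))`. Must be
#'   small enough that the rate never goes negative (error otherwise).
#' @param noise_frac Fraction of the modulation variance taken by independent
#'   per-unit noise (default 0.1).
#' @param fs Sampling rate stored in the recording (default 2048).
#' @param latent_fs Internal rate-function grid (default 256 Hz; the signals
#'   live below 2.5 Hz so this is far beyond sufficient).
#' @param isi_shape Gamma shape of the renewal process (default 16, i.e.
#'   ISI CoV 0.25).
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A list: `pop` (a [population_recording()] with four 20 s segments
#'   when `duration` is a multiple of 20, otherwise one full-length segment),
#'   `latents` (`k_true` x grid-samples matrix), `weights`
#'   (`n_units` x `k_true`), `latent_fs`, `rate_fun` (units x grid-samples
#'   matrix of the true rate functions).
#' @export
latent_population <- function(n_units = 30, duration = 80, k_true = 1,
                              mixing = c("homogeneous", "heterogeneous"),
                              base_rate = 12, depth = 0.2, noise_frac = 0.1,
                              fs = 2048, latent_fs = 256, isi_shape = 16,
                              seed = NULL) {
  mixing <- match.arg(mixing)
  stopifnot(k_true >= 1, base_rate > 0, depth >= 0,
            noise_frac >= 0, noise_frac <= 1)
  with_seed(seed, {
    n <- round(duration * latent_fs)
    lat <- orthogonalize_cols(lp_gauss(n, latent_fs, 2.5, ncol = k_true))
    w <- if (mixing == "homogeneous") {
      matrix(1 / k_true, n_units, k_true)
    } else {
      softmax_rows(matrix(runif(n_units * k_true), n_units, k_true))
    }
    common <- lat %*% t(w) # n x units
    common <- scale(common) # unit variance per unit before the noise split
    noise <- lp_gauss(n, latent_fs, 2.5, ncol = n_units)
    s <- sqrt(1 - noise_frac) * common + sqrt(noise_frac) * noise
    rate <- base_rate * (1 + depth * s)
    if (any(rate < 0)) {
      abort("Instantaneous rate went negative; reduce `depth`.")
    }
    spikes <- purrr::map_dfr(seq_len(n_units), function(u) {
      t <- sample_renewal(rate[, u], latent_fs, shape = isi_shape)
      tibble(unit_id = sprintf("u%03d", u), time_s = t)
    })
    segs <- if (duration %% 20 == 0 && duration >= 40) {
      k <- duration / 20
      tibble(start = 20 * (seq_len(k) - 1), end = 20 * seq_len(k))
    } else {
      tibble(start = 0, end = duration)
    }
    list(
      pop = population_recording(spikes, duration = duration, fs = fs,
                                 segments = segs),
      latents = t(lat), weights = w, latent_fs = latent_fs,
      rate_fun = t(rate)
    )
  })
}

# inhomogeneous gamma-renewal spikes by time rescaling: rescaled inter-event
# gaps are gamma(shape, rate = shape) with unit mean, mapped back through the
# inverse of the cumulative rate
sample_renewal <- function(rate, fs, shape = 16) {
  n <- length(rate)
  cum <- c(0, cumsum(rate) / fs) # cumulative intensity at grid edges
  total <- cum[n + 1]
  n_exp <- max(16, ceiling(total + 6 * sqrt(total / shape)))
  gaps <- stats::rgamma(n_exp, shape = shape, rate = shape)
  while (sum(gaps) < total) {
    gaps <- c(gaps, stats::rgamma(n_exp, shape = shape, rate = shape))
  }
  lam <- cumsum(gaps)
  lam <- lam[lam < total]
  stats::approx(cum, seq(0, n) / fs, xout = lam)$y
}

#' Synthetic multi-channel EMG with known action-potential templates
#'
#' Places one fixed biphasic waveform per unit on an electrode grid (with
#' exponential spatial decay around a seeded centre channel), sums
#' contributions at each firing time and adds white noise. The ground-truth
#' templates are returned so spike-triggered averaging and localization can
#' be validated against them.
#'
#' @param pop A [population_recording()] providing the firing times.
#' @param layout A [grid_layout()] describing the differential electrode map.
#' @param centers Integer vector (one per unit, recycled) of centre channel
#'   indices in the `(rows-1) x cols` differential map; `NULL` draws them at
#'   random.
#' @param fs EMG sampling rate (default `pop$fs`).
#' @param amp Peak amplitude of the waveform (arbitrary units, default 1).
#' @param noise_sd White-noise standard deviation (default 0.1).
#' @param wave_dur Waveform duration in seconds (default 0.01; must fit the
#'   50 ms spike-triggered-averaging window).
#' @param space_const Spatial decay constant in mm (default 8).
#' @param seed Integer seed.
#' @return A list: `emg` (channels x samples matrix, channel order follows
#'   the flattened differential map), `templates` (list per unit of
#'   channels x wave-samples ground truth), `centers`, `fs`, `layout`.
#' @export
toy_emg <- function(pop, layout = grid_layout(), centers = NULL,
                    fs = pop$fs, amp = 1, noise_sd = 0.1,
                    wave_dur = 0.01, space_const = 8, seed = NULL) {
  stopifnot(wave_dur <= 0.05)
  with_seed(seed, {
    ids <- unit_ids(pop)
    nch <- (layout$rows - 1L) * layout$cols
    if (is.null(centers)) centers <- sample.int(nch, length(ids), replace = TRUE)
    centers <- rep_len(centers, length(ids))
    nw <- round(wave_dur * fs)
    tt <- seq_len(nw) / fs
    wave <- amp * sin(2 * pi * tt / wave_dur) *
      (0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1)))
    pos <- electrode_positions(layout)
    n <- round(pop$duration * fs)
    emg <- matrix(rnorm(nch * n, sd = noise_sd), nch, n)
    templates <- vector("list", length(ids))
    clipped <- 0L
    for (u in seq_along(ids)) {
      gain <- exp(-sqrt(rowSums(
        (pos[, c("x_mm", "y_mm")] -
           matrix(unlist(pos[centers[u], c("x_mm", "y_mm")]),
                  nch, 2, byrow = TRUE))^2)) / space_const)
      tpl <- outer(gain, wave)
      templates[[u]] <- tpl
      # spike sample index is round(t*fs)+1, matching binarize() and the
      # centred spike-triggered-averaging window
      starts <- round(spike_times(pop, ids[u]) * fs) + 1L - floor(nw / 2)
      for (s in starts) {
        a <- max(1L, s)
        b <- min(n, s + nw - 1L)
        if (b < a) next
        if (a != s || b != s + nw - 1L) clipped <- clipped + 1L
        emg[, a:b] <- emg[, a:b] + tpl[, (a - s + 1L):(b - s + 1L), drop = FALSE]
      }
    }
    if (clipped > 0) {
      warn(sprintf("toy_emg: %d waveform(s) clipped at the recording edges.",
                   clipped))
    }
    list(emg = emg, templates = templates, centers = centers, fs = fs,
         layout = layout)
  })
}

#' Write the seeded fixture set used by the test suite
#'
#' Emits small plain-text fixtures with fully known ground truth: a 1-latent
#' homogeneous population, a 3-latent heterogeneous population, a
#' duplicate-pair case (one train plus a 2 ms-shifted copy among independent
#' units) and a toy EMG grid recording, together with a `manifest.json`
#' recording the generating parameters. Seeds are fixed, so repeated calls
#' produce byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()

  lp1 <- latent_population(n_units = 20, duration = 40, k_true = 1,
                           mixing = "homogeneous", seed = 101)
  write_spike_csv(lp1$pop$spikes, file.path(out_dir, "pop_k1.csv"))
  manifest$pop_k1 <- list(file = "pop_k1.csv", k_true = 1,
                          mixing = "homogeneous", n_units = 20,
                          duration = 40, seed = 101)

  lp3 <- latent_population(n_units = 30, duration = 80, k_true = 3,
                           mixing = "heterogeneous", seed = 103)
  write_spike_csv(lp3$pop$spikes, file.path(out_dir, "pop_k3.csv"))
  manifest$pop_k3 <- list(file = "pop_k3.csv", k_true = 3,
                          mixing = "heterogeneous", n_units = 30,
                          duration = 80, seed = 103)

  dup <- duplicate_fixture(seed = 107)
  write_spike_csv(dup$spikes, file.path(out_dir, "pop_duplicates.csv"))
  manifest$pop_duplicates <- list(file = "pop_duplicates.csv",
                                  duplicate_of = dup$duplicate_of,
                                  shift_s = dup$shift_s, seed = 107)

  emg_pop <- latent_population(n_units = 3, duration = 4, k_true = 1,
                               mixing = "homogeneous", fs = 512, seed = 109)
  emg <- toy_emg(emg_pop$pop, fs = 512, noise_sd = 0.05, seed = 109)
  utils::write.csv(as.data.frame(t(emg$emg)),
                   file.path(out_dir, "toy_emg.csv"), row.names = FALSE,
                   quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  write_spike_csv(emg_pop$pop$spikes, file.path(out_dir, "toy_emg_spikes.csv"))
  manifest$toy_emg <- list(file = "toy_emg.csv",
                           spikes = "toy_emg_spikes.csv", fs = 512,
                           centers = emg$centers, seed = 109)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

duplicate_fixture <- function(seed, shift_s = 0.002) {
  lp <- latent_population(n_units = 4, duration = 20, k_true = 1,
                          mixing = "homogeneous", seed = seed)
  spk <- lp$pop$spikes
  first <- spk[spk$unit_id == "u001", ]
  dup <- first
  dup$unit_id <- "u001b"
  dup$time_s <- dup$time_s + shift_s
  dup <- dup[dup$time_s < 20, ]
  list(spikes = dplyr::bind_rows(spk, dup), duplicate_of = "u001",
       shift_s = shift_s)
}
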