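#' Build a motor-neuron pool
#'
#' Returns the per-neuron electrical parameters of a conductance-based LIF
#' pool. Soma diameters follow the quadratic distribution
#' `D_i = D_min + (i/N)^2 (D_max - D_min)`, giving the physiological
#' over-representation of small, low-threshold neurons. The remaining
#' parameters derive from the normalized diameter `d = D/D_min` through
#' power-law size relations calibrated so that the pool produces
#' physiological behaviour under the default drive (8-10.5 pps firing among
#' continuously active neurons, roughly 120-150 of 300 such neurons):
#'
#' * membrane resistance `R = r1 / d^alpha_r` (small neurons have the highest
#'   input resistance);
#' * responsiveness `S = R / R_1`, so exactly the smallest neuron has `S = 1`;
#' * the rheobase offset is constructed from a recruitment-threshold
#'   conductance curve over normalized rank `u`: a gently rising segment
#'   `rec_min * exp(rec_slope1 * u)` up to the knee at `u_knee`, then a steep
#'   wall `exp(rec_wall * (u - u_knee))` beyond it. The offset is the value
#'   making a steady excitatory conductance at that curve exactly sufficient
#'   to reach threshold, handing the pool an orderly, size-principle
#'   recruitment by construction. The knee pins the continuously active
#'   fraction near `u_knee` of the pool across input conditions (the units
#'   below the knee hold comfortable, similar voltage margins; the wall
#'   units recruit only under much stronger drive, as high-threshold motor
#'   units do);
#' * capacitance sets the effective time constant at the reference drive;
#' * the refractory period shortens weakly with size.
#'
#' @param n Number of neurons (default 300).
#' @param d_min,d_max Soma diameter range in um (50, 100).
#' @param r1_kohm Membrane resistance of the smallest neuron (kOhm; the leak
#'   conductance `1/R` is then in mS).
#' @param alpha_r Resistance/size exponent (default 2.4).
#' @param rec_min Recruitment-threshold conductance of the smallest neuron
#'   (mS).
#' @param rec_slope1,u_knee,rec_wall Shape of the recruitment-threshold
#'   curve: sub-knee exponential slope, knee position (fraction of the
#'   pool), and wall slope.
#' @param tau_eff Effective membrane time constant (s) at the reference drive
#'   `gamma_ref`, setting the firing-rate scale.
#' @param gamma_ref Reference excitatory conductance (mS) used for the
#'   capacitance calibration.
#' @param t_refr1 Refractory period of the smallest neuron (s).
#' @param alpha_refr Refractory/size exponent.
#' @return A tibble with one row per neuron: `neuron`, `u` (normalized rank),
#'   `soma_um`, `r_kohm`, `c_mss`, `s_fac`, `i_rheo`, `t_refr`, `gamma_star`.
#' @export
motor_pool <- function(n = 300, d_min = 50, d_max = 100,
                       r1_kohm = 100, alpha_r = 2.4,
                       rec_min = 0.40, rec_slope1 = 0.12, u_knee = 0.45,
                       rec_wall = 3.0,
                       tau_eff = 0.040, gamma_ref = 0.5,
                       t_refr1 = 0.025, alpha_refr = 0.5) {
  stopifnot(n >= 2, d_min < d_max)
  u <- (seq_len(n) - 1) / (n - 1)
  soma <- d_min + u^2 * (d_max - d_min)
  d <- soma / d_min
  r <- r1_kohm / d^alpha_r
  s <- r / r[1]
  gamma_star <- rec_min * exp(rec_slope1 * pmin(u, u_knee) +
                                rec_wall * pmax(u - u_knee, 0))
  v_th <- 10
  e_ex <- 25
  i_rheo <- (e_ex - v_th) * s * gamma_star - v_th / r
  if (any(i_rheo < 0)) {
    abort("Negative rheobase offset; increase `r1_kohm` or `rec_min`.")
  }
  tibble(
    neuron = seq_len(n), u = u, soma_um = soma,
    r_kohm = r, c_mss = tau_eff * (1 / r + gamma_ref * s),
    s_fac = s, i_rheo = i_rheo,
    t_refr = t_refr1 / d^alpha_refr, gamma_star = gamma_star
  )
}

#' Simulation scenario specifications
#'
#' Seven input-distribution scenarios for the motor-pool simulator:
#' (i) a single common excitatory input; (ii) three excitatory inputs
#' distributed homogeneously or (iii) heterogeneously; (iv) three inhibitory
#' inputs (on top of one uniform excitatory input) distributed homogeneously
#' or (v) heterogeneously; (vi) homonymous recurrent inhibition; (vii) both
#' homonymous and heteronymous recurrent inhibition across three pools
#' receiving correlated (~0.7) excitatory inputs.
#'
#' @param id One of `"i"`..`"vii"` (roman numerals, lower case).
#' @return A `scenario_spec` list: `id`, `k_sources`, `distribution`,
#'   `polarity`, `renshaw`, `n_pools`, `rho`, `baseline_inhib`.
#' @export
scenario_spec <- function(id) {
  specs <- list(
    i   = list(k_sources = 1, distribution = "homogeneous", polarity = "excit",
               renshaw = "none", n_pools = 1, rho = 0, baseline_inhib = 0),
    ii  = list(k_sources = 3, distribution = "homogeneous", polarity = "excit",
               renshaw = "none", n_pools = 1, rho = 0, baseline_inhib = 0),
    iii = list(k_sources = 3, distribution = "heterogeneous", polarity = "excit",
               renshaw = "none", n_pools = 1, rho = 0, baseline_inhib = 0),
    iv  = list(k_sources = 3, distribution = "homogeneous", polarity = "inhib",
               renshaw = "none", n_pools = 1, rho = 0, baseline_inhib = 0.12),
    v   = list(k_sources = 3, distribution = "heterogeneous", polarity = "inhib",
               renshaw = "none", n_pools = 1, rho = 0, baseline_inhib = 0.12),
    vi  = list(k_sources = 1, distribution = "homogeneous", polarity = "excit",
               renshaw = "homonymous", n_pools = 1, rho = 0, baseline_inhib = 0),
    vii = list(k_sources = 1, distribution = "homogeneous", polarity = "excit",
               renshaw = "homonymous+heteronymous", n_pools = 3, rho = 0.7,
               baseline_inhib = 0)
  )
  if (!id %in% names(specs)) {
    abort(sprintf("Unknown scenario '%s' (use one of %s).", id,
                  paste(names(specs), collapse = ", ")))
  }
  structure(c(list(id = id), specs[[id]]), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %s> %d source(s), %s, %s, renshaw: %s, %d pool(s)\n",
              x$id, x$k_sources, x$distribution, x$polarity, x$renshaw,
              x$n_pools))
  invisible(x)
}

#' Generate synaptic input conductances for a scenario
#'
#' Builds the per-neuron excitatory and inhibitory conductance drives: a
#' baseline plus zero-mean fluctuations composed of common sources (Gaussian
#' noise low-pass filtered at 2.5 Hz, standardized and mutually
#' orthogonalized - or correlated at `rho` across pools via a shared
#' component) mixed through per-neuron weights, and independent noise
#' (low-pass 50 Hz). Sources and noise are scaled so that, at the source
#' level, the common:independent variance split is 25:75 with a total SD of
#' `sd_total` (0.03 mS); under homogeneous mixing the common variance
#' actually delivered to a neuron is attenuated by `1/k` because the
#' orthogonal sources average out - the defining feature that makes
#' homogeneously distributed multi-source inputs act like one weaker common
#' input. Homogeneous mixing weights every source `1/k`;
#' heterogeneous mixing draws uniform(0,1) weights passed through a softmax
#' with temperature 0.1, so rows sum to one while concentrating each neuron
#' on a dominant source.
#'
#' In the inhibitory scenarios the three common sources ride on the
#' inhibitory baseline (0.12 mS), scaled by `(E_excit - V_th)/(V_th -
#' E_inhib) = 0.6` so that a unit of inhibitory conductance fluctuation has
#' the same efficacy at the firing threshold as a unit of excitatory
#' fluctuation; the excitatory channel carries one uniformly distributed
#' common source plus the independent noise.
#'
#' @param spec A [scenario_spec()].
#' @param n_per_pool Neurons per pool.
#' @param duration Seconds of input to generate.
#' @param fs_input Input sampling rate (Hz, default 500; the drive bands are
#'   0-2.5 and 0-50 Hz, far below Nyquist).
#' @param baseline_e Baseline excitatory conductance (mS) added to every
#'   neuron's excitatory drive.
#' @param sd_total Total fluctuation SD (mS, default 0.03).
#' @param common_frac Fraction of fluctuation variance from common sources
#'   (default 0.25).
#' @param seed Integer seed.
#' @return A list: `gamma_e`, `gamma_i` (N x T matrices, N = pools x
#'   `n_per_pool`), `weights`, `sources` (k_total x T), `fs_input`,
#'   `baseline_e`.
#' @export
generate_inputs <- function(spec, n_per_pool = 300, duration = 60,
                            fs_input = 500, baseline_e = 0.5,
                            sd_total = 0.03, common_frac = 0.25,
                            seed = NULL) {
  with_seed(seed, {
    t_n <- round(duration * fs_input)
    n_pools <- spec$n_pools
    n_tot <- n_pools * n_per_pool
    sd_common <- sd_total * sqrt(common_frac)
    sd_indep <- sd_total * sqrt(1 - common_frac)

    if (n_pools == 1) {
      k <- spec$k_sources
      src <- orthogonalize_cols(lp_gauss(t_n, fs_input, 2.5, ncol = max(k, 1)))
      w <- mixing_weights(n_per_pool, k, spec$distribution)
      # sources (not mixtures) carry the common-variance budget: averaging k
      # orthogonal sources under homogeneous weights attenuates the delivered
      # common variance by 1/k, which is precisely what makes homogeneously
      # distributed multi-source scenarios behave like a single weaker input
      common <- src %*% t(w) # T x N
    } else {
      # correlated single source per pool through a shared component
      z <- orthogonalize_cols(lp_gauss(t_n, fs_input, 2.5, ncol = n_pools + 1))
      src <- sapply(seq_len(n_pools), function(p) {
        as.vector(scale(sqrt(spec$rho) * z[, 1] +
                          sqrt(1 - spec$rho) * z[, p + 1]))
      })
      w <- mixing_weights(n_tot, 1, spec$distribution)
      common <- matrix(0, t_n, n_tot)
      for (p in seq_len(n_pools)) {
        cols <- (p - 1) * n_per_pool + seq_len(n_per_pool)
        common[, cols] <- src[, p]
      }
    }
    noise <- lp_gauss(t_n, fs_input, 50, ncol = n_tot)

    if (spec$polarity == "excit") {
      fluct_e <- sd_common * common + sd_indep * noise
      gamma_i <- matrix(0, n_tot, t_n)
    } else {
      # inhibitory common sources; the excitatory channel keeps one uniform
      # common source plus the independent noise
      e_src <- as.vector(scale(lp_gauss(t_n, fs_input, 2.5)))
      fluct_e <- sd_common * matrix(e_src, t_n, n_tot) + sd_indep * noise
      # inhibitory sources are scaled by (E_excit - V_th)/(V_th - E_inhib)
      # = 15/25 so that excitatory and inhibitory fluctuations have equal
      # efficacy at the firing threshold, where recruitment and pause
      # dynamics are decided
      gamma_i <- t(spec$baseline_inhib + 0.6 * sd_common * common)
    }
    gamma_e <- t(baseline_e + fluct_e)
    list(gamma_e = gamma_e, gamma_i = gamma_i, weights = w,
         sources = t(src), fs_input = fs_input, baseline_e = baseline_e)
  })
}

mixing_weights <- function(n, k, distribution) {
  if (k < 1) return(matrix(0, n, 0))
  if (distribution == "homogeneous") {
    matrix(1 / k, n, k)
  } else {
    softmax_rows(matrix(runif(n * k), n, k))
  }
}

#' Build Renshaw-cell layers and their connectivity
#'
#' Renshaw interneurons (60 per pool) provide recurrent inhibition. In the
#' homonymous configuration each cell is excited by a random subset of 17%
#' of its pool's motor neurons (exact in-degree) and each motor neuron is
#' inhibited by ~40% of the cells (independent Bernoulli draws, expected
#' density). In the homonymous+heteronymous configuration each cell receives
#' from 50% of its own pool's motor neurons (never from other pools), each
#' motor neuron from 60% of its own cells, and the motor neurons of every
#' pool are split at random into thirds: one third is additionally inhibited
#' by 60% of the cells of one heteronymous pool, another third by the other
#' pool, and the last third receives no heteronymous inhibition.
#'
#' @param spec A [scenario_spec()] with `renshaw != "none"`.
#' @param n_per_pool Motor neurons per pool.
#' @param m_per_pool Renshaw cells per pool (default 60).
#' @param duration,fs_input Extent and rate of the independent noise drive.
#' @param tau Membrane time constant (s, default 0.008).
#' @param t_refr Refractory period (s, default 0.010).
#' @param epsp_mv EPSP jump per motor-neuron spike (mV, default 1.5).
#' @param ipsp_ms Inhibitory conductance increment per Renshaw spike
#'   (mS, default 0.002).
#' @param delay Synaptic delay in both directions (s, default 0.005).
#' @param tau_syn Decay time constant of the recurrent inhibitory
#'   conductance (s, default 0.06). The per-spike amplitude is the stated
#'   0.002 mS; the decay constant is a calibration parameter chosen so the
#'   integrated recurrent inhibition is strong enough to require a visibly
#'   higher compensatory baseline drive and to shape the manifold, as
#'   reported for these circuits.
#' @param noise_sd SD of the 50 Hz low-pass independent input (mV, default 3).
#' @param seed Integer seed.
#' @return A list consumable by the simulator: scalar parameters, the
#'   `noise` matrix (cells x T), and 0-based adjacency lists `adj_mn2rc`
#'   (per motor neuron: target cells) and `adj_rc2mn` (per cell: target
#'   motor neurons).
#' @export
build_renshaw <- function(spec, n_per_pool = 300, m_per_pool = 60,
                          duration = 60, fs_input = 500,
                          tau = 0.008, t_refr = 0.010, epsp_mv = 1.5,
                          ipsp_ms = 0.002, delay = 0.005, tau_syn = 0.06,
                          noise_sd = 3, seed = NULL) {
  if (spec$renshaw == "none") abort("Scenario has no Renshaw layer.")
  with_seed(seed, {
    n_pools <- spec$n_pools
    n_tot <- n_pools * n_per_pool
    m_tot <- n_pools * m_per_pool
    c_mn2rc <- matrix(FALSE, m_tot, n_tot) # cell <- motor neuron excitation
    c_rc2mn <- matrix(FALSE, n_tot, m_tot) # motor neuron <- cell inhibition
    hom_in <- if (spec$renshaw == "homonymous") 0.17 else 0.50
    hom_out <- if (spec$renshaw == "homonymous") 0.40 else 0.60
    for (p in seq_len(n_pools)) {
      mn <- (p - 1) * n_per_pool + seq_len(n_per_pool)
      rc <- (p - 1) * m_per_pool + seq_len(m_per_pool)
      for (c in rc) {
        c_mn2rc[c, sample(mn, round(hom_in * n_per_pool))] <- TRUE
      }
      c_rc2mn[mn, rc] <- matrix(runif(n_per_pool * m_per_pool) < hom_out,
                                n_per_pool, m_per_pool)
    }
    if (spec$renshaw == "homonymous+heteronymous") {
      for (p in seq_len(n_pools)) {
        mn <- (p - 1) * n_per_pool + seq_len(n_per_pool)
        thirds <- split(sample(mn), rep(1:3, length.out = n_per_pool))
        others <- setdiff(seq_len(n_pools), p)
        for (g in 1:2) {
          rc_het <- (others[g] - 1) * m_per_pool + seq_len(m_per_pool)
          sub <- thirds[[g]]
          c_rc2mn[sub, rc_het] <-
            matrix(runif(length(sub) * m_per_pool) < 0.60,
                   length(sub), m_per_pool)
        }
      }
    }
    noise <- t(lp_gauss(round(duration * fs_input), fs_input, 50,
                        ncol = m_tot)) * noise_sd
    list(
      m = m_tot, tau = tau, v_thresh = 10, t_refr = t_refr,
      epsp_mv = epsp_mv, ipsp_ms = ipsp_ms, delay = delay, tau_syn = tau_syn,
      noise = noise,
      adj_mn2rc = lapply(seq_len(n_tot), function(j) which(c_mn2rc[, j]) - 1L),
      adj_rc2mn = lapply(seq_len(m_tot), function(c) which(c_rc2mn[, c]) - 1L),
      c_mn2rc = c_mn2rc, c_rc2mn = c_rc2mn
    )
  })
}
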