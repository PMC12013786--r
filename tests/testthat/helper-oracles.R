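# Brute-force reference implementations used as independent oracles.
# These are deliberately written as plain nested loops over lags and
# timestamp pairs, mirroring the definitions rather than the optimized code.

oracle_displacement <- function(r, n_lag) {
  n <- ncol(r)
  best <- Inf
  for (la in -n_lag:n_lag) for (lb in -n_lag:n_lag) {
    lo <- 1 - min(la, lb, 0)
    hi <- n - max(la, lb, 0)
    m <- -Inf
    for (t1 in lo:hi) for (t2 in lo:hi) {
      d1 <- max(r[1, t1 + la] - r[1, t2 + la], r[2, t1 + lb] - r[2, t2 + lb])
      d2 <- max(r[1, t2 + la] - r[1, t1 + la], r[2, t2 + lb] - r[2, t1 + lb])
      m <- max(m, min(d1, d2))
    }
    if (m < best) best <- m
  }
  best
}

oracle_dispersion <- function(r, n_lag, norm_tol) {
  n <- ncol(r)
  best <- Inf
  matched <- FALSE
  for (la in -n_lag:n_lag) for (lb in -n_lag:n_lag) {
    lo <- 1 - min(la, lb, 0)
    hi <- n - max(la, lb, 0)
    a <- r[1, (lo + la):(hi + la)]
    b <- r[2, (lo + lb):(hi + lb)]
    nrm <- abs(a) + abs(b)
    tol <- if (is.null(norm_tol)) 0.005 * diff(range(nrm)) else norm_tol
    bin <- if (tol > 0) floor((nrm - min(nrm)) / tol) else nrm
    m <- NA_real_
    for (t1 in seq_along(a)) for (t2 in seq_along(a)) {
      if (t1 == t2 || bin[t1] != bin[t2]) next
      m <- max(m, abs(a[t1] - a[t2]) + abs(b[t1] - b[t2]), na.rm = TRUE)
    }
    if (is.na(m)) next
    matched <- TRUE
    if (m < best) best <- m
  }
  if (!matched) 0 else best
}

# exhaustive scan for the earliest firing opening a triple within 1 s
oracle_recruitment_time <- function(times) {
  for (i in seq_along(times)) {
    if (i + 2 <= length(times) && times[i + 2] - times[i] <= 1) return(times[i])
  }
  NA_real_
}

# direct (slow) centred convolution of a binarized train with a unit-integral
# Hanning kernel
oracle_smooth <- function(times, fs, duration, kernel_dur = 0.4) {
  x <- binarize(times, fs, duration)
  m <- floor(kernel_dur * fs / 2)
  j <- 0:(2 * m)
  w <- 0.5 * (1 - cos(2 * pi * j / (2 * m)))
  w <- w * fs / sum(w)
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (s in -m:m) {
      if (t + s >= 1 && t + s <= n) out[t] <- out[t] + x[t + s] * w[s + m + 1]
    }
  }
  out
}

# greedy factor-to-latent matching by absolute correlation
match_abs_cor <- function(scores, latents) {
  k <- nrow(scores)
  cm <- abs(stats::cor(t(scores), t(latents)))
  out <- numeric(k)
  used_f <- used_l <- integer(0)
  for (i in seq_len(k)) {
    cm2 <- cm
    if (length(used_f)) cm2[used_f, ] <- -1
    if (length(used_l)) cm2[, used_l] <- -1
    hit <- which(cm2 == max(cm2), arr.ind = TRUE)[1, ]
    out[i] <- cm[hit[1], hit[2]]
    used_f <- c(used_f, hit[1])
    used_l <- c(used_l, hit[2])
  }
  out
}

resample_to <- function(x, n_out) {
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

# pass a latent signal through the same smoothing kernel the rates went
# through, so score-recovery checks compare against what the rates encode
smooth_signal <- function(x, fs, kernel_dur = 0.4) {
  k <- muflex:::hanning_kernel(kernel_dur, fs) / fs
  as.vector(stats::filter(x, k, sides = 2, circular = TRUE))
}
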