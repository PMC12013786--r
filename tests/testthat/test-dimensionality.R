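mk_rm <- function(rates, fs = 64, detrended = TRUE) {
  muflex:::new_rate_matrix(rates, fs, sprintf("u%02d", seq_len(nrow(rates))),
                           detrended = detrended)
}

test_that("perfectly correlated units load fully on a single factor", {
  set.seed(1)
  x <- rnorm(500)
  rm <- mk_rm(rbind(x, x))
  expect_warning(fit <- fit_factor_model(rm, 1), "Heywood")
  expect_true(all(abs(fit$loadings) > 0.99))
  expect_gt(fit$r2, 0.999)
})

test_that("the identifiability bound is enforced", {
  set.seed(2)
  rm <- mk_rm(matrix(rnorm(5 * 400), 5))
  expect_error(fit_factor_model(rm, 4), "identifiability")
  expect_equal(muflex:::fa_max_factors(2), 1)
  expect_equal(muflex:::fa_max_factors(30), 22)
})

test_that("reconstruction R2 is high for low-rank data, monotone in k, low for noise", {
  set.seed(3)
  n <- 1500
  p <- 15
  g <- rnorm(n)
  rank1 <- outer(runif(p, 0.5, 2), g) + matrix(rnorm(p * n, sd = 1e-4), p)
  expect_gt(suppressWarnings(fit_factor_model(mk_rm(rank1), 1))$r2, 0.999)

  lat <- matrix(rnorm(n * 3), n, 3)
  x <- t(lat %*% matrix(runif(p * 3), 3, p) + matrix(rnorm(n * p, sd = 0.5), n))
  r2 <- fa_r2_curve(mk_rm(x), 6)
  expect_true(all(diff(r2) > -1e-6))
  expect_true(all(r2 >= 0 & r2 <= 1))

  # pure white-noise units: R2 at k = 1 stays small (worst case over seeds)
  worst <- max(vapply(1:20, function(s) {
    set.seed(s)
    fa_r2_curve(mk_rm(matrix(rnorm(20 * 2560), 20)), 1)[1]
  }, numeric(1)))
  expect_lt(worst, 0.2)
})

test_that("R2 curves are invariant to rate scaling", {
  set.seed(4)
  x <- matrix(rnorm(10 * 800), 10) + outer(runif(10), rnorm(800))
  expect_equal(fa_r2_curve(mk_rm(x), 4), fa_r2_curve(mk_rm(3 * x), 4),
               tolerance = 1e-6) # correlation is scale-free; ML optimizer
                                 # tolerance bounds the residual difference
})

test_that("ISI shuffling preserves counts and span but destroys common modulation", {
  lp <- latent_population(n_units = 12, duration = 30, k_true = 1,
                          seed = 21)
  pop <- lp$pop
  surr <- surrogate_population(pop, seed = 1)
  for (u in unit_ids(pop)) {
    a <- spike_times(pop, u)
    b <- spike_times(surr, u)
    expect_identical(length(a), length(b))
    expect_equal(max(b) - min(b), max(a) - min(a), tolerance = 1e-9)
    expect_equal(b[1], a[1])
  }

  # common-drive correlations collapse in the surrogate
  mean_abs_cor <- function(p) {
    rm <- smooth_rates(p, fs_out = 64)
    cm <- cor(t(rm$rates))
    mean(abs(cm[upper.tri(cm)]))
  }
  cors <- vapply(1:20, function(s) {
    mean_abs_cor(surrogate_population(pop, seed = s))
  }, numeric(1))
  expect_gt(mean_abs_cor(pop), 0.3)
  expect_lt(mean(cors), 0.1)
})

test_that("surrogate-slope criterion recovers the latent dimensionality", {
  for (s in 1:3) {
    lp1 <- latent_population(n_units = 25, duration = 60, k_true = 1,
                             mixing = "homogeneous", seed = 300 + s)
    rep1 <- select_dimensionality(lp1$pop, kmax = 6, fs_out = 64,
                                  seed = 400 + s)
    expect_equal(rep1$k_slope, 1)

    lp3 <- latent_population(n_units = 30, duration = 80, k_true = 3,
                             mixing = "heterogeneous", seed = 500 + s)
    rep3 <- select_dimensionality(lp3$pop, kmax = 6, fs_out = 64,
                                  seed = 600 + s)
    expect_equal(rep3$k_slope, 3)
  }
})

test_that("an ISI-shuffled population is its own null: no factor structure to find", {
  # For structureless data the data and surrogate R2 curves are
  # indistinguishable, so the selected count carries no signal; what must
  # hold is that the curves agree and the selection respects its bounds.
  for (s in 1:3) {
    lp <- latent_population(n_units = 20, duration = 40, k_true = 3,
                            mixing = "heterogeneous", seed = 30 + s)
    surr <- surrogate_population(lp$pop, seed = 5 + s)
    rep <- select_dimensionality(surr, kmax = 6, fs_out = 64, seed = 600 + s)
    expect_lt(max(abs(rep$r2_data - rep$r2_surrogate)), 0.06)
    expect_gte(rep$k_slope, 1)
    expect_lte(rep$k_slope, rep$kmax - 1)

    # the same population with its structure intact is clearly separated
    rep0 <- select_dimensionality(lp$pop, kmax = 6, fs_out = 64,
                                  seed = 600 + s)
    expect_gt(rep0$r2_data[3] - rep0$r2_surrogate[3], 0.2)
  }
})

test_that("factor scores recover heterogeneously mixed latents", {
  for (s in 1:3) {
    lp <- latent_population(n_units = 30, duration = 80, k_true = 3,
                            mixing = "heterogeneous", seed = 700 + s)

    # from the true rate functions the chain recovers the latents almost
    # perfectly (this isolates correctness of detrending + FA + scoring)
    rm_true <- detrend_concat(
      muflex:::new_rate_matrix(lp$rate_fun, lp$latent_fs,
                               sprintf("u%03d", 1:30)), NULL)
    fit_true <- fit_factor_model(rm_true, 3)
    lat_rs_true <- lp$latents[, seq_len(ncol(fit_true$factor_scores)),
                              drop = FALSE]
    expect_true(all(match_abs_cor(fit_true$factor_scores,
                                  lp$latents) > 0.95))

    # from the spikes, recovery is bounded by the gamma-renewal noise floor
    # of ~1000 spikes per unit; latents dominated by small softmax clusters
    # land near that floor
    rm <- detrend_concat(smooth_rates(lp$pop, fs_out = 64),
                         lp$pop$segments)
    fit <- fit_factor_model(rm, 3)
    lat_sm <- t(apply(lp$latents, 1, smooth_signal, fs = lp$latent_fs))
    lat_rs <- t(apply(lat_sm, 1, resample_to,
                      n_out = ncol(fit$factor_scores)))
    expect_true(all(match_abs_cor(fit$factor_scores, lat_rs) > 0.85))
  }
})

test_that("dominant-factor clustering uses magnitude with lowest-index ties", {
  fake <- structure(
    list(loadings = rbind(c(0.9, 0.1, -0.2), c(0.5, -0.5, 0), c(0.1, 0.2, -0.6)),
         unit_ids = c("a", "b", "c"), k = 3),
    class = "factor_model")
  cl <- dominant_factor_clusters(fake)
  expect_equal(cl$factor, c(1L, 1L, 3L))

  fake1 <- structure(
    list(loadings = matrix(c(0.7, -0.4, 0.5), 3), unit_ids = c("a", "b", "c"),
         k = 1),
    class = "factor_model")
  expect_equal(unique(dominant_factor_clusters(fake1)$factor), 1L)
})

test_that("tidy and glance methods expose the report in tabular form", {
  lp <- latent_population(n_units = 15, duration = 30, k_true = 1, seed = 9)
  rep <- select_dimensionality(lp$pop, kmax = 4, fs_out = 64, seed = 10)
  td <- tidy(rep)
  expect_named(td, c("k", "r2_data", "r2_surrogate"))
  expect_equal(nrow(td), 4)
  gl <- glance(rep)
  expect_equal(gl$k_slope, rep$k_slope)
  expect_s3_class(autoplot(rep), "ggplot")
})
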