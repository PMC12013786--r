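test_that("binarize places spikes at rounded sample indices and conserves counts", {
  v <- binarize(0.5, fs = 2048, duration = 1)
  expect_length(v, 2048)
  expect_equal(which(v == 1L), 1025) # 0-based sample 1024
  expect_equal(sum(v), 1L)

  expect_equal(sum(binarize(numeric(0), 2048, 1)), 0L)

  set.seed(42)
  for (i in 1:5) {
    times <- sort(runif(50, 0, 10))
    expect_equal(sum(binarize(times, 512, 10)), 50L)
  }

  expect_error(binarize(c(0.5, 1.2), fs = 100, duration = 1, unit_id = "u9"),
               "u9")
})

test_that("smoothing is zero-phase, unit-integral and matches direct convolution", {
  fs <- 256
  pop <- population_recording(tibble::tibble(unit_id = "a", time_s = 1.0),
                              duration = 2, fs = fs)
  rm <- smooth_rates(pop)
  row <- rm$rates[1, ]
  peak <- which.max(row)
  expect_equal(peak, round(1.0 * fs) + 1)
  half <- floor(0.4 * fs / 2)
  expect_equal(row[(peak - half):(peak - 1)], rev(row[(peak + 1):(peak + half)]),
               tolerance = 1e-12)

  # regular 10 Hz train: interior smoothed rate within 2% of 10 pps
  times <- seq(0.25, 9.75, by = 0.1)
  pop10 <- population_recording(tibble::tibble(unit_id = "a", time_s = times),
                                duration = 10, fs = fs)
  rm10 <- smooth_rates(pop10)
  interior <- rm10$rates[1, (2 * fs):(8 * fs)]
  expect_true(all(abs(interior - 10) / 10 < 0.02))
  expect_equal(rm10$rates[1, ], oracle_smooth(times, fs, 10), tolerance = 1e-9)

  # spike-count conservation on an interior window
  expect_equal(sum(rm10$rates[1, ]) / fs, length(times), tolerance = 0.005)

  # empty unit smooths to a zero row
  pop2 <- population_recording(
    tibble::tibble(unit_id = c("a", "b"), time_s = c(1.0, 1.5)),
    duration = 2, fs = fs)
  pop2$spikes <- pop2$spikes[pop2$spikes$unit_id == "a", , drop = FALSE]
  pop2$spikes <- rbind(pop2$spikes)
  rm_a <- smooth_rates(population_recording(pop2$spikes, 2, fs))
  expect_equal(nrow(rm_a$rates), 1)

  # decimation subsamples the full-rate convolution
  rm_dec <- smooth_rates(pop10, fs_out = 64)
  expect_equal(rm_dec$fs, 64)
  expect_equal(rm_dec$rates[1, 1:100], rm10$rates[1, seq(1, by = 4, length.out = 100)])
})

test_that("continuity filter enforces the 400 ms pause rule including window edges", {
  mk <- function(times, id = "a") tibble::tibble(unit_id = id, time_s = times)
  w <- c(0, 10)
  ok_unit <- mk(seq(0.2, 9.9, by = 0.38))
  gap_unit <- mk(c(seq(0.2, 5, by = 0.3), seq(5.5, 9.9, by = 0.3)), "b")
  late_unit <- mk(seq(0.6, 9.9, by = 0.3), "c")
  pop <- population_recording(dplyr::bind_rows(ok_unit, gap_unit, late_unit),
                              duration = 10, fs = 256)
  kept <- unit_ids(filter_continuous(pop, window = w))
  expect_equal(kept, "a")

  # idempotence
  f1 <- filter_continuous(pop, window = w)
  f2 <- filter_continuous(f1, window = w)
  expect_identical(f1$spikes, f2$spikes)

  expect_warning(
    filter_continuous(population_recording(mk(c(1, 2, 3)), 10, 256),
                      window = w),
    "no unit")
})

test_that("detrending removes affine trends exactly and concatenates segments", {
  fs <- 64
  t <- (0:(40 * fs - 1)) / fs
  rates <- rbind(3 + 0.2 * t, 10 - 0.1 * t)
  rm <- muflex:::new_rate_matrix(rates, fs, c("a", "b"))
  out <- detrend_concat(rm)
  expect_true(out$detrended)
  expect_lt(max(abs(out$rates)), 1e-9)

  segs <- tibble::tibble(start = c(0, 20), end = c(20, 40))
  out2 <- detrend_concat(rm, segs)
  expect_equal(ncol(out2$rates), 2 * 20 * fs)

  # invariance to adding an affine trend
  rnd <- matrix(rnorm(2 * length(t)), 2)
  rm_a <- muflex:::new_rate_matrix(rnd, fs, c("a", "b"))
  rm_b <- muflex:::new_rate_matrix(rnd + rbind(1 + 0.5 * t, -2 + 0.1 * t),
                                   fs, c("a", "b"))
  expect_equal(detrend_concat(rm_a, segs)$rates,
               detrend_concat(rm_b, segs)$rates, tolerance = 1e-8)

  expect_error(detrend_concat(rm, tibble::tibble(start = 30, end = 50)),
               "outside")
})

test_that("duplicate detection aligns, thresholds at 30% shared and keeps lowest ISI CoV", {
  set.seed(7)
  base <- sort(runif(150, 0.2, 19.8))
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = "orig", time_s = base),
    tibble::tibble(unit_id = "shift", time_s = base + 0.002),
    tibble::tibble(unit_id = "indep", time_s = sort(runif(150, 0.2, 19.9)))
  )
  pop <- population_recording(spikes, duration = 20, fs = 2048)
  tab <- find_duplicates(pop)
  expect_equal(tab$group[tab$unit_id == "orig"],
               tab$group[tab$unit_id == "shift"])
  expect_false(tab$group[tab$unit_id == "indep"] ==
                 tab$group[tab$unit_id == "orig"])
  expect_equal(sum(tab$retained[tab$unit_id %in% c("orig", "shift")]), 1L)

  # lag invariance: extra conduction-like shifts within the alignment search
  # range keep the groups (total offset stays below the 10 ms search radius)
  for (lag in c(-0.007, -0.003, 0.003, 0.007)) {
    sh <- spikes
    sh$time_s[sh$unit_id == "shift"] <- base + 0.002 + lag
    tab2 <- find_duplicates(population_recording(sh, 20.1, 2048))
    expect_equal(tab2$group[tab2$unit_id == "orig"],
                 tab2$group[tab2$unit_id == "shift"])
  }

  # the member with the lowest ISI CoV is retained
  reg <- seq(0.5, 19.5, by = 0.1) # CoV ~ 0
  irr <- reg + runif(length(reg), -2e-4, 2e-4) # same unit seen with jitter
  irr[1] <- reg[1]
  pop2 <- population_recording(dplyr::bind_rows(
    tibble::tibble(unit_id = "regular", time_s = reg),
    tibble::tibble(unit_id = "jittery", time_s = sort(irr))
  ), duration = 20, fs = 2048)
  tab3 <- find_duplicates(pop2)
  expect_true(tab3$retained[tab3$unit_id == "regular"])
  expect_false(tab3$retained[tab3$unit_id == "jittery"])
})

test_that("independent trains share well under 30% of firings", {
  # Monte-Carlo over seeded pairs of independent 10 Hz Poisson trains
  shares <- vapply(1:100, function(s) {
    set.seed(s)
    a <- cumsum(rexp(250, 10))
    b <- cumsum(rexp(250, 10))
    a <- a[a < 20]
    b <- b[b < 20]
    lag_grid <- seq(-20, 20) / 2048
    muflex:::pair_share(a, b, lag_grid, 0.0005)
  }, numeric(1))
  expect_gte(mean(shares < 0.30), 0.95)
})

test_that("recruitment threshold takes the first of three firings within 1 s", {
  ramp <- tibble::tibble(time_s = seq(0, 5, by = 0.01),
                         torque_pct_mvc = seq(0, 20, length.out = 501))
  expect_equal(recruitment_threshold(c(1.0, 1.3, 1.6, 2.0, 2.4), ramp), 4.0)

  times <- c(0.5, 2.0, 2.1, 2.2)
  expect_equal(oracle_recruitment_time(times), 2.0)
  expect_equal(recruitment_threshold(times, ramp), 8.0)

  expect_true(is.na(recruitment_threshold(c(0.5, 1.6, 2.7), ramp)))

  # multi-contraction variant averages per-contraction thresholds
  expect_equal(
    recruitment_threshold(list(c(1, 1.2, 1.4), c(2, 2.2, 2.4)), ramp),
    mean(c(4, 8)))
})

test_that("spike and torque CSV round-trips preserve the data", {
  dir <- withr::local_tempdir()
  spikes <- tibble::tibble(unit_id = c("a", "a", "b"),
                           time_s = c(0.1, 0.25, 0.5),
                           grid = c("g1", "g1", "g2"))
  p <- file.path(dir, "spikes.csv")
  write_spike_csv(spikes, p)
  expect_equal(as.data.frame(read_spike_csv(p)), as.data.frame(spikes))

  torque <- tibble::tibble(time_s = c(0, 0.5), torque_pct_mvc = c(0, 10))
  pt <- file.path(dir, "torque.csv")
  write_torque_csv(torque, pt)
  expect_equal(as.data.frame(read_torque_csv(pt)), as.data.frame(torque))
})
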