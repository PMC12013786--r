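test_that("electrode geometry matches the stated montage distances", {
  lay <- grid_layout(n_grids = 4)
  pos <- electrode_positions(lay)
  expect_equal(nrow(pos), 4 * 12 * 5)

  at <- function(g, r, c) pos[pos$grid == g & pos$row == r & pos$col == c, ]
  # adjacent electrodes in one grid: 8 mm apart
  expect_equal(unit_distance(at(1, 3, 2), at(1, 4, 2)), 8)
  expect_equal(unit_distance(at(1, 3, 2), at(1, 3, 3)), 8)
  # last row of grid 1 to first row of grid 2: rows 0.5 ie from each edge,
  # plus the 24 mm edge-to-edge inter-grid gap
  gap <- unit_distance(at(1, 12, 1), at(2, 1, 1))
  expect_equal(gap, (12.5 - 11.5) * 8 + 24)
  # 3 columns apart plus one grid gap along the muscle axis
  d <- unit_distance(at(1, 12, 1), at(2, 1, 4))
  expect_equal(d, sqrt((3 * 8)^2 + 32^2))
})

test_that("spike-triggered averaging recovers planted templates", {
  lay <- grid_layout()
  fs <- 1000
  lp <- latent_population(n_units = 1, duration = 20, k_true = 1,
                          base_rate = 10, fs = fs, seed = 41)
  emg <- toy_emg(lp$pop, lay, centers = 25, fs = fs, noise_sd = 0.2,
                 seed = 42)
  times <- spike_times(lp$pop, "u001")
  tpl <- spike_triggered_average(emg$emg, times, fs)
  expect_equal(ncol(tpl$waveforms), round(0.05 * fs))
  truth <- emg$templates[[1]]
  pad <- (ncol(tpl$waveforms) - ncol(truth)) / 2
  expect_gt(cor(as.vector(tpl$waveforms[25, ]),
                c(rep(0, pad), truth[25, ], rep(0, pad))),
            0.95)

  # single spike: the template is the raw windowed signal
  one <- spike_triggered_average(emg$emg, times[5], fs)
  s <- round(times[5] * fs) + 1 - floor(round(0.05 * fs) / 2)
  expect_equal(one$waveforms, emg$emg[, s:(s + ncol(one$waveforms) - 1)])

  expect_error(spike_triggered_average(emg$emg, 0.001, fs), "full")
})

test_that("noise-only template amplitude shrinks like 1/sqrt(spike count)", {
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    emg <- matrix(rnorm(4 * 40000), 4)
    t_few <- sort(runif(25, 1, 18))
    t_many <- sort(runif(400, 1, 18))
    few <- spike_triggered_average(emg, t_few, 2048)
    many <- spike_triggered_average(emg, t_many, 2048)
    sd(few$waveforms) / sd(many$waveforms)
  }, numeric(1))
  expect_equal(mean(ratios), sqrt(400 / 25), tolerance = 0.25)
})

test_that("amplitude maps are non-negative, blur-correct and permutation-equivariant", {
  lay <- grid_layout()
  # interior delta of 9 -> blurred 3x3 patch of ones (fully in-bounds kernel)
  w <- matrix(0, 60, 10)
  delta_ch <- 6 + (3 - 1) * 12 # row 6, col 3
  w[delta_ch, 3] <- 9
  m <- amplitude_map(w, lay)
  expect_equal(m[5:7, 2:4], matrix(1, 3, 3))
  expect_equal(sum(m > 0), 9)

  # constant map is unchanged (edge renormalization)
  const <- matrix(5, 60, 4)
  const[, 2] <- -5
  expect_equal(amplitude_map(const, lay), matrix(10, 12, 5))

  set.seed(8)
  wr <- matrix(rnorm(60 * 20), 60)
  expect_true(all(amplitude_map(wr, lay) >= 0))

  perm <- sample(60)
  m1 <- amplitude_map(wr[perm, ], lay, blur = FALSE)
  m0 <- amplitude_map(wr, lay, blur = FALSE)
  expect_equal(as.vector(m1), as.vector(m0)[perm])
})

test_that("localization picks the global argmax and distances form a metric", {
  lay4 <- grid_layout(n_grids = 4)
  mk_map <- function(r, c, amp = 1) {
    m <- matrix(0, 12, 5)
    m[r, c] <- amp
    m
  }
  maps_a <- list(mk_map(3, 2, 5), mk_map(1, 1, 1), mk_map(1, 1, 0.5),
                 mk_map(1, 1, 0.2))
  loc_a <- locate_unit(maps_a, lay4)
  expect_equal(loc_a$grid, 1)
  expect_equal(unname(c(loc_a$row, loc_a$col)), c(3, 2))
  expect_equal(unit_distance(loc_a, loc_a), 0)
  expect_equal(locate_and_distance(maps_a, maps_a, lay4), 0)

  set.seed(12)
  pos <- electrode_positions(lay4)
  tri <- pos[sample(nrow(pos), 3), ]
  d12 <- unit_distance(tri[1, ], tri[2, ])
  d13 <- unit_distance(tri[1, ], tri[3, ])
  d23 <- unit_distance(tri[2, ], tri[3, ])
  expect_equal(d12, unit_distance(tri[2, ], tri[1, ]))
  expect_lte(d13, d12 + d23 + 1e-12)

  # tie: lowest (grid, row, col) wins with a warning
  tie <- list(mk_map(2, 2), mk_map(2, 2), mk_map(1, 1, 0.3), mk_map(1, 1, 0.1))
  expect_warning(loc_t <- locate_unit(tie, lay4), "tie")
  expect_equal(loc_t$grid, 1)
})

test_that("toy EMG argmax localization finds the seeded channel at moderate SNR", {
  hits <- vapply(1:10, function(s) {
    lay <- grid_layout()
    lp <- latent_population(n_units = 1, duration = 10, k_true = 1,
                            base_rate = 12, fs = 1024, seed = 800 + s)
    ctr <- 29 + (s %% 3) # rows 5-7 of col 3: interior channels, where the
    # blurred argmax is unbiased (the renormalized edge kernel pulls the
    # argmax outward for sources one electrode from a grid edge)
    emg <- toy_emg(lp$pop, lay, centers = ctr, fs = 1024, amp = 1,
                   noise_sd = 0.2, seed = 900 + s)
    tpl <- spike_triggered_average(emg$emg, spike_times(lp$pop, "u001"), 1024)
    m <- amplitude_map(tpl, lay)
    hit <- which(m == max(m), arr.ind = TRUE)[1, ]
    ch <- hit[1] + (hit[2] - 1) * 12
    ch == ctr
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
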