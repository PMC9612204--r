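test_that("center window extraction follows the midpoint convention", {
  fs <- 500
  m <- matrix(seq_len(184 * fs), nrow = 1)  # sample index as value
  w <- extract_center_window(m, fs, 30)
  expect_equal(ncol(w), 30 * fs)
  # 184 s segment: window covers [77 s, 107 s)
  expect_equal(w[1, 1], 77 * fs + 1)
  expect_equal(w[1, ncol(w)], 107 * fs)
  # whole segment at the boundary
  m30 <- matrix(seq_len(30 * fs), nrow = 1)
  expect_equal(extract_center_window(m30, fs, 30), m30)
  # odd leftover: extra sample goes before the window
  modd <- matrix(seq_len(11), nrow = 1)
  expect_equal(extract_center_window(modd, 1, 10)[1, 1], 2)
  expect_error(extract_center_window(matrix(1:100, 1), fs, 30),
               "shorter than")
})

test_that("Welch PSD satisfies Parseval on a pure sinusoid", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  psd <- welch_psd(x, fs)
  df <- psd$freqs[2] - psd$freqs[1]
  expect_equal(df, 0.5)
  band <- psd$freqs >= 8 & psd$freqs <= 13
  expect_equal(sum(psd$power[1, band]) * df, 0.5, tolerance = 0.05)
})

test_that("Welch PSD of white noise is flat at sigma^2 / (fs/2)", {
  set.seed(20)
  fs <- 250
  sigma <- 3
  x <- rnorm(60 * fs, sd = sigma)
  psd <- welch_psd(x, fs)
  sel <- psd$freqs > 5 & psd$freqs < 100
  expect_equal(mean(psd$power[1, sel]), sigma^2 / (fs / 2), tolerance = 0.1)
})

test_that("Welch PSD scaling and degenerate inputs behave", {
  set.seed(21)
  fs <- 250
  x <- matrix(rnorm(2 * 20 * fs), nrow = 2)
  p1 <- welch_psd(x, fs)
  p2 <- welch_psd(2 * x, fs)
  expect_equal(p2$power, 4 * p1$power, tolerance = 1e-6)
  expect_true(all(welch_psd(matrix(0, 2, fs * 4), fs)$power == 0))
  expect_true(all(p1$power >= 0))
  expect_error(welch_psd(matrix(1:10, 1), fs), "shorter than")
})

test_that("estimator variance shrinks with record length", {
  set.seed(22)
  fs <- 250
  dens_sd <- vapply(c(10, 80), function(dur) {
    reps <- vapply(1:8, function(i) {
      p <- welch_psd(rnorm(dur * fs), fs)
      mean(p$power[1, p$freqs > 5 & p$freqs < 100])
    }, 0)
    stats::sd(reps)
  }, 0)
  expect_lt(dens_sd[2], dens_sd[1])
})

test_that("alpha band power averages in-band bins and finds the peak", {
  fs <- 500
  psd <- welch_psd(matrix(rnorm(2 * 20 * fs), 2), fs)
  # constant density -> mean power equals the constant
  psd$power[] <- 3.3
  bp <- alpha_band_power(psd)
  expect_equal(bp$power$power, c(3.3, 3.3))
  expect_gte(bp$peak_freq, 8); expect_lte(bp$peak_freq, 13)
  psd$power[] <- 0
  expect_equal(alpha_band_power(psd)$power$power, c(0, 0))
  psd$freqs <- psd$freqs / 100
  expect_error(alpha_band_power(psd), "outside")
})

test_that("simulated eyes-closed alpha peaks at the configured frequency", {
  a <- fix_cohort_analysis()$analyses[[1]]
  expect_lte(abs(a$alpha$eyes_closed$peak_freq - 10), 0.5)
})

test_that("topography reproduces constants and localizes point sources", {
  tt <- builtin_layout("ten_twenty")
  tp <- topography(rep(2.5, 64), tt, grid_n = 40)
  vals <- tp$grid$value[!is.na(tp$grid$value)]
  expect_lt(max(abs(vals - 2.5)), 1e-6)

  v <- rep(0, 64); v[match("Cz", tt$label)] <- 1
  tp2 <- topography(v, tt, grid_n = 40)
  peak <- tp2$grid[which.max(tp2$grid$value), ]
  cell <- 2 * tp2$radius / 39
  cz <- tp2$electrodes[tp2$electrodes$label == "Cz", ]
  expect_lt(sqrt((peak$x - cz$x)^2 + (peak$y - cz$y)^2), 2 * cell)
})

test_that("simulated alpha topography is posterior-dominant", {
  a <- fix_cohort_analysis()$analyses[[1]]
  tp <- topography(a$alpha$eyes_closed$power$power, a$layout, grid_n = 40)
  on_head <- tp$grid[!is.na(tp$grid$value), ]
  peak <- on_head[which.max(on_head$value), ]
  expect_lt(peak$y, -tp$radius / 3)  # lower (posterior) third of the disk
})
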