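sinusoid_matrix <- function(freq, fs = 500, dur = 10, n_ch = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  matrix(rep(sin(2 * pi * freq * t), n_ch), nrow = n_ch, byrow = TRUE)
}

rms <- function(m) sqrt(mean(m^2))

test_that("band-pass + notch meet their attenuation contract", {
  fs <- 500
  # 50 Hz: attenuated by at least 30 dB
  x50 <- sinusoid_matrix(50, fs)
  y50 <- apply_filters(x50, filter_spec(), fs)
  mid <- 1001:4000  # avoid transients at the edges
  expect_lt(20 * log10(rms(y50[, mid]) / rms(x50[, mid])), -30)
  # 10 Hz: passed within 1 dB
  x10 <- sinusoid_matrix(10, fs)
  y10 <- apply_filters(x10, filter_spec(), fs)
  expect_lt(abs(20 * log10(rms(y10[, mid]) / rms(x10[, mid]))), 1)
  # DC removed by the 1 Hz high-pass
  dc <- matrix(5, 2, fs * 10)
  ydc <- apply_filters(dc, filter_spec(), fs)
  expect_lt(max(abs(ydc[, mid])), 0.05)
})

test_that("filter specs violating Nyquist are rejected", {
  expect_error(apply_filters(sinusoid_matrix(10, 100, 2),
                             filter_spec(band = c(1, 60)), 100), "Nyquist")
  expect_error(apply_filters(sinusoid_matrix(10), filter_spec()),
               "sampling_rate")
  expect_error(filter_spec(band = c(40, 1)))
})

test_that("channel rating flags isoelectric and artifactual channels", {
  fs <- 500
  set.seed(10)
  n_win <- 10
  clean <- matrix(rnorm(5 * n_win * fs, sd = 10), nrow = 5)
  m <- rbind(clean, 0)  # all-zero channel
  r <- rate_channels(m, fs, labels = c(paste0("c", 1:5), "flat"))
  expect_identical(r$verdict[6], "bad")
  expect_identical(r$reason[6], "isoelectric")
  expect_true(all(r$verdict[1:5] == "good"))

  # 600 uV noise in 6 of 10 windows -> bad, artifact, bad_fraction 0.6
  art <- clean
  art[3, 1:(6 * fs)] <- rnorm(6 * fs, sd = 600)
  r2 <- rate_channels(art, fs, labels = paste0("c", 1:5))
  expect_identical(r2$verdict[3], "bad")
  expect_identical(r2$reason[3], "artifact")
  expect_equal(r2$bad_fraction[3], 0.6)
})

test_that("channel rating is invariant to channel order", {
  fs <- 500
  set.seed(11)
  m <- matrix(rnorm(6 * 5 * fs, sd = 10), nrow = 6)
  m[2, ] <- 0
  labels <- paste0("c", 1:6)
  r <- rate_channels(m, fs, labels = labels)
  perm <- c(4, 2, 6, 1, 3, 5)
  rp <- rate_channels(m[perm, ], fs, labels = labels[perm])
  expect_equal(rp[order(match(rp$channel, labels)), ],
               r[order(match(r$channel, labels)), ], ignore_attr = TRUE)
})

test_that("clean simulated channels rate good; too-short segments error", {
  s <- fix_cohort()$sessions[[1]]
  filt <- apply_filters(s, filter_spec())
  r <- rate_channels(segment_data(filt, "eyes_closed"), s$sampling_rate,
                     labels = s$layout$label)
  good_truth <- setdiff(s$layout$label, s$true_bad_channels)
  expect_true(all(r$verdict[r$channel %in% good_truth] == "good"))
  expect_true(all(r$verdict[r$channel %in% s$true_bad_channels] == "bad"))
  expect_error(rate_channels(matrix(rnorm(300), 2), 500),
               "too short")
})

test_that("to_combined interpolates to 128 rows with native pass-through", {
  tt <- builtin_layout("ten_twenty")
  f <- y20_field(layout_positions(tt))
  m <- outer(f, sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)))  # smooth field
  out <- to_combined(m, tt, character(), fix_combined())
  expect_equal(nrow(out), 128)
  idx <- match(tt$label, fix_combined()$label)
  expect_equal(out[idx, ], m, ignore_attr = TRUE)

  # a bad channel is reconstructed from its neighbours within 5%
  bad_ch <- "Pz"
  out2 <- to_combined(m, tt, bad_ch, fix_combined())
  i <- match(bad_ch, fix_combined()$label)
  truth <- m[match(bad_ch, tt$label), ]
  expect_lt(max(abs(out2[i, ] - truth)) / diff(range(m)), 0.05)

  expect_error(to_combined(m, tt, "NotAChannel", fix_combined()),
               "not in layout")
  expect_error(to_combined(m, tt, tt$label[1:60], fix_combined()),
               "good channels")
})

test_that("common average reference zeroes the spatial mean", {
  set.seed(12)
  m <- matrix(rnorm(64 * 100), 64)
  out <- common_average_reference(m)
  expect_lt(max(abs(colMeans(out))), 1e-9)
  expect_equal(common_average_reference(out), out)  # idempotent
  two <- rbind(a = c(1, 4), b = c(3, 0))
  expect_equal(common_average_reference(two),
               rbind(a = c(-1, 2), b = c(1, -2)), ignore_attr = TRUE)
  expect_error(common_average_reference(m[1, , drop = FALSE]), "2 channels")
})

test_that("filtering and re-referencing commute", {
  set.seed(13)
  fs <- 250
  m <- matrix(rnorm(8 * fs * 4), 8)
  a <- common_average_reference(apply_filters(m, filter_spec(), fs))
  b <- apply_filters(common_average_reference(m), filter_spec(), fs)
  expect_lt(max(abs(a - b)), 1e-6)
})
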