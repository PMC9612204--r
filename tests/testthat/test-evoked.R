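test_that("epoching cuts the 500-ms VEP window with baseline correction", {
  fs <- 500
  set.seed(30)
  n_s <- 120 * fs
  m <- matrix(rnorm(4 * n_s), 4)
  triggers <- seq(1, 110, length.out = 150)
  ep <- epoch_trials(m, fs, triggers)
  expect_equal(dim(ep$epochs), c(150, 4, 250))
  expect_equal(range(ep$times), c(-100, 398))
  # constant channel -> all zeros after baseline removal
  mc <- matrix(7, 2, 10 * fs)
  epc <- epoch_trials(mc, fs, c(2, 5))
  expect_true(all(epc$epochs == 0))
  # trigger too close to the start is dropped
  ep2 <- epoch_trials(m, fs, c(0.05, 10, 20))
  expect_equal(dim(ep2$epochs)[1], 2)
  expect_equal(ep2$n_dropped, 1)
  expect_error(epoch_trials(m, fs, 0.05), "no usable triggers")
})

test_that("trial rejection removes whole trials above threshold", {
  fs <- 500
  set.seed(31)
  m <- matrix(rnorm(2 * 30 * fs, sd = 5), 2)
  # inject a 600 uV artifact into the second trial's window on channel 1
  m[1, (10 * fs):(10 * fs + 50)] <- 600
  ep <- epoch_trials(m, fs, c(5, 10, 15))
  rej <- reject_trials(ep, 150)
  expect_identical(rej$rejected, 2L)
  expect_identical(reject_trials(ep, Inf)$rejected, integer(0))
  expect_error(reject_trials(ep, 1e-9), "rejection threshold")
})

test_that("averaging reduces noise like 1/sqrt(n)", {
  fs <- 250
  set.seed(32)
  sigma <- 4
  n_trials <- 150
  signal <- sin(2 * pi * 8 * seq(0, 0.4, by = 1 / fs))[1:100]
  trials <- array(rep(signal, each = n_trials * 2), c(n_trials, 2, 100)) +
    array(rnorm(n_trials * 2 * 100, sd = sigma), c(n_trials, 2, 100))
  ep <- structure(list(epochs = trials, times = seq_len(100),
                       rejected = integer(), n_dropped = 0,
                       channels = c("a", "b")), class = "epoch_set")
  av <- average_epochs(ep)
  resid <- av$mean - rbind(signal, signal)
  expect_equal(stats::sd(resid), sigma / sqrt(n_trials), tolerance = 0.2)
  # identical trials average to any one trial; x and -x cancel
  same <- ep; same$epochs <- array(rep(trials[1, , ], each = 3),
                                   c(3, 2, 100))
  expect_equal(average_epochs(same)$mean, trials[1, , ],
               ignore_attr = TRUE)
  anti <- ep; anti$epochs[2, , ] <- -anti$epochs[1, , ]
  anti$epochs <- anti$epochs[1:2, , , drop = FALSE]
  expect_equal(max(abs(average_epochs(anti)$mean)), 0)
})

test_that("GFPt equals brute-force per-sample population SD", {
  set.seed(33)
  m <- matrix(rnorm(64 * 200), 64, 200)
  g <- gfp_t(m)
  brute <- vapply(seq_len(200), function(j) {
    v <- m[, j]
    sqrt(sum((v - mean(v))^2) / length(v))
  }, 0)
  expect_lt(max(abs(g$gfp - brute)), 1e-12)
  # closed forms
  expect_equal(gfp_t(matrix(c(1, -1), 2, 1))$gfp, 1)
  expect_true(all(gfp_t(matrix(5, 8, 10))$gfp == 0))
  # invariance to per-sample channel-constant offsets; |alpha| scaling
  offs <- matrix(rnorm(200), 64, 200, byrow = TRUE)
  expect_equal(gfp_t(m + offs)$gfp, g$gfp, tolerance = 1e-12)
  expect_equal(gfp_t(-3 * m)$gfp, 3 * g$gfp, tolerance = 1e-12)
})

test_that("component peaks are found at the configured latencies", {
  a <- fix_cohort_analysis()$analyses[[1]]
  expect_lte(abs(a$peaks$latency[a$peaks$component == "N75"] - 72), 4)
  expect_lte(abs(a$peaks$latency[a$peaks$component == "P100"] - 120), 4)
  expect_true(all(a$peaks$amplitude >= 0))
})

test_that("peak detection handles degenerate series per contract", {
  times <- seq(-100, 398, by = 2)
  # single bump at 95 ms falls in both windows -> unresolved order
  g1 <- structure(list(gfp = exp(-((times - 95) / 5)^2), times = times),
                  class = "gfp_series")
  expect_error(find_peaks(g1), "unresolved component order")
  # flat series -> earliest sample of each window, low confidence
  g2 <- structure(list(gfp = rep(1, length(times)), times = times),
                  class = "gfp_series")
  pk <- find_peaks(g2)
  expect_equal(pk$latency, c(50, 90))
  expect_true(all(pk$low_confidence))
  expect_error(find_peaks(g2, list(N75 = c(-500, 0))), "outside")
})

test_that("latency alignment shifts by whole samples with edge truncation", {
  a <- fix_cohort_analysis()$analyses[[1]]
  ev <- a$vep
  # null shift is the identity
  expect_equal(align_latency(ev, 72, 72)$mean, ev$mean)
  sh <- align_latency(ev, 80, 72)
  expect_equal(sh$shift_ms, -8)
  expect_equal(ncol(sh$mean), ncol(ev$mean))
  # self-consistency: after shifting, N75 lands at the reference
  own <- a$peaks$latency[a$peaks$component == "N75"]
  ref <- own + 10
  shifted <- align_latency(ev, own, ref)
  pk <- find_peaks(gfp_t(shifted))
  dt <- ev$times[2] - ev$times[1]
  expect_lte(abs(pk$latency[pk$component == "N75"] - ref), dt)
  expect_error(align_latency(ev, 72, 160), "suspicious")
})
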