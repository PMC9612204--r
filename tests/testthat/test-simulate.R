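test_that("simulated sessions honor the paradigm structure", {
  cfg <- desk_config(n_subjects = 1)
  s <- fix_cohort()$sessions[[1]]
  expect_identical(s$segments$kind,
                   c("eyes_open", "eyes_closed", "blink", "vep"))
  expect_equal(length(segment_triggers(s, "vep")), cfg$n_vep_epochs)
  # blink triggers: one per beep interval
  expect_equal(length(segment_triggers(s, "blink")),
               floor(cfg$segment_durations[["blink"]] / cfg$blink_interval))
  expect_false(any(!is.finite(s$data)))
  expect_equal(nrow(s$data), 64)
})

test_that("the default configuration requests 150 VEP epochs", {
  cfg <- sim_config()
  expect_equal(cfg$n_vep_epochs, 150L)
  expect_equal(unname(cfg$segment_durations),
               c(184.0, 183.0, 67.1, 204.8))
  # trigger grid arithmetic without simulating signals: 2-s beeps in 60 s
  cfg2 <- sim_config(n_subjects = 1, seed = 42,
                     segment_durations = c(eyes_open = 40, eyes_closed = 40,
                                           blink = 60, vep = 45),
                     n_vep_epochs = 60)
  s <- simulate_session(cfg2, "S01", "gel", builtin_layout("ten_twenty"))
  expect_equal(length(segment_triggers(s$session, "blink")), 30)
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- desk_config(n_subjects = 1)
  l <- builtin_layout("equidistant")
  a <- simulate_session(cfg, "S01", "dry", l)
  b <- simulate_session(cfg, "S01", "dry", l)
  expect_identical(a$session$data, b$session$data)
  expect_identical(a$metadata, b$metadata)
  # different cap or subject gives a different stream
  c1 <- simulate_session(cfg, "S01", "gel", l)
  expect_false(identical(a$session$data, c1$session$data))
})

test_that("bad_channel_prob = 0 yields no bad channels", {
  cfg <- desk_config(n_subjects = 1, bad_channel_prob = 0)
  s <- simulate_session(cfg, "S01", "gel", builtin_layout("ten_twenty"))
  expect_identical(s$session$true_bad_channels, character(0))
})

test_that("cohorts pair one gel and one dry session per subject", {
  coh <- fix_cohort()
  expect_equal(length(coh$sessions), 6)
  expect_equal(nrow(coh$metadata), 6)
  caps <- vapply(coh$sessions, `[[`, "", "cap_type")
  ids <- vapply(coh$sessions, `[[`, "", "subject_id")
  expect_equal(unname(table(ids)), rep(2L, 3), ignore_attr = TRUE)
  expect_setequal(unique(caps), c("gel", "dry"))
})

test_that("metadata reproduces the expected directional contrasts at n = 50", {
  md <- simulate_cohort_metadata(desk_config(n_subjects = 50, seed = 7))
  prep <- tapply(md$prep_time, md$cap_type, mean)
  expect_lt(prep[["dry"]], prep[["gel"]])
  comfort <- tapply(md$comfort_end, md$cap_type, mean)
  expect_gte(comfort[["dry"]], comfort[["gel"]])  # higher value = less comfort
  imp <- tapply(vapply(md$impedance_start, mean, 0), md$cap_type, mean)
  expect_gt(imp[["dry"]], imp[["gel"]])
})

test_that("metadata-only simulation equals the full cohort's metadata", {
  coh <- fix_cohort()
  expect_equal(simulate_cohort_metadata(desk_config()), coh$metadata)
})

test_that("eyes-closed alpha dominates eyes-open at occipital electrodes", {
  s <- fix_cohort()$sessions[[1]]
  pos <- layout_positions(s$layout)
  oz <- c(0, -sin(72 * pi / 180), cos(72 * pi / 180))
  occ <- which(acos(pmin(1, pos %*% oz)) < 40 * pi / 180)
  fs <- s$sampling_rate
  p_cl <- welch_psd(segment_data(s, "eyes_closed")[occ, , drop = FALSE], fs)
  p_op <- welch_psd(segment_data(s, "eyes_open")[occ, , drop = FALSE], fs)
  a_cl <- alpha_band_power(p_cl)
  a_op <- alpha_band_power(p_op)
  expect_gt(mean(a_cl$power$power), mean(a_op$power$power))
  # spectral maximum (above the 1/f rolloff knee) falls in the alpha band
  sel <- p_cl$freqs >= 3
  peak_f <- p_cl$freqs[sel][which.max(colMeans(p_cl$power[, sel]))]
  expect_gte(peak_f, 8); expect_lte(peak_f, 13)
})

test_that("blink transients are frontal-dominant by at least 5x", {
  s <- fix_cohort()$sessions[[1]]
  tr <- segment_triggers(s, "blink") -
    s$segments$start[s$segments$kind == "blink"]
  av <- average_epochs(epoch_trials(segment_data(s, "blink"),
                                    s$sampling_rate, tr,
                                    window = c(-500, 1000),
                                    baseline = TRUE))
  lab <- s$layout$label
  frontal <- max(abs(av$mean[lab %in% c("Fpz", "Fp1", "Fp2", "1L", "1R"), ]))
  occip <- max(abs(av$mean[lab %in% c("Oz", "O1", "O2"), ]))
  expect_gte(frontal / occip, 5)
})
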