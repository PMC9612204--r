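test_that("channel reliability is the good/total ratio", {
  ratings <- tibble::tibble(
    channel = rep("Cz", 4), segment = c("a", "b", "c", "d"),
    verdict = c("good", "good", "good", "bad"),
    cap_type = "dry", layout = "equidistant")
  rel <- channel_reliability(ratings)
  expect_equal(rel$reliability, 0.75)
  expect_equal(rel$n_good, 3); expect_equal(rel$n_total, 4)

  all_good <- ratings; all_good$verdict <- "good"
  expect_equal(channel_reliability(all_good)$reliability, 1)
})

test_that("reliability is permutation-invariant and bounded", {
  set.seed(50)
  ratings <- tibble::tibble(
    channel = rep(paste0("c", 1:8), times = 12),
    verdict = sample(c("good", "bad"), 96, replace = TRUE),
    cap_type = rep(c("gel", "dry"), each = 48),
    layout = "ten_twenty")
  rel <- channel_reliability(ratings)
  perm <- ratings[sample(nrow(ratings)), ]
  rel_p <- channel_reliability(perm)
  expect_equal(dplyr::arrange(tibble::as_tibble(rel_p), cap_type, channel),
               dplyr::arrange(tibble::as_tibble(rel), cap_type, channel))
  expect_true(all(rel$reliability >= 0 & rel$reliability <= 1))
})

test_that("reliability estimates match the binomial generating rate", {
  # 20 subjects x 4 segments rated per channel, bad with p = 0.2
  set.seed(51)
  p_good <- 0.8
  n_seq <- 20 * 4
  ratings <- tidyr::expand_grid(channel = paste0("c", 1:16),
                                seq_i = seq_len(n_seq))
  ratings$verdict <- ifelse(stats::rbinom(nrow(ratings), 1, p_good) == 1,
                            "good", "bad")
  ratings$cap_type <- "dry"; ratings$layout <- "equidistant"
  rel <- channel_reliability(ratings)
  ci_half <- 1.96 * sqrt(p_good * (1 - p_good) / n_seq)
  # every channel within a generous (3 SE) band, the grand mean much tighter
  expect_true(all(abs(rel$reliability - p_good) <=
                    3 * sqrt(p_good * (1 - p_good) / n_seq)))
  expect_lt(abs(mean(rel$reliability) - p_good), ci_half / 2)
  gl <- glance(rel)
  expect_setequal(gl$level, c("cap_layout", "cap", "overall"))
})

test_that("impedance summary averages start/end then subjects", {
  md <- tibble::tibble(
    subject_id = c("S01", "S02"), cap_type = "gel", layout = "ten_twenty",
    impedance_start = list(c(Cz = 100, Pz = 10), c(Cz = 20, Pz = 30)),
    impedance_end = list(c(Cz = 200, Pz = 20), c(Cz = 40, Pz = 10)))
  s <- impedance_summary(md)
  cz <- s$per_electrode[s$per_electrode$channel == "Cz", ]
  expect_equal(cz$mean_impedance, mean(c(150, 30)))
  expect_equal(s$grand$mean_impedance, mean(c(150, 30, 15, 20)))

  bad <- md
  bad$impedance_end[[1]] <- c(Cz = 200)  # Pz missing from the end map
  expect_error(impedance_summary(bad), "electrode sets differ")
})

test_that("simulated dry impedances exceed gel impedances", {
  md <- simulate_cohort_metadata(desk_config(n_subjects = 20, seed = 3))
  s <- impedance_summary(md)
  agg <- tapply(s$grand$mean_impedance, s$grand$cap_type, mean)
  expect_gt(agg[["dry"]], agg[["gel"]])
})

test_that("metadata summary reproduces the printed-value arithmetic", {
  # one subject per cap holding the grand-average values exactly
  md <- tibble::tibble(
    cap_type = c("gel", "dry"),
    prep_time = c(32.3, 12.4), acquisition_time = c(21.3, 23.4),
    attention_start = c(3.3, 3.2), attention_end = c(3.6, 3.7),
    comfort_start = c(2.4, 3.6), comfort_end = c(2.5, 4.3))
  s <- metadata_summary(md)
  expect_equal(s$prep_time_ratio, 0.38)
  expect_equal(s$prep_time_reduction_pct, 62)
  expect_true(all(s$by_cap$degenerate_sd))
  expect_true(all(s$by_cap$sd == 0))

  same <- md; same$prep_time <- c(20, 20)
  s2 <- metadata_summary(same)
  expect_equal(s2$prep_time_ratio, 1.0)
  expect_equal(s2$prep_time_reduction_pct, 0)
  expect_equal(glance(s)$prep_time_reduction_pct, 62)
})
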