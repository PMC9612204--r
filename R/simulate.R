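#' Simulate one EEG session
#'
#' Generates a four-segment recording (eyes open, eyes closed, triggered eye
#' blinks, pattern-reversal VEP) with the statistical structure the analysis
#' pipeline assumes:
#' * background: 1/f ("pink") noise per channel plus white sensor noise;
#' * alpha: an amplitude-modulated sinusoid at `alpha_freq`, spatially
#'   weighted toward occipito-parietal electrodes (maximal near Oz), with a
#'   larger amplitude during eyes-closed;
#' * blinks: a stereotyped biphasic ~300 ms transient added at each beep
#'   trigger, weighted toward frontal electrodes;
#' * VEP: negative N75 and positive P100 Gaussian-windowed lobes over
#'   occipital electrodes added at each reversal trigger;
#' * bad channels: each channel is independently bad for the whole session
#'   with probability `bad_channel_prob`, and is then replaced by either a
#'   near-isoelectric trace or high-amplitude noise (equal probability);
#' * impedances: log-normal per cap, with the dry cap elevated
#'   centro-parietally.
#'
#' The same `(config, subject_id, cap_type, layout, seed)` always produces
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @param subject_id subject identifier string.
#' @param cap_type `"gel"` or `"dry"`.
#' @param layout an [eeg_layout()] (64 channels in the study design).
#' @param seed integer seed for this session; defaults to a stream derived
#'   from `config$seed` and the session identity.
#' @return list with elements `session` (an [eeg_session()]) and `metadata`
#'   (a one-row tibble of subject metadata, impedance maps as list-columns).
#' @export
simulate_session <- function(config, subject_id, cap_type, layout,
                             seed = NULL) {
  validate_sim_config(config)
  cap_type <- match.arg(cap_type, c("gel", "dry"))
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, subject_id, cap_type)
  }
  fs <- config$sampling_rate
  kinds <- c("eyes_open", "eyes_closed", "blink", "vep")
  durs <- config$segment_durations[kinds]
  starts <- cumsum(c(0, utils::head(durs, -1)))
  names(starts) <- kinds
  n_total <- sum(round(durs * fs))
  n_ch <- nrow(layout)
  pos <- layout_positions(layout)

  # spatial weights from geometry, not labels, so any layout works
  w_occ <- spatial_weight(pos, center = sph_vec(72 * pi / 180, pi),
                          width_deg = 40)
  w_front <- spatial_weight(pos, center = sph_vec(72 * pi / 180, 0),
                            width_deg = 35)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(derive_seed(seed, 1L))
  data <- pink_noise_matrix(n_ch, n_total, fs, config$pink_exponent,
                            config$pink_sd)
  data <- data + matrix(stats::rnorm(n_ch * n_total, sd = config$noise_sd),
                        nrow = n_ch)

  # alpha rhythm over the whole recording; amplitude depends on segment kind
  set.seed(derive_seed(seed, 2L))
  t_all <- (seq_len(n_total) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.3 * sin(2 * pi * 0.08 * t_all + stats::runif(1, 0, 2 * pi))
  alpha_wave <- env * sin(2 * pi * config$alpha_freq * t_all + phase)
  amp_by_kind <- c(eyes_open = config$alpha_amp_open,
                   eyes_closed = config$alpha_amp_closed,
                   blink = config$alpha_amp_open,
                   vep = config$alpha_amp_open)
  amp_t <- numeric(n_total)
  for (k in kinds) {
    idx <- seg_sample_range(starts[k], durs[k], fs, n_total)
    amp_t[idx] <- amp_by_kind[k]
  }
  data <- data + outer(w_occ, amp_t * alpha_wave)

  # triggered eye blinks
  blink_trig <- starts["blink"] +
    seq_len(floor(durs["blink"] / config$blink_interval)) *
    config$blink_interval
  blink_trig <- blink_trig[blink_trig <= starts["blink"] + durs["blink"]]
  tmpl <- blink_template(fs)
  for (tr in blink_trig) {
    i0 <- round(tr * fs) + 1
    idx <- i0:min(n_total, i0 + length(tmpl) - 1)
    data[, idx] <- data[, idx] +
      config$blink_amp * outer(w_front, tmpl[seq_along(idx)])
  }

  # pattern-reversal VEP: n_vep_epochs reversals evenly spaced in the segment
  n_ep <- config$n_vep_epochs
  vep_trig <- starts["vep"] +
    seq(1, durs["vep"] - 0.5, length.out = n_ep)
  comp <- vep_template(fs, config)
  for (tr in vep_trig) {
    i0 <- round(tr * fs) + 1
    idx <- i0:min(n_total, i0 + length(comp) - 1)
    data[, idx] <- data[, idx] + outer(w_occ, comp[seq_along(idx)])
  }

  # bad channels: isoelectric or high-amplitude noise, whole session
  set.seed(derive_seed(seed, 3L))
  is_bad <- stats::runif(n_ch) < config$bad_channel_prob
  bad_iso <- stats::runif(n_ch) < 0.5
  for (ci in which(is_bad)) {
    data[ci, ] <- if (bad_iso[ci]) {
      stats::rnorm(n_total, sd = 0.01)
    } else {
      stats::rnorm(n_total, sd = 150)
    }
  }

  segments <- tibble::tibble(
    kind = kinds,
    start = as.numeric(starts),
    duration = as.numeric(durs),
    triggers = list(numeric(), numeric(), as.numeric(blink_trig),
                    as.numeric(vep_trig)))

  session <- eeg_session(data, fs, layout, segments,
                         subject_id = subject_id, cap_type = cap_type,
                         true_bad_channels = layout$label[is_bad])

  set.seed(derive_seed(seed, 4L))
  metadata <- simulate_metadata(config, subject_id, cap_type, layout, pos)
  list(session = session, metadata = metadata)
}

seg_sample_range <- function(start, dur, fs, n_total) {
  from <- round(start * fs) + 1
  to <- min(n_total, round((start + dur) * fs))
  from:to
}

# Gaussian falloff with angular distance from a scalp location
spatial_weight <- function(pos, center, width_deg) {
  cosang <- pos %*% center
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  ang <- acos(cosang) * 180 / pi
  as.numeric(exp(-(ang / width_deg)^2 / 2))
}

# biphasic ~300 ms blink transient, unit peak amplitude
blink_template <- function(fs) {
  t <- seq(0, 0.3, by = 1 / fs)
  w <- exp(-((t - 0.10) / 0.04)^2 / 2) - 0.3 * exp(-((t - 0.22) / 0.05)^2 / 2)
  w / max(w)
}

# N75 (negative) + P100 (positive) Gaussian lobes, latencies/amps from config
vep_template <- function(fs, config) {
  t <- seq(0, 0.35, by = 1 / fs) * 1000  # ms post-trigger
  sd_ms <- config$component_width
  -config$n75_amp * exp(-((t - config$n75_latency) / sd_ms)^2 / 2) +
    config$p100_amp * exp(-((t - config$p100_latency) / sd_ms)^2 / 2)
}

# 1/f^beta background noise via spectral shaping, per channel, SD normalized
pink_noise_matrix <- function(n_ch, n, fs, exponent, sd_target) {
  if (sd_target <= 0) return(matrix(0, n_ch, n))
  freqs <- seq(0, fs - fs / n, by = fs / n)
  half <- floor(n / 2)
  shape <- numeric(n)
  f_pos <- freqs[2:(half + 1)]
  shape[2:(half + 1)] <- f_pos^(-exponent / 2)
  if (n %% 2 == 0) {
    shape[(half + 2):n] <- rev(shape[2:half])
  } else {
    shape[(half + 2):n] <- rev(shape[2:(half + 1)])
  }
  out <- matrix(0, n_ch, n)
  for (ci in seq_len(n_ch)) {
    spec <- stats::fft(stats::rnorm(n)) * shape
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[ci, ] <- x / stats::sd(x) * sd_target
  }
  out
}

simulate_metadata <- function(config, subject_id, cap_type, layout, pos) {
  mp <- config$metadata_params[[cap_type]]
  ip <- config$impedance_params[[cap_type]]
  rtrunc <- function(mean, sd, lower) max(lower, stats::rnorm(1, mean, sd))
  rscale <- function(mean, sd, upper) {
    min(upper, max(1, round(stats::rnorm(1, mean, sd))))
  }
  # dry impedances elevated centro-parietally (around CPz)
  scale <- rep(1, nrow(pos))
  if (cap_type == "dry") {
    cs <- config$impedance_params$dry_central_scale
    scale <- 1 + (cs - 1) *
      spatial_weight(pos, sph_vec(18 * pi / 180, pi), width_deg = 45)
  }
  imp_start <- stats::rlnorm(nrow(pos), ip$meanlog + log(scale), ip$sdlog)
  imp_end <- imp_start * stats::rlnorm(nrow(pos), 0, 0.15)
  names(imp_start) <- names(imp_end) <- layout$label
  tibble::tibble(
    subject_id = subject_id,
    cap_type = cap_type,
    layout = attr(layout, "layout_kind"),
    prep_time = rtrunc(mp$prep[1], mp$prep[2], 1),
    acquisition_time = rtrunc(mp$acq[1], mp$acq[2], 5),
    attention_start = rscale(mp$attention[1], mp$attention[2],
                             config$attention_scale_max),
    attention_end = rscale(mp$attention[3], mp$attention[4],
                           config$attention_scale_max),
    comfort_start = rscale(mp$comfort[1], mp$comfort[2],
                           config$comfort_scale_max),
    comfort_end = rscale(mp$comfort[3], mp$comfort[4],
                         config$comfort_scale_max),
    impedance_start = list(imp_start),
    impedance_end = list(imp_end))
}

#' Simulate a paired gel/dry cohort
#'
#' One gel and one dry session per subject. Cap/layout pairings mirror the
#' multi-center validation design this pipeline targets: the gel cap uses
#' the extended ten-twenty or the
#' equidistant layout with equal probability, the dry cap mostly the
#' equidistant layout (with a 20% chance of ten-twenty).
#'
#' @param config a [sim_config()].
#' @param layouts optional named list with elements `ten_twenty` and
#'   `equidistant`; defaults to the built-in layouts.
#' @return list with `sessions` (list of [eeg_session()], gel and dry
#'   interleaved per subject), `metadata` (tibble, one row per session) and
#'   `config`.
#' @export
simulate_cohort <- function(config, layouts = NULL) {
  validate_sim_config(config)
  if (is.null(layouts)) {
    layouts <- list(ten_twenty = builtin_layout("ten_twenty"),
                    equidistant = builtin_layout("equidistant"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  sessions <- list()
  meta <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    set.seed(derive_seed(config$seed, i, 99L))
    gel_layout <- if (stats::runif(1) < 0.5) "ten_twenty" else "equidistant"
    dry_layout <- if (stats::runif(1) < 0.2) "ten_twenty" else "equidistant"
    for (cap in c("gel", "dry")) {
      lay <- layouts[[if (cap == "gel") gel_layout else dry_layout]]
      res <- simulate_session(config, sid, cap, lay)
      sessions[[length(sessions) + 1]] <- res$session
      meta[[length(meta) + 1]] <- res$metadata
    }
  }
  list(sessions = sessions, metadata = dplyr::bind_rows(meta),
       config = config)
}

#' Simulate cohort metadata only
#'
#' Draws the per-session subject metadata (times, ratings, impedances) of
#' [simulate_cohort()] without synthesizing any signal data. Uses the same
#' derived random streams, so the returned tibble is identical to the
#' `metadata` element of the full cohort for the same configuration.
#'
#' @inheritParams simulate_cohort
#' @return metadata tibble, one row per session.
#' @export
simulate_cohort_metadata <- function(config, layouts = NULL) {
  validate_sim_config(config)
  if (is.null(layouts)) {
    layouts <- list(ten_twenty = builtin_layout("ten_twenty"),
                    equidistant = builtin_layout("equidistant"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  meta <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    set.seed(derive_seed(config$seed, i, 99L))
    gel_layout <- if (stats::runif(1) < 0.5) "ten_twenty" else "equidistant"
    dry_layout <- if (stats::runif(1) < 0.2) "ten_twenty" else "equidistant"
    for (cap in c("gel", "dry")) {
      lay <- layouts[[if (cap == "gel") gel_layout else dry_layout]]
      session_seed <- derive_seed(config$seed, sid, cap)
      set.seed(derive_seed(session_seed, 4L))
      meta[[length(meta) + 1]] <-
        simulate_metadata(config, sid, cap, lay, layout_positions(lay))
    }
  }
  dplyr::bind_rows(meta)
}
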