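#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-session generator. Defaults are the
#' study conditions the pipeline is designed around: 500 Hz sampling, segment
#' durations of 184.0 / 183.0 / 67.1 / 204.8 s (eyes open, eyes closed, blink,
#' pattern-reversal VEP), 150 VEP epochs, blink beeps every 2 s, a 10 Hz
#' occipito-parietal alpha rhythm stronger with eyes closed, N75/P100
#' components at 72/120 ms, and cap-dependent log-normal electrode-skin
#' impedances (gel in the tens of kOhm, dry in the hundreds, elevated
#' centro-parietally).
#'
#' @param n_subjects number of volunteers (each gets one gel and one dry
#'   session).
#' @param sampling_rate Hz, >= 200.
#' @param seed master seed; all per-subject / per-segment streams are derived
#'   from it, so a cohort is reproducible independent of execution order.
#' @param segment_durations named numeric: seconds for `eyes_open`,
#'   `eyes_closed`, `blink`, `vep`.
#' @param alpha_freq alpha rhythm frequency, Hz.
#' @param alpha_amp_closed,alpha_amp_open alpha amplitude at the occipital
#'   maximum, uV.
#' @param noise_sd white sensor-noise SD, uV.
#' @param pink_sd broadband background (1/f) SD, uV.
#' @param pink_exponent spectral exponent of the background.
#' @param blink_amp blink-artifact peak amplitude at the frontal maximum, uV.
#' @param blink_interval beep interval in the blink segment, s.
#' @param n_vep_epochs number of pattern reversals in the VEP segment.
#' @param n75_latency,p100_latency component latencies, ms.
#' @param n75_amp,p100_amp component peak amplitudes at the occipital
#'   maximum, uV.
#' @param component_width temporal SD of each Gaussian component lobe, ms.
#' @param bad_channel_prob probability that a channel is bad for a session.
#' @param impedance_params per-cap log-normal parameters (kOhm scale):
#'   list with elements `gel` and `dry`, each `list(meanlog, sdlog)`, plus
#'   `dry_central_scale`, the multiplicative impedance elevation at
#'   centro-parietal sites for the dry cap.
#' @param attention_scale_max,comfort_scale_max upper bounds of the rating
#'   scales (sleepiness-type attention scale and pain-type comfort scale).
#' @param metadata_params per-cap normal location/spread for preparation and
#'   acquisition times (min) and start/end attention and comfort ratings.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       sampling_rate = 500,
                       seed = 1L,
                       segment_durations = c(eyes_open = 184.0,
                                             eyes_closed = 183.0,
                                             blink = 67.1,
                                             vep = 204.8),
                       alpha_freq = 10,
                       alpha_amp_closed = 20,
                       alpha_amp_open = 5,
                       noise_sd = 2,
                       pink_sd = 10,
                       pink_exponent = 1.0,
                       blink_amp = 150,
                       blink_interval = 2,
                       n_vep_epochs = 150,
                       n75_latency = 72,
                       p100_latency = 120,
                       n75_amp = 7.38,
                       p100_amp = 17.57,
                       component_width = 10,
                       bad_channel_prob = 0.1,
                       impedance_params = list(
                         gel = list(meanlog = log(15), sdlog = 1.0),
                         dry = list(meanlog = log(350), sdlog = 0.7),
                         dry_central_scale = 1.8),
                       attention_scale_max = 8,
                       comfort_scale_max = 10,
                       metadata_params = list(
                         gel = list(prep = c(32.3, 13.8),
                                    acq = c(21.3, 9.3),
                                    attention = c(3.3, 1.6, 3.6, 1.9),
                                    comfort = c(2.4, 1.3, 2.5, 1.4)),
                         dry = list(prep = c(12.4, 6.5),
                                    acq = c(23.4, 8.3),
                                    attention = c(3.2, 1.6, 3.7, 1.9),
                                    comfort = c(3.6, 1.8, 4.3, 2.2)))) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              sampling_rate = sampling_rate, seed = as.integer(seed),
              segment_durations = segment_durations,
              alpha_freq = alpha_freq,
              alpha_amp_closed = alpha_amp_closed,
              alpha_amp_open = alpha_amp_open,
              noise_sd = noise_sd, pink_sd = pink_sd,
              pink_exponent = pink_exponent,
              blink_amp = blink_amp, blink_interval = blink_interval,
              n_vep_epochs = as.integer(n_vep_epochs),
              n75_latency = n75_latency, p100_latency = p100_latency,
              n75_amp = n75_amp, p100_amp = p100_amp,
              component_width = component_width,
              bad_channel_prob = bad_channel_prob,
              impedance_params = impedance_params,
              attention_scale_max = attention_scale_max,
              comfort_scale_max = comfort_scale_max,
              metadata_params = metadata_params)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  stopifnot_msg(cfg$sampling_rate >= 200, "sampling_rate must be >= 200 Hz")
  amps <- c(cfg$alpha_amp_closed, cfg$alpha_amp_open, cfg$noise_sd,
            cfg$pink_sd, cfg$blink_amp, cfg$n75_amp, cfg$p100_amp)
  stopifnot_msg(all(amps >= 0), "amplitudes must be >= 0")
  stopifnot_msg(cfg$bad_channel_prob >= 0 && cfg$bad_channel_prob <= 1,
                "bad_channel_prob must be in [0, 1]")
  kinds <- c("eyes_open", "eyes_closed", "blink", "vep")
  stopifnot_msg(all(kinds %in% names(cfg$segment_durations)),
                "segment_durations must name eyes_open, eyes_closed, blink, vep")
  stopifnot_msg(all(cfg$segment_durations > 0), "segment durations must be > 0")
  stopifnot_msg(cfg$blink_interval > 0, "blink_interval must be > 0")
  stopifnot_msg(cfg$n_vep_epochs >= 1, "n_vep_epochs must be >= 1")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if ("segment_durations" %in% names(raw)) {
    raw$segment_durations <- unlist(raw$segment_durations)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$segment_durations <- as.list(x$segment_durations)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Deterministic sub-stream derivation: successive integer keys are folded
# into the master seed with a multiplicative-congruential mix (mod 2^31 - 1),
# so (seed, subject, cap, stage) pin down an independent stream regardless of
# the order sessions are generated in.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647)
  for (v in keys) {
    v <- if (is.character(v)) sum(utf8ToInt(v) * seq_along(utf8ToInt(v))) else v
    h <- (h * 69069 + as.double(v) %% 2147483647 * 40503 + 12345) %% 2147483647
  }
  as.integer(h)
}
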