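#' Analysis parameters
#'
#' Tunables of the per-session analysis chain, with the defaults the
#' pipeline is designed around: 30-s centered resting-state windows, 2-s
#' Hamming Welch windows with 50% overlap (0.5 Hz resolution), the 8--13 Hz
#' alpha band, 500-ms VEP epochs (100 ms pre-stimulus), 150 uV peak-to-peak
#' trial rejection, and N75/P100 search windows of 50--100 / 90--170 ms.
#'
#' @param psd_window_s centered resting-state analysis window, s.
#' @param welch_window_s,welch_overlap Welch taper length (s) and fractional
#'   overlap.
#' @param band spectral band of interest, Hz.
#' @param epoch_window_ms VEP epoch window relative to the reversal, ms.
#' @param reject_ptp_uv peak-to-peak trial-rejection threshold, uV.
#' @param peak_windows_ms named list of GFPt component search windows, ms.
#' @param blink_overlay_s durations of the short and long blink overlays, s.
#' @param filter a [filter_spec()].
#' @param rate_params,spline_params named lists forwarded to
#'   [rate_channels()] / [fit_spline()].
#' @return a list of class `analysis_params`.
#' @export
analysis_params <- function(psd_window_s = 30, welch_window_s = 2,
                            welch_overlap = 0.5, band = c(8, 13),
                            epoch_window_ms = c(-100, 400),
                            reject_ptp_uv = 150,
                            peak_windows_ms = list(N75 = c(50, 100),
                                                   P100 = c(90, 170)),
                            blink_overlay_s = c(2, 10),
                            filter = filter_spec(),
                            rate_params = list(),
                            spline_params = list()) {
  structure(list(psd_window_s = psd_window_s,
                 welch_window_s = welch_window_s,
                 welch_overlap = welch_overlap, band = band,
                 epoch_window_ms = epoch_window_ms,
                 reject_ptp_uv = reject_ptp_uv,
                 peak_windows_ms = peak_windows_ms,
                 blink_overlay_s = blink_overlay_s,
                 filter = filter, rate_params = rate_params,
                 spline_params = spline_params),
            class = "analysis_params")
}

#' Analyze one session end to end
#'
#' Runs the preprocessing chain ([preprocess_session()]) and the three
#' segment analyses on the combined montage: resting-state Welch PSD and
#' alpha band power for eyes open and eyes closed, blink overlays (short
#' trials centered on each beep and long trials spanning 5 consecutive
#' beeps, both from the center of the blink segment), and the VEP chain
#' (epoching, trial rejection, averaging, GFPt, component peaks).
#'
#' @param session an [eeg_session()].
#' @param combined the combined target [eeg_layout()].
#' @param params an [analysis_params()].
#' @return list of class `session_analysis` with elements `subject_id`,
#'   `cap_type`, `source_layout`, `ratings`, `bad`, `psd` (list
#'   `eyes_open` / `eyes_closed` of `psd_result`), `alpha` (list of
#'   `band_power`), `blink_short` / `blink_long` (`evoked_waveform`), `vep`
#'   (`evoked_waveform`), `gfp` (`gfp_series`), `peaks` (tibble), `layout`.
#' @export
analyze_session <- function(session, combined, params = analysis_params()) {
  pp <- preprocess_session(session, combined, spec = params$filter,
                           rate_params = params$rate_params,
                           spline_params = params$spline_params)
  fs <- session$sampling_rate

  psd <- list(); alpha <- list()
  for (k in c("eyes_open", "eyes_closed")) {
    win <- extract_center_window(pp$segments[[k]], fs, params$psd_window_s)
    psd[[k]] <- welch_psd(win, fs, params$welch_window_s,
                          params$welch_overlap)
    alpha[[k]] <- alpha_band_power(psd[[k]], params$band)
  }

  # blink overlays; trigger times are absolute, make them segment-relative
  seg_i <- which(session$segments$kind == "blink")
  blink_rel <- segment_triggers(session, "blink") -
    session$segments$start[seg_i]
  short_ms <- params$blink_overlay_s[1] / 2 * 1000
  bl_short <- epoch_trials(pp$segments$blink, fs, blink_rel,
                           window = c(-short_ms, short_ms),
                           baseline = FALSE) |> average_epochs()
  # long trials span 5 consecutive beeps, anchored on every 5th beep
  long_anchor <- blink_rel[seq(1, length(blink_rel) - 4, by = 5)]
  bl_long <- if (length(long_anchor) >= 1) {
    epoch_trials(pp$segments$blink, fs, long_anchor,
                 window = c(-short_ms,
                            params$blink_overlay_s[2] * 1000 - short_ms),
                 baseline = FALSE) |> average_epochs()
  }

  seg_v <- which(session$segments$kind == "vep")
  vep_rel <- segment_triggers(session, "vep") - session$segments$start[seg_v]
  vep <- epoch_trials(pp$segments$vep, fs, vep_rel,
                      window = params$epoch_window_ms) |>
    reject_trials(params$reject_ptp_uv) |>
    average_epochs()
  gfp <- gfp_t(vep)
  peaks <- find_peaks(gfp, params$peak_windows_ms)

  structure(list(subject_id = session$subject_id,
                 cap_type = session$cap_type,
                 source_layout = attr(session$layout, "layout_kind"),
                 ratings = pp$ratings, bad = pp$bad,
                 psd = psd, alpha = alpha,
                 blink_short = bl_short, blink_long = bl_long,
                 vep = vep, gfp = gfp, peaks = peaks,
                 layout = combined),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf(
    "<session_analysis %s/%s (%s): %d bad ch, alpha peak %.2f Hz, N75 %g ms, P100 %g ms>\n",
    x$subject_id, x$cap_type, x$source_layout, length(x$bad),
    x$alpha$eyes_closed$peak_freq,
    x$peaks$latency[x$peaks$component == "N75"],
    x$peaks$latency[x$peaks$component == "P100"]))
  invisible(x)
}

#' Analyze every session of a cohort
#'
#' @param cohort a [simulate_cohort()] result (or any list with `sessions`
#'   and `metadata`).
#' @param combined combined target layout; defaults to the union of the two
#'   built-in layouts.
#' @param params an [analysis_params()].
#' @param progress print one line per session?
#' @return list of class `cohort_analysis`: `analyses` (list of
#'   `session_analysis`), `ratings` (tibble over all sessions with
#'   `subject_id`, `cap_type`, `layout` columns), `metadata`, `layout`.
#' @export
analyze_cohort <- function(cohort, combined = NULL,
                           params = analysis_params(), progress = FALSE) {
  if (is.null(combined)) {
    combined <- combined_layout(builtin_layout("ten_twenty"),
                                builtin_layout("equidistant"))
  }
  analyses <- lapply(cohort$sessions, function(s) {
    if (progress) {
      message("analyzing ", s$subject_id, "/", s$cap_type)
    }
    analyze_session(s, combined, params)
  })
  ratings <- purrr::map_dfr(analyses, function(a) {
    dplyr::mutate(a$ratings, subject_id = a$subject_id,
                  cap_type = a$cap_type, layout = a$source_layout)
  })
  structure(list(analyses = analyses, ratings = ratings,
                 metadata = cohort$metadata, layout = combined,
                 params = params,
                 config = cohort$config),
            class = "cohort_analysis")
}
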