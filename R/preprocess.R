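#' Filtering specification
#'
#' Defaults follow standard clinical-band EEG preprocessing: a 1--40 Hz
#' Butterworth band-pass whose asymptotic slope of 24 dB/octave corresponds
#' to order 4, and a 50 Hz notch realized as an order-3 Butterworth band-stop
#' over 49--51 Hz. Filters are applied forward--backward (zero phase), which
#' preserves evoked-component latencies.
#'
#' @param band band-pass cut-off frequencies, Hz.
#' @param band_order Butterworth order of the band-pass.
#' @param notch notch band-stop edges, Hz; `NULL` disables the notch.
#' @param notch_order Butterworth order of the band-stop.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(band = c(1, 40), band_order = 4,
                        notch = c(49, 51), notch_order = 3) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  structure(list(band = band, band_order = band_order, notch = notch,
                 notch_order = notch_order), class = "filter_spec")
}

#' Apply band-pass and notch filters to a session or matrix
#'
#' @param x an [eeg_session()] or a channels x samples matrix.
#' @param spec a [filter_spec()].
#' @param sampling_rate required when `x` is a matrix.
#' @return object of the same type as `x`, filtered per channel.
#' @export
apply_filters <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  if (inherits(x, "eeg_session")) {
    x$data <- apply_filters(x$data, spec, x$sampling_rate)
    return(x)
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("sampling_rate required for matrix input",
                        call. = FALSE)
  nyq <- fs / 2
  if (spec$band[2] >= nyq) {
    stop("band-pass upper edge ", spec$band[2],
         " Hz violates Nyquist (fs/2 = ", nyq, " Hz)", call. = FALSE)
  }
  bp <- signal::butter(spec$band_order, spec$band / nyq, type = "pass")
  bs <- if (!is.null(spec$notch)) {
    if (spec$notch[2] >= nyq) {
      stop("notch upper edge violates Nyquist", call. = FALSE)
    }
    signal::butter(spec$notch_order, spec$notch / nyq, type = "stop")
  }
  out <- x
  for (ci in seq_len(nrow(x))) {
    y <- signal::filtfilt(bp, x[ci, ])
    if (!is.null(bs)) y <- signal::filtfilt(bs, y)
    out[ci, ] <- y
  }
  if (any(!is.finite(out))) stop("filtering produced non-finite samples",
                                 call. = FALSE)
  out
}

#' Rate channels of one segment as good or bad
#'
#' Automated surrogate for visual channel inspection: the segment is split
#' into 1-s windows, and a window fails as *isoelectric* when its SD falls
#' below `iso_threshold`, or as *artifact* when its peak-to-peak exceeds
#' `ptp_threshold` or its SD exceeds `sd_factor` times the median window SD
#' across channels. A channel is rated bad when at least half of its windows
#' fail; the dominant failure mode gives the reason.
#'
#' @param segment_data channels x samples matrix, uV.
#' @param sampling_rate Hz.
#' @param labels channel labels (defaults to rownames).
#' @param iso_threshold SD below which a window counts as isoelectric, uV.
#' @param ptp_threshold peak-to-peak above which a window counts as
#'   artifactual, uV.
#' @param sd_factor multiple of the cross-channel median window SD above
#'   which a window counts as artifactual.
#' @param bad_fraction_min fraction of failing windows at which a channel is
#'   rated bad.
#' @return tibble with columns `channel`, `verdict` (`"good"`/`"bad"`),
#'   `reason` (`"artifact"`, `"isoelectric"`, `"none"`), `bad_fraction`.
#' @export
rate_channels <- function(segment_data, sampling_rate,
                          labels = rownames(segment_data),
                          iso_threshold = 0.1, ptp_threshold = 400,
                          sd_factor = 8, bad_fraction_min = 0.5) {
  m <- as.matrix(segment_data)
  fs <- sampling_rate
  n_win <- floor(ncol(m) / fs)
  if (n_win < 2) stop("segment too short to rate (need >= 2 s)",
                      call. = FALSE)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(m)))
  n_ch <- nrow(m)
  win_sd <- matrix(0, n_ch, n_win)
  win_ptp <- matrix(0, n_ch, n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * fs + 1):(w * fs)
    seg <- m[, idx, drop = FALSE]
    win_sd[, w] <- apply(seg, 1, stats::sd)
    win_ptp[, w] <- apply(seg, 1, function(v) diff(range(v)))
  }
  med_sd <- apply(win_sd, 2, stats::median)
  iso <- win_sd < iso_threshold
  art <- win_ptp > ptp_threshold |
    win_sd > sd_factor * matrix(med_sd, n_ch, n_win, byrow = TRUE)
  fail <- iso | art
  bad_fraction <- rowMeans(fail)
  verdict <- ifelse(bad_fraction >= bad_fraction_min, "bad", "good")
  reason <- ifelse(verdict == "good", "none",
                   ifelse(rowSums(iso) >= rowSums(art & !iso),
                          "isoelectric", "artifact"))
  tibble::tibble(channel = labels, verdict = verdict, reason = reason,
                 bad_fraction = bad_fraction)
}

#' Interpolate a recording to the combined 128-channel montage
#'
#' Fits a spherical spline on the good source electrodes only (bad channels
#' are excluded before fitting) and evaluates it at every electrode of the
#' combined layout. Good native channels pass through unchanged; bad native
#' channels and all novel positions are interpolated.
#'
#' @param data channels x samples matrix on `source_layout`.
#' @param source_layout the recording's [eeg_layout()].
#' @param bad character vector of bad channel labels (subset of the source
#'   labels).
#' @param combined the target [eeg_layout()] (e.g.
#'   `combined_layout(builtin_layout("ten_twenty"), builtin_layout("equidistant"))`).
#' @param ... passed to [fit_spline()].
#' @return matrix `nrow(combined)` x samples, rows ordered as `combined`.
#' @export
to_combined <- function(data, source_layout, bad = character(), combined,
                        ...) {
  m <- as.matrix(data)
  stopifnot(nrow(m) == nrow(source_layout))
  unknown <- setdiff(bad, source_layout$label)
  if (length(unknown) > 0) {
    stop("bad channels not in layout: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  good <- !(source_layout$label %in% bad)
  if (sum(good) < 16) {
    stop("only ", sum(good), " good channels; need at least 16 to interpolate",
         call. = FALSE)
  }
  model <- fit_spline(layout_positions(source_layout)[good, , drop = FALSE],
                      ...)
  out <- interpolate_spline(model, m[good, , drop = FALSE],
                            layout_positions(combined))
  # native good channels pass through unchanged
  pass <- match(source_layout$label[good], combined$label)
  keep <- !is.na(pass)
  out[pass[keep], ] <- m[good, , drop = FALSE][keep, ]
  rownames(out) <- combined$label
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every sample.
#'
#' @param data channels x samples matrix.
#' @return matrix of the same shape with zero channel-mean at every sample.
#' @export
common_average_reference <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) < 2) stop("need at least 2 channels", call. = FALSE)
  sweep(m, 2, colMeans(m))
}

#' Preprocess a session to the combined montage
#'
#' The full preprocessing chain: zero-phase band-pass + notch filtering,
#' automated per-segment bad-channel rating, spherical-spline interpolation
#' of every segment onto the combined 128-channel layout (bad channels
#' excluded from the fit), and common average referencing.
#'
#' A channel is excluded from interpolation when it is rated bad in *any*
#' segment; per-segment ratings are returned for reliability scoring.
#'
#' @param session an [eeg_session()].
#' @param combined the combined target [eeg_layout()].
#' @param spec a [filter_spec()].
#' @param rate_params optional named list overriding [rate_channels()]
#'   thresholds.
#' @param spline_params optional named list overriding [fit_spline()]
#'   parameters.
#' @return list with `segments` (named list of 128 x samples matrices, one
#'   per segment kind, common-average referenced), `ratings` (tibble of
#'   per-segment channel ratings with a `segment` column), `bad` (labels
#'   excluded from the fit), `layout` (the combined layout), `session`
#'   (the filtered input session).
#' @export
preprocess_session <- function(session, combined, spec = filter_spec(),
                               rate_params = list(),
                               spline_params = list()) {
  filtered <- apply_filters(session, spec)
  kinds <- filtered$segments$kind
  ratings <- purrr::map_dfr(kinds, function(k) {
    sd_k <- segment_data(filtered, k)
    r <- do.call(rate_channels,
                 c(list(segment_data = sd_k,
                        sampling_rate = filtered$sampling_rate,
                        labels = filtered$layout$label), rate_params))
    r$segment <- k
    r
  })
  bad <- unique(ratings$channel[ratings$verdict == "bad"])
  segs <- lapply(kinds, function(k) {
    m <- do.call(to_combined,
                 c(list(data = segment_data(filtered, k),
                        source_layout = filtered$layout, bad = bad,
                        combined = combined), spline_params))
    common_average_reference(m)
  })
  names(segs) <- kinds
  list(segments = segs, ratings = ratings, bad = bad, layout = combined,
       session = filtered)
}
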