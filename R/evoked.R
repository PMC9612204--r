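#' Epoch a recording around trigger times
#'
#' Cuts trials from `window[1]` to `window[2]` ms around each trigger and
#' baseline-corrects each trial per channel by subtracting the mean of the
#' pre-stimulus interval (disable with `baseline = FALSE`). Triggers whose
#' window would exceed the recording bounds are dropped (their count is
#' recorded in `n_dropped`).
#'
#' @param data channels x samples matrix, uV.
#' @param sampling_rate Hz.
#' @param triggers trigger times in seconds, absolute within `data`.
#' @param window epoch window relative to the trigger, ms; the 500 ms VEP
#'   epoch (100 ms pre-stimulus) by default.
#' @param baseline apply pre-stimulus baseline correction?
#' @return object of class `epoch_set`: `epochs` (array trials x channels x
#'   samples), `times` (ms), `rejected` (integer trial indices), `n_dropped`,
#'   `channels`.
#' @export
epoch_trials <- function(data, sampling_rate, triggers,
                         window = c(-100, 400), baseline = TRUE) {
  m <- as.matrix(data)
  fs <- sampling_rate
  i_pre <- round(window[1] / 1000 * fs)
  i_post <- round(window[2] / 1000 * fs)
  n_s <- i_post - i_pre                  # half-open window [pre, post)
  times <- (i_pre:(i_post - 1)) / fs * 1000
  onsets <- round(triggers * fs) + 1
  usable <- onsets + i_pre >= 1 & onsets + i_post - 1 <= ncol(m)
  n_dropped <- sum(!usable)
  onsets <- onsets[usable]
  if (length(onsets) == 0) {
    stop("no usable triggers: every epoch window exceeds the recording",
         call. = FALSE)
  }
  ep <- array(0, dim = c(length(onsets), nrow(m), n_s))
  pre_idx <- which(times < 0)
  for (k in seq_along(onsets)) {
    idx <- (onsets[k] + i_pre):(onsets[k] + i_post - 1)
    trial <- m[, idx, drop = FALSE]
    if (baseline && length(pre_idx) > 0) {
      trial <- trial - rowMeans(trial[, pre_idx, drop = FALSE])
    }
    ep[k, , ] <- trial
  }
  structure(list(epochs = ep, times = times, rejected = integer(),
                 n_dropped = n_dropped, channels = rownames(m)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<epoch_set: %d trials x %d ch x %d samples (%g..%g ms), %d rejected, %d dropped>\n",
    d[1], d[2], d[3], min(x$times), max(x$times), length(x$rejected),
    x$n_dropped))
  invisible(x)
}

#' Reject artifactual trials
#'
#' Automated surrogate for visual trial inspection: a trial is rejected when
#' any channel's peak-to-peak amplitude within the epoch exceeds the
#' threshold; rejection removes the whole trial across all channels.
#'
#' @param epochs an [epoch_trials()] result.
#' @param ptp_threshold peak-to-peak rejection threshold, uV.
#' @return the `epoch_set` with `rejected` updated.
#' @export
reject_trials <- function(epochs, ptp_threshold = 150) {
  d <- dim(epochs$epochs)
  ptp_max <- vapply(seq_len(d[1]), function(k) {
    tr <- epochs$epochs[k, , , drop = FALSE]
    max(apply(matrix(tr, d[2], d[3]), 1, function(v) diff(range(v))))
  }, numeric(1))
  rejected <- which(ptp_max > ptp_threshold)
  if (length(rejected) == d[1]) {
    stop("all ", d[1], " trials exceed the ", ptp_threshold,
         " uV rejection threshold", call. = FALSE)
  }
  epochs$rejected <- rejected
  epochs
}

#' Average the kept trials of an epoch set
#'
#' @param epochs an [epoch_trials()] result (after optional
#'   [reject_trials()]).
#' @return object of class `evoked_waveform`: `mean` (channels x samples,
#'   uV), `times` (ms), `n_trials_used`, `channels`, `shift_ms` (latency
#'   correction applied so far, see [align_latency()]).
#' @export
average_epochs <- function(epochs) {
  d <- dim(epochs$epochs)
  keep <- setdiff(seq_len(d[1]), epochs$rejected)
  if (length(keep) == 0) stop("no kept trials to average", call. = FALSE)
  avg <- apply(epochs$epochs[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- epochs$channels
  structure(list(mean = avg, times = epochs$times,
                 n_trials_used = length(keep), channels = epochs$channels,
                 shift_ms = 0),
            class = "evoked_waveform")
}

#' @export
print.evoked_waveform <- function(x, ...) {
  cat(sprintf(
    "<evoked_waveform: %d ch x %d samples (%g..%g ms), %d trials, shift %g ms>\n",
    nrow(x$mean), ncol(x$mean), min(x$times), max(x$times),
    x$n_trials_used, x$shift_ms))
  invisible(x)
}

#' Global field power in time (GFPt)
#'
#' Per time sample, the population standard deviation (divisor N, the
#' channel count) of the instantaneous potential distribution across all
#' electrodes. Adding a channel-constant offset at a sample (e.g. a
#' reference shift) leaves it unchanged.
#'
#' @param x an `evoked_waveform` or a channels x samples matrix.
#' @return object of class `gfp_series`: `gfp` (uV, >= 0), `times` (ms, or
#'   sample index when `x` is a bare matrix).
#' @export
gfp_t <- function(x) {
  if (inherits(x, "evoked_waveform")) {
    m <- x$mean
    times <- x$times
  } else {
    m <- as.matrix(x)
    times <- seq_len(ncol(m))
  }
  if (nrow(m) < 2) stop("GFPt needs at least 2 channels", call. = FALSE)
  mu <- colMeans(m)
  g <- sqrt(colMeans(sweep(m, 2, mu)^2))
  structure(list(gfp = g, times = times), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series: %d samples, max %.3g uV>\n", length(x$gfp),
              max(x$gfp)))
  invisible(x)
}

#' Detect evoked-component peaks in a GFPt series
#'
#' For each named component, the latency is the argmax of GFPt within its
#' search window (ties broken toward the earliest sample, flagged
#' low-confidence when the window is flat). Component order must be
#' anatomically consistent: the P100 latency must exceed the N75 latency,
#' otherwise detection fails with both candidates reported.
#'
#' @param gfp a [gfp_t()] result with a millisecond time axis.
#' @param windows named list of search windows (ms); defaults bracket the
#'   canonical pattern-reversal components.
#' @return tibble with columns `component`, `latency` (ms), `amplitude`
#'   (GFPt at the peak, uV), `low_confidence`.
#' @export
find_peaks <- function(gfp,
                       windows = list(N75 = c(50, 100), P100 = c(90, 170))) {
  if (min(unlist(windows)) < min(gfp$times) ||
      max(unlist(windows)) > max(gfp$times)) {
    stop("peak search window outside the GFP time axis", call. = FALSE)
  }
  rows <- purrr::imap(windows, function(w, nm) {
    in_w <- which(gfp$times >= w[1] & gfp$times <= w[2])
    g <- gfp$gfp[in_w]
    i <- in_w[which.max(g)]             # which.max takes the earliest tie
    tibble::tibble(component = nm, latency = gfp$times[i],
                   amplitude = gfp$gfp[i],
                   low_confidence = max(g) - min(g) < 1e-12)
  })
  out <- dplyr::bind_rows(rows)
  if (all(c("N75", "P100") %in% out$component)) {
    l75 <- out$latency[out$component == "N75"]
    l100 <- out$latency[out$component == "P100"]
    if (l100 <= l75) {
      stop(sprintf(
        "unresolved component order: N75 candidate at %g ms, P100 candidate at %g ms",
        l75, l100), call. = FALSE)
    }
  }
  out
}

#' Shift an evoked waveform to a reference N75 latency
#'
#' Compensates for center-dependent stimulation-trigger latency: the
#' waveform (and its GFPt) is shifted by `reference_n75 - own_n75`, rounded
#' to whole samples, with edge truncation (vacated samples repeat the edge
#' value; there is no wrap-around). The applied shift is stored in
#' `shift_ms`.
#'
#' @param evoked an `evoked_waveform`.
#' @param own_n75 this recording's N75 latency, ms.
#' @param reference_n75 the reference N75 latency, ms.
#' @param max_shift_ms largest plausible correction; larger requests error.
#' @return the shifted `evoked_waveform`.
#' @export
align_latency <- function(evoked, own_n75, reference_n75,
                          max_shift_ms = 50) {
  shift_ms <- reference_n75 - own_n75
  if (abs(shift_ms) > max_shift_ms) {
    stop("suspicious latency shift of ", shift_ms, " ms (limit ",
         max_shift_ms, " ms)", call. = FALSE)
  }
  dt <- evoked$times[2] - evoked$times[1]
  k <- round(shift_ms / dt)
  if (k == 0) {
    evoked$shift_ms <- evoked$shift_ms + 0
    return(evoked)
  }
  n <- ncol(evoked$mean)
  src <- pmin(pmax(seq_len(n) - k, 1), n)   # edge truncation
  evoked$mean <- evoked$mean[, src, drop = FALSE]
  evoked$shift_ms <- evoked$shift_ms + k * dt
  evoked
}
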