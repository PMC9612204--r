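#' EEG session recordings
#'
#' An `eeg_session` is one cap application for one subject: a channels x
#' samples matrix in uV, its sampling rate, the electrode layout (rows of
#' `data` correspond 1:1 to layout electrodes), and segment annotations with
#' trigger times. Simulated sessions also carry the ground-truth list of bad
#' channels.
#'
#' @param data numeric matrix, channels x samples, uV; rownames are ignored
#'   (the layout defines channel identity and order).
#' @param sampling_rate Hz.
#' @param layout an [eeg_layout()] with one electrode per data row.
#' @param segments tibble with columns `kind` (`eyes_open`, `eyes_closed`,
#'   `blink`, `vep`), `start` (s), `duration` (s) and a list-column
#'   `triggers` of trigger times (s, absolute).
#' @param subject_id,cap_type session identity; `cap_type` is `"gel"` or
#'   `"dry"`.
#' @param true_bad_channels character vector of simulated bad-channel labels
#'   (empty for real data).
#' @return an object of class `eeg_session`.
#' @export
eeg_session <- function(data, sampling_rate, layout, segments,
                        subject_id = "S01", cap_type = c("gel", "dry"),
                        true_bad_channels = character()) {
  cap_type <- match.arg(cap_type)
  data <- as.matrix(data)
  if (nrow(data) != nrow(layout)) {
    stop("data has ", nrow(data), " rows but layout has ", nrow(layout),
         " electrodes", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("session data contains non-finite samples",
                                  call. = FALSE)
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("kind", "start", "duration", "triggers") %in%
                  names(segments)))
  ends <- segments$start + segments$duration
  ord <- order(segments$start)
  if (any(segments$start[ord][-1] < ends[ord][-nrow(segments)] - 1e-9)) {
    stop("segments overlap", call. = FALSE)
  }
  for (i in seq_len(nrow(segments))) {
    tr <- segments$triggers[[i]]
    if (length(tr) > 0 &&
        (min(tr) < segments$start[i] - 1e-9 || max(tr) > ends[i] + 1e-9)) {
      stop("trigger outside its segment ('", segments$kind[i], "')",
           call. = FALSE)
    }
  }
  rownames(data) <- layout$label
  structure(list(subject_id = subject_id, cap_type = cap_type,
                 data = data, sampling_rate = sampling_rate,
                 layout = layout, segments = segments,
                 true_bad_channels = true_bad_channels),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf(
    "<eeg_session %s/%s: %d ch x %d samples @ %g Hz (%s), %d segments>\n",
    x$subject_id, x$cap_type, nrow(x$data), ncol(x$data), x$sampling_rate,
    attr(x$layout, "layout_kind"), nrow(x$segments)))
  invisible(x)
}

#' Extract one segment's samples from a session
#'
#' @param session an `eeg_session`.
#' @param kind segment kind (`"eyes_open"`, `"eyes_closed"`, `"blink"`,
#'   `"vep"`).
#' @return channels x samples matrix for that segment.
#' @export
segment_data <- function(session, kind) {
  i <- which(session$segments$kind == kind)
  if (length(i) == 0) stop("session has no '", kind, "' segment",
                           call. = FALSE)
  i <- i[1]
  fs <- session$sampling_rate
  from <- round(session$segments$start[i] * fs) + 1
  to <- min(ncol(session$data),
            round((session$segments$start[i] +
                     session$segments$duration[i]) * fs))
  session$data[, from:to, drop = FALSE]
}

#' Trigger times of one segment, relative to recording start
#'
#' @inheritParams segment_data
#' @return numeric vector of trigger times (s).
#' @export
segment_triggers <- function(session, kind) {
  i <- which(session$segments$kind == kind)
  if (length(i) == 0) stop("session has no '", kind, "' segment",
                           call. = FALSE)
  session$segments$triggers[[i[1]]]
}
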