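#' Extract a centered analysis window from a segment
#'
#' Returns a contiguous window of `duration` seconds centered on the segment
#' midpoint. When the leftover sample count is odd the extra sample is placed
#' before the window.
#'
#' @param segment_data channels x samples matrix.
#' @param sampling_rate Hz.
#' @param duration window length, s.
#' @return channels x `duration * sampling_rate` matrix.
#' @export
extract_center_window <- function(segment_data, sampling_rate,
                                  duration = 30) {
  m <- as.matrix(segment_data)
  n_want <- round(duration * sampling_rate)
  if (ncol(m) < n_want) {
    stop("segment (", ncol(m), " samples) shorter than analysis window (",
         n_want, " samples)", call. = FALSE)
  }
  lead <- ceiling((ncol(m) - n_want) / 2)
  m[, (lead + 1):(lead + n_want), drop = FALSE]
}

#' Welch power spectral density
#'
#' Hamming-tapered segments of `window_length` seconds with the given
#' fractional overlap; modified periodograms are averaged per channel and
#' scaled as a one-sided density (uV^2/Hz), so the integral over frequency
#' recovers signal variance. Frequency resolution is `1/window_length`.
#'
#' @param data channels x samples matrix (a plain vector is treated as one
#'   channel), uV.
#' @param sampling_rate Hz.
#' @param window_length taper length, s.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return object of class `psd_result`: list with `freqs` (Hz), `power`
#'   (channels x freqs matrix, uV^2/Hz), `window_length`, `overlap`,
#'   `n_segments`.
#' @export
welch_psd <- function(data, sampling_rate, window_length = 2,
                      overlap = 0.5) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  m <- as.matrix(data)
  fs <- sampling_rate
  nper <- round(window_length * fs)
  if (ncol(m) < nper) {
    stop("data (", ncol(m), " samples) shorter than one Welch window (",
         nper, " samples)", call. = FALSE)
  }
  stopifnot(overlap >= 0, overlap < 1)
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, ncol(m) - nper + 1, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hamming
  u <- sum(win^2)                        # window power normalization
  half <- floor(nper / 2)
  freqs <- (0:half) * fs / nper
  acc <- matrix(0, nrow(m), half + 1)
  for (s0 in starts) {
    seg <- m[, s0:(s0 + nper - 1), drop = FALSE]
    tapered <- sweep(seg, 2, win, `*`)
    spec <- t(apply(tapered, 1, function(v) {
      X <- stats::fft(v)
      Mod(X[1:(half + 1)])^2
    }))
    acc <- acc + spec
  }
  pxx <- acc / length(starts) / (fs * u)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, half + 1)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[half + 1] <- 1
  pxx <- sweep(pxx, 2, dbl, `*`)
  rownames(pxx) <- rownames(m)
  structure(list(freqs = freqs, power = pxx,
                 window_length = window_length, overlap = overlap,
                 n_segments = length(starts)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result: %d ch, %g-%g Hz (df = %g Hz), %d Welch segments>\n",
    nrow(x$power), min(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
    x$n_segments))
  invisible(x)
}

#' Tidy a PSD into a long tibble
#'
#' @param x a `psd_result`.
#' @param ... unused.
#' @return tibble with columns `channel`, `freq`, `power`.
#' @export
tidy.psd_result <- function(x, ...) {
  ch <- rownames(x$power)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(x$power)))
  tibble::tibble(channel = rep(ch, each = length(x$freqs)),
                 freq = rep(x$freqs, times = nrow(x$power)),
                 power = as.numeric(t(x$power)))
}

#' Alpha-band mean power
#'
#' Per-channel arithmetic mean of the density bins whose center frequency
#' lies in the band (edges inclusive), plus the band peak of the
#' channel-mean density.
#'
#' @param psd a [welch_psd()] result.
#' @param band frequency band, Hz; the 8--13 Hz alpha band by default.
#' @return list of class `band_power`: `band`, `power` (tibble `channel`,
#'   `power`), `peak_freq` (Hz), `peak_power` (uV^2/Hz, channel-mean density
#'   at the peak bin).
#' @export
alpha_band_power <- function(psd, band = c(8, 13)) {
  in_band <- psd$freqs >= band[1] - 1e-9 & psd$freqs <= band[2] + 1e-9
  if (!any(in_band)) {
    stop("band [", band[1], ", ", band[2],
         "] Hz outside the PSD frequency grid", call. = FALSE)
  }
  sub <- psd$power[, in_band, drop = FALSE]
  ch <- rownames(psd$power)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(psd$power)))
  mean_density <- colMeans(sub)
  peak_i <- which.max(mean_density)
  structure(list(band = band,
                 power = tibble::tibble(channel = ch,
                                        power = rowMeans(sub)),
                 peak_freq = psd$freqs[in_band][peak_i],
                 peak_power = mean_density[peak_i]),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf(
    "<band_power %g-%g Hz: peak %.3g uV^2/Hz at %.2f Hz, %d channels>\n",
    x$band[1], x$band[2], x$peak_power, x$peak_freq, nrow(x$power)))
  invisible(x)
}

#' Topographic map of a per-channel scalar
#'
#' Projects electrodes to a disk by the azimuthal-equidistant projection
#' about the vertex (radius = polar angle) and interpolates the values onto
#' a square grid with the spherical spline, masked to the head disk.
#'
#' @param values numeric vector, one value per electrode of `layout`.
#' @param layout an [eeg_layout()].
#' @param grid_n grid resolution per side.
#' @param ... passed to [fit_spline()].
#' @return list of class `eeg_topography`: `grid` (tibble `x`, `y`, `value`
#'   with off-head cells `NA`), `electrodes` (tibble `label`, `x`, `y`,
#'   `value`), `radius` (disk radius, radians).
#' @export
topography <- function(values, layout, grid_n = 64, ...) {
  stopifnot(length(values) == nrow(layout), all(is.finite(values)))
  pos <- layout_positions(layout)
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  az <- atan2(-pos[, 1], pos[, 2])       # 0 at nasion, positive to the left
  ex <- -theta * sin(az)                 # screen x: right ear positive
  ey <- theta * cos(az)                  # screen y: nasion up
  radius <- max(theta) * 1.02
  g <- seq(-radius, radius, length.out = grid_n)
  grid <- expand.grid(x = g, y = g)
  r <- sqrt(grid$x^2 + grid$y^2)
  on_head <- r <= radius
  # invert the projection: grid point -> unit sphere
  gt <- pmin(r[on_head], pi - 1e-9)
  gaz <- atan2(grid$x[on_head], grid$y[on_head])
  sphere <- cbind(x = sin(gt) * sin(gaz), y = sin(gt) * cos(gaz),
                  z = cos(gt))
  model <- fit_spline(pos, ...)
  val <- rep(NA_real_, nrow(grid))
  val[on_head] <- interpolate_spline(model, values, sphere)
  structure(list(grid = tibble::tibble(x = grid$x, y = grid$y, value = val),
                 electrodes = tibble::tibble(label = layout$label, x = ex,
                                             y = ey, value = values),
                 radius = radius),
            class = "eeg_topography")
}

#' @export
print.eeg_topography <- function(x, ...) {
  cat(sprintf("<eeg_topography: %d electrodes, %d grid cells on head>\n",
              nrow(x$electrodes), sum(!is.na(x$grid$value))))
  invisible(x)
}
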