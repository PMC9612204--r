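#' Write a session to an EDF+ file
#'
#' Minimal EDF+C writer: 16-bit samples with per-channel physical scaling
#' (physical range set symmetrically from the data maximum), 1-s data
#' records, and one "EDF Annotations" signal carrying the segment
#' annotations (`segment:<kind>` with onset and duration), the trigger times
#' (`trig:<kind>`), the ground-truth bad channels of simulated sessions
#' (`badchan:<label>`), and the exact sample count (`nsamples:<n>`, used on
#' reading to drop the zero padding of the final record). Subject id and cap
#' type travel in the patient-identification field.
#'
#' @param session an [eeg_session()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  data <- session$data
  fs <- session$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("non-finite samples", call. = FALSE)
  n_ch <- nrow(data)
  n_total <- ncol(data)
  n_rec <- ceiling(n_total / fs)

  pmax_ch <- pmax(1, apply(abs(data), 1, max) * 1.0000001)
  dig_min <- -32768L; dig_max <- 32767L

  # annotation TALs per record (record r holds annotations with onset in
  # [r-1, r) seconds; record 1 additionally holds the bookkeeping entries)
  anns <- list()
  add_ann <- function(onset, duration, text) {
    anns[[length(anns) + 1]] <<- list(onset = onset, duration = duration,
                                      text = text)
  }
  add_ann(0, NA, paste0("nsamples:", n_total))
  for (ch in session$true_bad_channels) add_ann(0, NA, paste0("badchan:", ch))
  for (i in seq_len(nrow(session$segments))) {
    sg <- session$segments[i, ]
    add_ann(sg$start, sg$duration, paste0("segment:", sg$kind))
    for (tr in sg$triggers[[1]]) add_ann(tr, NA, paste0("trig:", sg$kind))
  }
  fmt <- function(x) format(x, trim = TRUE, digits = 15, scientific = FALSE)
  tal <- function(a) {
    dur <- if (is.na(a$duration)) "" else sprintf("\x15%s", fmt(a$duration))
    sprintf("+%s%s\x14%s\x14", fmt(a$onset), dur, a$text)
  }
  rec_of <- vapply(anns, function(a) min(n_rec, floor(a$onset) + 1),
                   numeric(1))
  rec_tals <- vapply(seq_len(n_rec), function(r) {
    body <- paste(vapply(anns[rec_of == r], tal, ""), collapse = "")
    paste0(sprintf("+%d\x14\x14", r - 1), body)  # timekeeping TAL first
  }, "")
  ann_bytes <- max(nchar(rec_tals, type = "bytes")) + 2
  ann_samples <- ceiling(ann_bytes / 2)

  ns <- n_ch + 1
  header_bytes <- 256 + 256 * ns
  pad <- function(x, w) {
    x <- substr(x, 1, w)
    formatC(x, width = -w, flag = " ")
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 7), w)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s, type = "bytes"),
                              eos = NULL)
  wr(pad("0", 8))
  wr(pad(paste(session$subject_id, session$cap_type,
               attr(session$layout, "layout_kind")), 80))
  wr(pad("capcompare simulated EEG", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(as.character(header_bytes), 8))
  wr(pad("EDF+C", 44))
  wr(pad(as.character(n_rec), 8))
  wr(num(1, 8))
  wr(pad(as.character(ns), 4))
  labels <- c(substr(session$layout$label, 1, 16), "EDF Annotations")
  for (l in labels) wr(pad(l, 16))
  for (i in seq_len(ns)) wr(pad(if (i <= n_ch) "AgAgCl electrode" else "",
                                80))
  for (i in seq_len(ns)) wr(pad(if (i <= n_ch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(num(if (i <= n_ch) -pmax_ch[i] else -1, 8))
  for (i in seq_len(ns)) wr(num(if (i <= n_ch) pmax_ch[i] else 1, 8))
  for (i in seq_len(ns)) wr(num(dig_min, 8))
  for (i in seq_len(ns)) wr(num(dig_max, 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(as.character(if (i <= n_ch) fs else
    ann_samples), 8))
  for (i in seq_len(ns)) wr(pad("", 32))

  scale <- (dig_max - dig_min) / (2 * pmax_ch)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(n_ch)) {
      x <- numeric(fs)
      ok <- idx <= n_total
      x[ok] <- data[ci, idx[ok]]
      dig <- as.integer(round((x + pmax_ch[ci]) * scale[ci]) + dig_min)
      dig[dig > dig_max] <- dig_max
      writeBin(dig, con, size = 2, endian = "little")
    }
    bytes <- utf8ToInt(rec_tals[r])
    raw_ann <- c(bytes, rep(0L, 2 * ann_samples - length(bytes)))
    writeBin(as.integer(raw_ann), con, size = 1)
  }
  invisible(path)
}

#' Read a session from an EDF+ file
#'
#' Counterpart of [write_edf()]. The electrode layout is reconstructed from
#' the channel labels: labels matching a built-in layout use it; otherwise
#' `layout` must be supplied.
#'
#' @param path EDF file path.
#' @param layout optional [eeg_layout()] whose labels match the file's
#'   channels.
#' @return an [eeg_session()].
#' @export
read_edf <- function(path, layout = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (too short): ", path,
                                  call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w) stop("truncated EDF header: ", path, call. = FALSE)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF (bad version field): ", path,
                           call. = FALSE)
  patient <- rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    stop("malformed EDF header: ", path, call. = FALSE)
  }
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)

  is_ann <- labels == "EDF Annotations"
  ch_i <- which(!is_ann)
  n_ch <- length(ch_i)
  expected <- header_bytes + n_rec * sum(spr) * 2
  if (sz < expected) {
    stop("truncated EDF data (", sz, " of ", expected, " bytes): ", path,
         call. = FALSE)
  }
  data <- matrix(0, n_ch, n_rec * spr[ch_i[1]])
  ann_text <- character()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        raw <- readBin(con, "raw", 2 * spr[i])
        txt <- rawToChar(raw[raw != as.raw(0)])
        ann_text <- c(ann_text, txt)
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                       endian = "little")
        phys <- phys_min[i] + (dig - dig_min[i]) *
          (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        ci <- match(i, ch_i)
        data[ci, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
      }
    }
  }
  fs <- spr[ch_i[1]] / rec_dur

  # parse TALs back into annotations
  tals <- unlist(strsplit(paste(ann_text, collapse = ""), "\x14\\+",
                          fixed = FALSE))
  parse_one <- function(s) {
    s <- sub("^\\+", "", s)
    parts <- strsplit(s, "\x14")[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) return(NULL)
    od <- strsplit(parts[1], "\x15")[[1]]
    tibble::tibble(onset = as.numeric(od[1]),
                   duration = if (length(od) > 1) as.numeric(od[2]) else NA,
                   text = parts[2])
  }
  ann <- purrr::map_dfr(tals, parse_one)

  n_total <- n_rec * spr[ch_i[1]]
  ns_ann <- ann$text[startsWith(ann$text, "nsamples:")]
  if (length(ns_ann) > 0) {
    n_total <- as.integer(sub("nsamples:", "", ns_ann[1]))
    data <- data[, seq_len(n_total), drop = FALSE]
  }
  bad <- sub("badchan:", "", ann$text[startsWith(ann$text, "badchan:")])

  seg_ann <- ann[startsWith(ann$text, "segment:"), ]
  seg_ann <- seg_ann[order(seg_ann$onset), ]
  trig_ann <- ann[startsWith(ann$text, "trig:"), ]
  segments <- if (nrow(seg_ann) > 0) {
    tibble::tibble(
      kind = sub("segment:", "", seg_ann$text),
      start = seg_ann$onset,
      duration = seg_ann$duration,
      triggers = lapply(sub("segment:", "", seg_ann$text), function(k) {
        sort(trig_ann$onset[trig_ann$text == paste0("trig:", k)])
      }))
  } else {
    tibble::tibble(kind = "eyes_open", start = 0,
                   duration = n_total / fs, triggers = list(numeric()))
  }

  id_parts <- strsplit(patient, " +")[[1]]
  subject_id <- if (length(id_parts) >= 1) id_parts[1] else "unknown"
  cap_type <- if (length(id_parts) >= 2 && id_parts[2] %in% c("gel", "dry"))
    id_parts[2] else "gel"

  if (is.null(layout)) {
    layout <- matching_builtin_layout(labels[ch_i])
    if (is.null(layout)) {
      stop("channel labels match no built-in layout; supply `layout`",
           call. = FALSE)
    }
  }
  if (!identical(layout$label, trimws(labels[ch_i]))) {
    ord <- match(layout$label, trimws(labels[ch_i]))
    if (any(is.na(ord))) stop("layout labels do not match EDF channels",
                              call. = FALSE)
    data <- data[ord, , drop = FALSE]
  }
  eeg_session(data, fs, layout, segments, subject_id = subject_id,
              cap_type = cap_type, true_bad_channels = bad)
}

matching_builtin_layout <- function(labels) {
  labels <- trimws(labels)
  for (k in c("ten_twenty", "equidistant")) {
    l <- builtin_layout(k)
    if (setequal(l$label, labels)) return(l)
  }
  tt <- builtin_layout("ten_twenty")
  eq <- builtin_layout("equidistant")
  cb <- combined_layout(tt, eq)
  if (setequal(cb$label, labels)) return(cb)
  NULL
}
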