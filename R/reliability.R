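#' Channel reliability from good/bad ratings
#'
#' Channel reliability is the ratio of the number of "good" data sequences
#' to the total number of analyzed data sequences of a channel, computed per
#' channel within each cap type and layout (each channel of each analyzed
#' segment of each session contributes one rating).
#'
#' @param ratings tibble with at least columns `channel`, `verdict`
#'   (`"good"`/`"bad"`), `cap_type`, `layout`; typically the per-segment
#'   ratings of [preprocess_session()] augmented with session identity (as
#'   produced by [analyze_cohort()]).
#' @return tibble of class `reliability_table` with columns `cap_type`,
#'   `layout`, `channel`, `n_good`, `n_total`, `reliability`.
#' @export
channel_reliability <- function(ratings) {
  stopifnot(all(c("channel", "verdict", "cap_type", "layout") %in%
                  names(ratings)))
  out <- ratings |>
    dplyr::group_by(.data$cap_type, .data$layout, .data$channel) |>
    dplyr::summarise(n_good = sum(.data$verdict == "good"),
                     n_total = dplyr::n(),
                     reliability = .data$n_good / .data$n_total,
                     .groups = "drop")
  class(out) <- c("reliability_table", class(out))
  out
}

#' Summarise a reliability table
#'
#' Grand mean and SD of per-channel reliability. Because the aggregation
#' level of a single "average reliability" is ambiguous, three aggregations
#' are reported: per cap x layout, per cap (pooling layouts), and overall.
#'
#' @param x a [channel_reliability()] table.
#' @param ... unused.
#' @return tibble with columns `level`, `cap_type`, `layout`,
#'   `mean_reliability`, `sd_reliability`, `n_channels`.
#' @export
glance.reliability_table <- function(x, ...) {
  by_both <- x |>
    dplyr::group_by(.data$cap_type, .data$layout) |>
    dplyr::summarise(mean_reliability = mean(.data$reliability),
                     sd_reliability = stats::sd(.data$reliability),
                     n_channels = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(level = "cap_layout")
  by_cap <- x |>
    dplyr::group_by(.data$cap_type) |>
    dplyr::summarise(mean_reliability = mean(.data$reliability),
                     sd_reliability = stats::sd(.data$reliability),
                     n_channels = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(layout = NA_character_, level = "cap")
  overall <- x |>
    dplyr::summarise(mean_reliability = mean(.data$reliability),
                     sd_reliability = stats::sd(.data$reliability),
                     n_channels = dplyr::n()) |>
    dplyr::mutate(cap_type = NA_character_, layout = NA_character_,
                  level = "overall")
  dplyr::bind_rows(by_both, by_cap, overall) |>
    dplyr::select("level", "cap_type", "layout", "mean_reliability",
                  "sd_reliability", "n_channels")
}
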