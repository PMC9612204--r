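#' Per-electrode impedance summary
#'
#' For each session the start and end impedance of every electrode are
#' averaged; those per-session means are then averaged per electrode across
#' subjects within each cap type and layout. Grand means pool electrodes.
#'
#' @param metadata metadata tibble as produced by [simulate_cohort()] (one
#'   row per session with list-columns `impedance_start` / `impedance_end`,
#'   named per electrode, kOhm).
#' @return list with `per_electrode` (tibble `cap_type`, `layout`,
#'   `channel`, `mean_impedance`, `sd_impedance`, `n`) and `grand` (tibble
#'   `cap_type`, `layout`, `mean_impedance`, `sd_impedance`).
#' @export
impedance_summary <- function(metadata) {
  rows <- purrr::pmap_dfr(
    list(metadata$cap_type, metadata$layout, metadata$impedance_start,
         metadata$impedance_end, metadata$subject_id),
    function(cap, lay, st, en, sid) {
      if (!setequal(names(st), names(en))) {
        stop("start/end impedance electrode sets differ for subject ", sid,
             call. = FALSE)
      }
      en <- en[names(st)]
      tibble::tibble(cap_type = cap, layout = lay, channel = names(st),
                     impedance = (as.numeric(st) + as.numeric(en)) / 2)
    })
  per_electrode <- rows |>
    dplyr::group_by(.data$cap_type, .data$layout, .data$channel) |>
    dplyr::summarise(mean_impedance = mean(.data$impedance),
                     sd_impedance = stats::sd(.data$impedance),
                     n = dplyr::n(), .groups = "drop")
  grand <- rows |>
    dplyr::group_by(.data$cap_type, .data$layout) |>
    dplyr::summarise(mean_impedance = mean(.data$impedance),
                     sd_impedance = stats::sd(.data$impedance),
                     .groups = "drop")
  list(per_electrode = per_electrode, grand = grand)
}

#' Grand-average subject metadata per cap
#'
#' Mean and SD per cap type of preparation time, acquisition time, and
#' start/end attention and comfort ratings, plus the derived dry/gel
#' preparation-time ratio and the percent reduction in preparation time
#' (ratios to 2 decimal places, percentages to whole percent, matching how
#' such results are conventionally reported).
#'
#' @param metadata tibble with one row per session: columns `cap_type`,
#'   `prep_time`, `acquisition_time`, `attention_start`, `attention_end`,
#'   `comfort_start`, `comfort_end` (extra columns are ignored).
#' @return list of class `metadata_summary`: `by_cap` (tibble of mean/SD per
#'   cap and measure, with `degenerate_sd` flagged when a group has a single
#'   subject), `prep_time_ratio` (dry/gel, 2 d.p.), `prep_time_reduction_pct`
#'   (integer percent).
#' @export
metadata_summary <- function(metadata) {
  measures <- c("prep_time", "acquisition_time", "attention_start",
                "attention_end", "comfort_start", "comfort_end")
  stopifnot(all(c("cap_type", measures) %in% names(metadata)))
  long <- metadata |>
    dplyr::select(dplyr::all_of(c("cap_type", measures))) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value")
  by_cap <- long |>
    dplyr::group_by(.data$cap_type, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     n = dplyr::n(),
                     degenerate_sd = dplyr::n() < 2,
                     .groups = "drop")
  prep <- by_cap[by_cap$measure == "prep_time", ]
  gel <- prep$mean[prep$cap_type == "gel"]
  dry <- prep$mean[prep$cap_type == "dry"]
  ratio <- if (length(gel) == 1 && length(dry) == 1) {
    round(dry / gel, 2)
  } else {
    NA_real_
  }
  structure(list(by_cap = by_cap,
                 prep_time_ratio = ratio,
                 prep_time_reduction_pct =
                   if (is.na(ratio)) NA_real_ else round(100 * (1 - dry / gel))),
            class = "metadata_summary")
}

#' @export
print.metadata_summary <- function(x, ...) {
  cat("<metadata_summary>\n")
  print(x$by_cap)
  cat(sprintf("dry/gel preparation-time ratio: %.2f (%d%% reduction)\n",
              x$prep_time_ratio, x$prep_time_reduction_pct))
  invisible(x)
}

#' @export
tidy.metadata_summary <- function(x, ...) x$by_cap

#' @export
glance.metadata_summary <- function(x, ...) {
  tibble::tibble(prep_time_ratio = x$prep_time_ratio,
                 prep_time_reduction_pct = x$prep_time_reduction_pct)
}
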