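#' Cap-versus-cap study report
#'
#' Assembles the full comparison layer from an analyzed cohort: grand-average
#' metadata (preparation/acquisition time, attention, comfort, with the
#' derived dry/gel preparation-time ratio), channel reliability tables,
#' impedance summaries, per-subject gel-versus-dry agreement metrics
#' (Pearson r and RMSD for the blink overlay at frontal channels, the
#' eyes-closed PSD over all combined channels, the VEP waveform over all
#' channels, and the VEP GFPt), normality (Lilliefors) checks of those
#' metrics, and Mann-Whitney U tests of alpha power and of N75/P100
#' amplitudes and latencies between caps. Per-cap grand-average VEPs are
#' built after aligning each subject's evoked response to the cap's mean
#' N75 latency.
#'
#' @param cohort_analysis an [analyze_cohort()] result.
#' @param frontal_channels channels used for the blink-overlay comparison
#'   (present in the combined layout).
#' @return list of class `study_report`; see Details. Errors when a subject
#'   is missing one of the stage outputs, naming the gaps.
#' @details Elements: `metadata_summary`, `reliability`,
#'   `reliability_summary`, `impedance`, `comparison_metrics` (per-subject
#'   tibble), `comparison_summary` (per-metric mean/SD), `normality_tests`,
#'   `u_tests`, `subject_measures` (per subject and cap: alpha power and
#'   peak frequency, component latencies/amplitudes), `grand_gfp` (per-cap
#'   grand-average GFPt with component peaks), `provenance`.
#' @export
build_report <- function(cohort_analysis,
                         frontal_channels = c("Fp1", "Fp2", "1L", "1R")) {
  ca <- cohort_analysis
  stopifnot(inherits(ca, "cohort_analysis"))
  required <- c("alpha", "blink_short", "vep", "gfp", "peaks", "ratings")
  gaps <- purrr::map_dfr(ca$analyses, function(a) {
    miss <- required[vapply(required, function(f) is.null(a[[f]]),
                            logical(1))]
    if (length(miss) == 0) return(NULL)
    tibble::tibble(subject_id = a$subject_id, cap_type = a$cap_type,
                   missing = paste(miss, collapse = ", "))
  })
  if (nrow(gaps) > 0) {
    stop("incomplete report; missing stage outputs:\n",
         paste(sprintf("  %s/%s: %s", gaps$subject_id, gaps$cap_type,
                       gaps$missing), collapse = "\n"), call. = FALSE)
  }

  meta_sum <- metadata_summary(ca$metadata)
  rel <- channel_reliability(ca$ratings)
  imp <- impedance_summary(ca$metadata)

  # per-subject measures
  subject_measures <- purrr::map_dfr(ca$analyses, function(a) {
    tibble::tibble(
      subject_id = a$subject_id, cap_type = a$cap_type,
      layout = a$source_layout,
      alpha_power_closed = mean(a$alpha$eyes_closed$power$power),
      alpha_power_open = mean(a$alpha$eyes_open$power$power),
      alpha_peak_freq = a$alpha$eyes_closed$peak_freq,
      n75_latency = a$peaks$latency[a$peaks$component == "N75"],
      n75_amplitude = a$peaks$amplitude[a$peaks$component == "N75"],
      p100_latency = a$peaks$latency[a$peaks$component == "P100"],
      p100_amplitude = a$peaks$amplitude[a$peaks$component == "P100"])
  })

  # paired gel-vs-dry agreement metrics per subject
  by_subj <- split(ca$analyses,
                   vapply(ca$analyses, `[[`, "", "subject_id"))
  frontal <- intersect(frontal_channels, ca$layout$label)
  comparison_metrics <- purrr::map_dfr(by_subj, function(pair) {
    caps <- vapply(pair, `[[`, "", "cap_type")
    if (!all(c("gel", "dry") %in% caps)) return(NULL)
    g <- pair[[which(caps == "gel")]]
    d <- pair[[which(caps == "dry")]]
    fi <- match(frontal, ca$layout$label)
    metrics <- list(
      blink_frontal = list(x = as.numeric(g$blink_short$mean[fi, ]),
                           y = as.numeric(d$blink_short$mean[fi, ]),
                           unit = "uV"),
      psd_closed = list(x = as.numeric(g$psd$eyes_closed$power),
                        y = as.numeric(d$psd$eyes_closed$power),
                        unit = "uV^2/Hz"),
      vep_channels = list(x = as.numeric(g$vep$mean),
                          y = as.numeric(d$vep$mean), unit = "uV"),
      vep_gfp = list(x = g$gfp$gfp, y = d$gfp$gfp, unit = "uV"))
    purrr::imap_dfr(metrics, function(mm, nm) {
      tibble::tibble(subject_id = g$subject_id, metric = nm,
                     layout_pair = paste(g$source_layout, d$source_layout,
                                         sep = "_vs_"),
                     pearson_r = pearson_r(mm$x, mm$y),
                     rmsd = rmsd(mm$x, mm$y), unit = mm$unit)
    })
  })

  comparison_summary <- comparison_metrics |>
    dplyr::group_by(.data$metric, .data$unit) |>
    dplyr::summarise(mean_r = mean(.data$pearson_r),
                     sd_r = stats::sd(.data$pearson_r),
                     mean_rmsd = mean(.data$rmsd),
                     sd_rmsd = stats::sd(.data$rmsd),
                     n = dplyr::n(), .groups = "drop")

  # Lilliefors normality checks of the across-subject metric samples
  normality_tests <- purrr::map_dfr(
    split(comparison_metrics, comparison_metrics$metric),
    function(df) {
      if (nrow(df) < 8 || stats::sd(df$pearson_r) == 0) return(NULL)
      dplyr::mutate(ks_normality(df$pearson_r),
                    sample = paste0("pearson_r:", df$metric[1]),
                    n = nrow(df))
    })

  # Mann-Whitney U tests between caps
  u_of <- function(col, label) {
    a <- subject_measures[[col]][subject_measures$cap_type == "gel"]
    b <- subject_measures[[col]][subject_measures$cap_type == "dry"]
    dplyr::mutate(mann_whitney_u(a, b), sample = label,
                  n_gel = length(a), n_dry = length(b))
  }
  u_tests <- dplyr::bind_rows(
    u_of("alpha_power_closed", "alpha_power_closed"),
    u_of("n75_amplitude", "n75_amplitude"),
    u_of("p100_amplitude", "p100_amplitude"),
    u_of("n75_latency", "n75_latency"),
    u_of("p100_latency", "p100_latency"))

  grand_gfp <- grand_average_gfp(ca)

  provenance <- list(
    package_version = tryCatch(
      as.character(utils::packageVersion("capcompare")),
      error = function(e) NA_character_),
    seed = if (!is.null(ca$config)) ca$config$seed else NA_integer_,
    n_subjects = length(by_subj),
    config_hash = if (!is.null(ca$config)) config_hash(ca$config) else NA,
    layout = attr(ca$layout, "layout_name"))

  structure(list(metadata_summary = meta_sum,
                 reliability = rel,
                 reliability_summary = glance(rel),
                 impedance = imp,
                 comparison_metrics = comparison_metrics,
                 comparison_summary = comparison_summary,
                 normality_tests = normality_tests,
                 u_tests = u_tests,
                 subject_measures = subject_measures,
                 grand_gfp = grand_gfp,
                 provenance = provenance),
            class = "study_report")
}

# per-cap grand-average evoked response: every subject's evoked waveform is
# first shifted to the cap's mean N75 latency (align_latency), then averaged;
# GFPt and component peaks are computed on the grand average
grand_average_gfp <- function(ca) {
  caps <- vapply(ca$analyses, `[[`, "", "cap_type")
  purrr::map_dfr(c("gel", "dry"), function(cap) {
    as_cap <- ca$analyses[caps == cap]
    if (length(as_cap) == 0) return(NULL)
    n75s <- vapply(as_cap, function(a) {
      a$peaks$latency[a$peaks$component == "N75"]
    }, numeric(1))
    ref <- mean(n75s)
    aligned <- purrr::map2(as_cap, n75s,
                           function(a, l) align_latency(a$vep, l, ref)$mean)
    grand <- Reduce(`+`, aligned) / length(aligned)
    g <- gfp_t(structure(list(mean = grand, times = as_cap[[1]]$vep$times),
                         class = "evoked_waveform"))
    pk <- find_peaks(g, ca$params$peak_windows_ms)
    dplyr::mutate(pk, cap_type = cap, reference_n75 = ref,
                  n_subjects = length(as_cap))
  })
}

# polynomial rolling hash over the deparsed configuration: cheap content
# fingerprint for provenance (not cryptographic)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  subjects: %d, seed: %s, config: %s\n",
              x$provenance$n_subjects, x$provenance$seed,
              x$provenance$config_hash))
  cat(sprintf("  prep-time ratio dry/gel: %.2f (%d%% reduction)\n",
              x$metadata_summary$prep_time_ratio,
              x$metadata_summary$prep_time_reduction_pct))
  ov <- x$reliability_summary[x$reliability_summary$level == "cap", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  reliability %s: %.0f%% +- %.0f%%\n", ov$cap_type[i],
                100 * ov$mean_reliability[i], 100 * ov$sd_reliability[i]))
  }
  print(x$comparison_summary)
  invisible(x)
}

#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$provenance$n_subjects,
    prep_time_ratio = x$metadata_summary$prep_time_ratio,
    prep_time_reduction_pct = x$metadata_summary$prep_time_reduction_pct,
    mean_reliability_overall = x$reliability_summary$mean_reliability[
      x$reliability_summary$level == "overall"],
    min_u_test_p = min(x$u_tests$p_value))
}

#' Write a study report to disk
#'
#' Serializes the report as `report.json` (nested summaries plus
#' provenance) and flat CSV tables: `metadata_summary.csv`,
#' `reliability.csv`, `impedance.csv`, `comparison_metrics.csv`. Re-running
#' on the same inputs yields byte-identical files.
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(provenance = report$provenance,
               metadata = list(
                 by_cap = report$metadata_summary$by_cap,
                 prep_time_ratio = report$metadata_summary$prep_time_ratio,
                 prep_time_reduction_pct =
                   report$metadata_summary$prep_time_reduction_pct),
               reliability_summary = report$reliability_summary,
               impedance_grand = report$impedance$grand,
               comparison_summary = report$comparison_summary,
               normality_tests = report$normality_tests,
               u_tests = report$u_tests,
               grand_gfp = report$grand_gfp)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$metadata_summary$by_cap,
                   file.path(dir, "metadata_summary.csv"), row.names = FALSE)
  utils::write.csv(report$reliability, file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$impedance$per_electrode,
                   file.path(dir, "impedance.csv"), row.names = FALSE)
  utils::write.csv(report$comparison_metrics,
                   file.path(dir, "comparison_metrics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
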