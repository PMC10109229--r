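# End-to-end analysis: cleaning, exposure classification, aggregation, the
# per-indicator split-plot ANOVAs with post hoc follow-ups, and the siren
# heart-rate statistic.

#' Run the full wellbeing analysis on a cohort bundle
#'
#' Deduplicates questionnaires, labels day types and study periods, infers
#' residence and exposure groups from baseline-night GPS (hometown fallback),
#' aggregates each indicator into 5/7-2/7 weighted period means, applies the
#' per-indicator inclusion filter, fits the split-plot mixed ANOVA per
#' indicator with Bonferroni post hoc pairs (cohort-wide and per exposure
#' group), assembles the results table, and computes the siren heart-rate
#' response statistic (per-siren deltas, per-participant means, cohort
#' median).
#'
#' @param bundle a \code{cohort_bundle} from [simulate_cohort()] or
#'   [read_cohort()].
#' @param calendar a [study_calendar()].
#' @param ref conflict reference coordinate (lat, lon).
#' @param indicators indicators to analyse (default: all present).
#' @param m Bonferroni family size for the period pairs.
#' @param gg add Greenhouse-Geisser adjusted p values.
#' @return list of class \code{wellbeing_analysis}: \code{exposure},
#'   \code{aggregates}, per-indicator \code{fits} (each with \code{fit},
#'   \code{posthoc}, \code{posthoc_by_group} or \code{error}),
#'   \code{report}, and \code{siren} (responses, participant means, median).
#' @export
run_wellbeing_analysis <- function(bundle, calendar = study_calendar(),
                                   ref = c(lat = 31.5017, lon = 34.4668),
                                   indicators = NULL, m = 6, gg = FALSE) {
  records <- daily_records(bundle, calendar)
  if (is.null(indicators)) indicators <- sort(unique(records$indicator))
  exposure <- assign_exposure(bundle$gps, bundle$profiles, calendar, ref)
  aggregates <- period_aggregates(records)
  eligible <- apply_inclusion_filter(aggregates, c("B", "W", "R1", "R2"))
  fits <- list()
  for (ind in indicators) {
    el <- eligible$participant_id[eligible$indicator == ind]
    a <- aggregates[aggregates$indicator == ind &
                      aggregates$participant_id %in% el, ]
    long <- data.frame(participant_id = a$participant_id, period = a$period,
                       value = a$weighted_mean, stringsAsFactors = FALSE)
    long$group <- exposure$group[match(long$participant_id,
                                       exposure$participant_id)]
    fits[[ind]] <- tryCatch({
      fit <- mixed_anova(value ~ period * group, long,
                         subject = "participant_id", gg = gg)
      list(fit = fit,
           posthoc = bonferroni_posthoc(fit, m = m),
           posthoc_by_group = bonferroni_posthoc(fit, m = m, by_group = TRUE))
    }, error = function(e) list(error = conditionMessage(e)))
  }
  report <- build_results_table(fits)
  siren <- NULL
  if (nrow(bundle$heart_rate) && nrow(bundle$sirens)) {
    responses <- siren_responses(bundle$heart_rate, bundle$sirens, exposure,
                                 tz = calendar$tz)
    means <- participant_mean_delta(responses)
    siren <- list(responses = responses, participant_means = means,
                  median_delta_bpm = if (nrow(means))
                    cohort_median_delta(means) else NA_real_)
  }
  structure(list(exposure = exposure, aggregates = aggregates, fits = fits,
                 report = report, siren = siren, calendar = calendar),
            class = "wellbeing_analysis")
}

#' @export
print.wellbeing_analysis <- function(x, ...) {
  cat("Wellbeing crisis analysis\n")
  cat("  participants:", nrow(x$exposure), "(",
      paste(names(table(x$exposure$group)), table(x$exposure$group),
            collapse = ", "), ")\n")
  if (!is.null(x$siren))
    cat("  siren response: median per-participant delta ",
        signif(x$siren$median_delta_bpm, 4), " bpm over ",
        nrow(x$siren$participant_means), " participants\n", sep = "")
  cat("\n")
  print(x$report)
  invisible(x)
}
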