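# Results-table assembly: per-indicator p values, significance stars and
# direction arrows in the layout of the study's within-subjects effects table.

#' Significance stars
#'
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, else empty;
#' NA yields empty.
#'
#' @param p numeric p value(s).
#' @return character vector of star markers.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

.arrow <- function(direction, significant) {
  ifelse(!significant | is.na(direction) | direction == "none", "",
         ifelse(direction == "increase", "↑", "↓"))
}

#' Assemble the per-indicator results table
#'
#' One row per indicator: the mixed-ANOVA p values for the time-period effect
#' and the period-by-group interaction, and the Bonferroni-corrected p of each
#' baseline-containing period pair -- cohort-wide for the period effect and
#' per exposure group for the interaction. Post hoc columns are filled only
#' when the corresponding main ANOVA effect is significant (alpha = 0.05),
#' matching the reporting convention; stars mark significance levels and
#' arrows the direction of significant changes.
#'
#' @param results named list (by indicator) of lists with elements \code{fit}
#'   (a [mixed_anova()]), \code{posthoc} ([bonferroni_posthoc()] cohort-wide)
#'   and \code{posthoc_by_group} (the \code{by_group = TRUE} variant); an
#'   element may instead carry \code{error} (a message string) for an
#'   indicator whose test aborted.
#' @param alpha significance threshold gating post hoc reporting.
#' @return data.frame of class \code{wellbeing_report}; machine-readable
#'   columns (numeric p values, directions) plus formatted display columns.
#' @export
build_results_table <- function(results, alpha = 0.05) {
  pairs <- c("B & W", "B & R1", "B & R2")
  rows <- lapply(names(results), function(ind) {
    r <- results[[ind]]
    if (!is.null(r$error)) {
      return(data.frame(indicator = ind, n = NA_integer_,
                        period_p = NA_real_, interaction_p = NA_real_,
                        note = r$error, stringsAsFactors = FALSE))
    }
    tab <- r$fit$table
    pp <- tab$p[tab$effect == "period"]
    ip <- tab$p[tab$effect == "period:group"]
    row <- data.frame(indicator = ind, n = sum(r$fit$n_per_group),
                      period_p = pp, interaction_p = ip, note = "",
                      stringsAsFactors = FALSE)
    for (pr in pairs) {
      nm <- gsub(" & ", "_", pr)
      ph <- r$posthoc[r$posthoc$pair == pr, ]
      show <- !is.na(pp) && pp < alpha && nrow(ph) == 1L
      row[[paste0("p_", nm)]] <- if (show) ph$p_bonferroni else NA_real_
      row[[paste0("dir_", nm)]] <-
        if (show && !is.na(ph$p_bonferroni) && ph$p_bonferroni < alpha)
          ph$direction else ""
      row[[paste0("d_", nm)]] <- if (show) ph$cohens_d else NA_real_
    }
    for (grp in r$fit$groups) {
      phg <- r$posthoc_by_group[r$posthoc_by_group$group == grp, ]
      for (pr in pairs) {
        nm <- paste0(gsub(" & ", "_", pr), "_", grp)
        ph <- phg[phg$pair == pr, ]
        show <- !is.na(ip) && ip < alpha && nrow(ph) == 1L
        row[[paste0("p_", nm)]] <- if (show) ph$p_bonferroni else NA_real_
        row[[paste0("dir_", nm)]] <-
          if (show && !is.na(ph$p_bonferroni) && ph$p_bonferroni < alpha)
            ph$direction else ""
      }
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wellbeing_report", "data.frame")
  out
}

#' @export
print.wellbeing_report <- function(x, ...) {
  fmt_p <- function(p) ifelse(is.na(p), "-",
                              paste0(format(round(p, 3), trim = TRUE), p_stars(p)))
  cat("Within-subjects effects by indicator\n")
  disp <- data.frame(indicator = x$indicator, n = x$n,
                     period = fmt_p(x$period_p),
                     interaction = fmt_p(x$interaction_p),
                     stringsAsFactors = FALSE)
  for (pr in c("B_W", "B_R1", "B_R2")) {
    pcol <- paste0("p_", pr); dcol <- paste0("dir_", pr)
    if (pcol %in% names(x))
      disp[[pr]] <- paste0(fmt_p(x[[pcol]]),
                           ifelse(x[[dcol]] == "" | is.na(x[[dcol]]), "",
                                  paste0(" ", .arrow(x[[dcol]], TRUE))))
  }
  print(disp, row.names = FALSE)
  grp_cols <- grep("^p_B_W_", names(x), value = TRUE)
  if (length(grp_cols)) {
    cat("\nPer-group B & W post hoc (interaction follow-up):\n")
    g <- data.frame(indicator = x$indicator, stringsAsFactors = FALSE)
    for (cc in grp_cols) {
      grp <- sub("^p_B_W_", "", cc)
      dcol <- paste0("dir_B_W_", grp)
      g[[grp]] <- paste0(fmt_p(x[[cc]]),
                         ifelse(x[[dcol]] == "" | is.na(x[[dcol]]), "",
                                paste0(" ", .arrow(x[[dcol]], TRUE))))
    }
    print(g, row.names = FALSE)
  }
  if (any(nzchar(x$note)))
    cat("\nnotes:", paste(x$indicator[nzchar(x$note)],
                          x$note[nzchar(x$note)], sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Write a results report to disk
#'
#' @param report a \code{wellbeing_report}.
#' @param csv path for the machine-readable CSV (full-precision p values and
#'   effect sizes), or NULL to skip.
#' @param txt path for the formatted plain-text table, or NULL to skip.
#' @return the report, invisibly.
#' @export
write_report <- function(report, csv = NULL, txt = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(report), csv,
                                      row.names = FALSE)
  if (!is.null(txt)) {
    con <- file(txt, open = "w", encoding = "UTF-8")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}
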