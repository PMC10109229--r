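# Bonferroni-corrected paired post hoc comparisons with Cohen's d.

#' Paired Cohen's d
#'
#' Standardized paired effect size: mean of the paired differences divided by
#' their standard deviation (n - 1 denominator). The sign carries the
#' direction (positive = \code{p2} larger). This is the variant consistent
#' with paired post hoc t comparisons; pooled-SD alternatives exist but are
#' not used here.
#'
#' @param values_p1,values_p2 paired numeric vectors (same subjects, same
#'   order), n >= 2.
#' @return d, or NA with a warning when the difference SD is zero.
#' @export
cohens_d_paired <- function(values_p1, values_p2) {
  stopifnot(length(values_p1) == length(values_p2), length(values_p1) >= 2L)
  d <- values_p2 - values_p1
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero standard deviation of paired differences; d undefined")
    return(NA_real_)
  }
  mean(d) / s
}

.pair_label <- function(p) paste(p, collapse = " & ")

.posthoc_one <- function(Y, pairs, m) {
  out <- lapply(pairs, function(pr) {
    y1 <- Y[, pr[1]]; y2 <- Y[, pr[2]]
    diff <- y2 - y1
    md <- mean(diff)
    # degenerate when the differences are constant to machine precision
    # (the same near-constancy guard stats::t.test applies)
    stderr <- stats::sd(diff) / sqrt(length(diff))
    if (stats::sd(diff) == 0 ||
        stderr < 10 * .Machine$double.eps * max(abs(md), abs(mean(y1)))) {
      p <- if (md == 0) 1 else NA_real_
      d <- if (md == 0) 0 else NA_real_
      note <- "zero variance of paired differences"
    } else {
      p <- stats::t.test(y2, y1, paired = TRUE)$p.value
      d <- suppressWarnings(cohens_d_paired(y1, y2))
      note <- ""
    }
    data.frame(pair = .pair_label(pr), n = length(diff), mean_diff = md,
               p_uncorrected = p, p_bonferroni = pmin(1, m * p),
               cohens_d = d,
               direction = ifelse(md > 0, "increase",
                                  ifelse(md < 0, "decrease", "none")),
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bonferroni post hoc comparisons of within-subject period means
#'
#' Two-sided paired t comparisons per period pair, Bonferroni-corrected by the
#' family size \code{m} (default 6, all pairwise comparisons among the four
#' periods, the family a standard statistics package applies -- corrected p
#' values clamp at 1). Reporting defaults to the three baseline-containing
#' pairs. With \code{by_group = TRUE} the comparisons are run separately
#' inside each exposure group (the follow-up to a significant interaction).
#'
#' @param fit a [mixed_anova()] object.
#' @param pairs list of length-2 character vectors of within-level names.
#' @param m Bonferroni family size.
#' @param by_group run the comparisons within each between-factor level.
#' @return data.frame with the pair, n, mean difference, uncorrected and
#'   corrected p, paired Cohen's d and direction (plus \code{group} when
#'   \code{by_group}).
#' @export
bonferroni_posthoc <- function(fit,
                               pairs = list(c("B", "W"), c("B", "R1"),
                                            c("B", "R2")),
                               m = 6, by_group = FALSE) {
  stopifnot(inherits(fit, "mixed_anova"))
  for (pr in pairs)
    if (!all(pr %in% fit$within_levels))
      stop("unknown within level(s) in pair: ", .pair_label(pr))
  if (!by_group) return(.posthoc_one(fit$y, pairs, m))
  out <- lapply(fit$groups, function(gname) {
    res <- .posthoc_one(fit$y[fit$group == gname, , drop = FALSE], pairs, m)
    cbind(group = gname, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
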