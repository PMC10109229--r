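# Subgroup analysis of war-minus-baseline changes: derived two-level factors
# and an additive between-subjects ANOVA with Type-III sums of squares.

#' Derive subgroup factors for the change analysis
#'
#' Builds the five between-subject factors of the change model: exposure group
#' (restricted downstream to the two affected tiers), age group split at the
#' cohort's median age (Younger = 59 and below, Older = 60 and above), gender,
#' income level (participants who did not state income are excluded from the
#' income factor but kept for the others), and baseline level -- below vs at
#' or above the population median of the indicator's baseline-period weighted
#' mean (ties count as at-or-above).
#'
#' @param profiles cohort profiles.
#' @param aggregates [period_aggregates()] output.
#' @param indicator the indicator whose baseline defines \code{baseline_level}.
#' @param exposure [assign_exposure()] output.
#' @return data.frame: \code{participant_id}, \code{exposure},
#'   \code{age_group}, \code{gender}, \code{income_level} (NA when
#'   unspecified), \code{baseline_level}.
#' @export
derive_subgroup_factors <- function(profiles, aggregates, indicator, exposure) {
  b <- aggregates[aggregates$indicator == indicator & aggregates$period == "B" &
                    !is.na(aggregates$weighted_mean), ]
  med <- stats::median(b$weighted_mean)
  out <- data.frame(
    participant_id = profiles$participant_id,
    exposure = exposure$group[match(profiles$participant_id,
                                    exposure$participant_id)],
    age_group = ifelse(profiles$age <= 59, "younger", "older"),
    gender = profiles$gender,
    income_level = ifelse(profiles$income_level == "unspecified",
                          NA_character_, profiles$income_level),
    stringsAsFactors = FALSE)
  bl <- b$weighted_mean[match(profiles$participant_id, b$participant_id)]
  out$baseline_level <- ifelse(bl >= med, "at_or_above_median", "below_median")
  n_unspec <- sum(is.na(out$income_level))
  if (n_unspec)
    message(n_unspec, " participant(s) with unspecified income excluded from ",
            "the income factor")
  out
}

# Type-III SS for one factor in an additive model: RSS increase from removing
# that factor's columns from the full design. With no interactions this is
# contrast-invariant.
.drop_factor_ss <- function(X, y, asgn, k, rss_full, rank_full) {
  Xr <- X[, asgn != k, drop = FALSE]
  fr <- stats::lm.fit(Xr, y)
  rss_r <- sum(fr$residuals^2)
  c(ss = rss_r - rss_full, df = rank_full - fr$rank)
}

#' Additive subgroup ANOVA on per-participant changes
#'
#' Between-subjects ANOVA of the war-minus-baseline change on the additive
#' factors exposure group + age group + gender + income level + baseline
#' level (no interactions), restricted to the affected (medium and high)
#' exposure tiers. Sums of squares are Type III, appropriate for the
#' unbalanced demographic cells; with only main effects they coincide with
#' Type II. Rows with a missing factor (e.g. unspecified income) are dropped;
#' a factor left with fewer than two levels is dropped entirely with a
#' diagnostic. Adjusted marginal mean differences (each level against its
#' factor's reference, holding the other factors fixed) are reported from the
#' model coefficients.
#'
#' @param deltas [period_delta()] output for one indicator.
#' @param factors [derive_subgroup_factors()] output.
#' @param exposure_levels the affected tiers the analysis is restricted to.
#' @return object of class \code{subgroup_anova}: Type-III \code{table}
#'   (SS, df, F, p per factor plus residuals), adjusted level
#'   \code{differences}, n, dropped factors.
#' @export
subgroup_anova <- function(deltas, factors,
                           exposure_levels = c("medium", "high")) {
  d <- merge(deltas, factors, by = "participant_id")
  d <- d[d$exposure %in% exposure_levels, ]
  fac_names <- c("exposure", "age_group", "gender", "income_level",
                 "baseline_level")
  keep <- stats::complete.cases(d[, c("delta", fac_names)])
  if (any(!keep))
    message(sum(!keep), " participant(s) dropped: missing factor level(s)")
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 10L) stop("too few complete cases for the subgroup ANOVA (",
                          nrow(d), ")")
  dropped <- character()
  for (f in fac_names) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(droplevels(d[[f]])) < 2L) {
      dropped <- c(dropped, f)
      message("factor '", f, "' dropped: fewer than two levels with cases")
    } else d[[f]] <- droplevels(d[[f]])
  }
  fac_use <- setdiff(fac_names, dropped)
  if (!length(fac_use)) stop("no usable factors remain")
  fml <- stats::as.formula(paste("delta ~", paste(fac_use, collapse = " + ")))
  mf <- stats::model.frame(fml, d)
  X <- stats::model.matrix(fml, mf)
  asgn <- attr(X, "assign")
  y <- stats::model.response(mf)
  fit <- stats::lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  df_res <- nrow(X) - fit$rank
  ms_res <- rss_full / df_res
  rows <- lapply(seq_along(fac_use), function(k) {
    s <- .drop_factor_ss(X, y, asgn, k, rss_full, fit$rank)
    Fv <- (s["ss"] / s["df"]) / ms_res
    data.frame(factor = fac_use[k], SS = unname(s["ss"]),
               df = unname(as.integer(s["df"])), F = unname(Fv),
               p = unname(stats::pf(Fv, s["df"], df_res, lower.tail = FALSE)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(factor = "residuals", SS = rss_full,
                               df = df_res, F = NA_real_, p = NA_real_))
  # adjusted level differences vs each factor's reference level
  cf <- fit$coefficients
  diffs <- lapply(seq_along(fac_use), function(k) {
    idx <- which(asgn == k)
    lv <- levels(mf[[fac_use[k]]])
    data.frame(factor = fac_use[k],
               level = sub(paste0("^", fac_use[k]), "", names(cf)[idx]),
               reference = lv[1],
               difference = unname(cf[idx]), stringsAsFactors = FALSE)
  })
  structure(list(table = tab, differences = do.call(rbind, diffs),
                 n = nrow(d), dropped_factors = dropped,
                 formula = fml, call = match.call()),
            class = "subgroup_anova")
}

#' @export
print.subgroup_anova <- function(x, digits = 4, ...) {
  cat("Additive subgroup ANOVA (Type-III SS), n =", x$n, "\n")
  cat("  ", deparse(x$formula), "\n")
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$F <- signif(tab$F, digits)
  tab$p <- format.pval(tab$p, digits = digits, eps = 1e-16)
  print(tab, row.names = FALSE)
  if (length(x$dropped_factors))
    cat("dropped factor(s):", paste(x$dropped_factors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.subgroup_anova <- function(object, ...) {
  print(object, ...)
  cat("\nAdjusted level differences (vs reference):\n")
  d <- object$differences
  d$difference <- signif(d$difference, 4)
  print(d, row.names = FALSE)
  invisible(object)
}

#' @export
coef.subgroup_anova <- function(object, ...) {
  object$differences
}
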