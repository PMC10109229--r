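# Split-plot (mixed) ANOVA: one between-subjects factor, one within-subjects
# factor, complete cases. Implemented as the classical closed-form
# decomposition; the projection identities make the five sums of squares add
# to the total exactly, balanced or not.

.order_levels <- function(x) {
  if (is.factor(x)) return(levels(droplevels(x)))
  u <- unique(x)
  for (canon in list(c("B", "W", "R1", "R2"), c("high", "medium", "low")))
    if (all(u %in% canon)) return(canon[canon %in% u])
  sort(u)
}

#' Split-plot mixed ANOVA
#'
#' Fits the model \code{value ~ within * between} with subjects nested in the
#' between factor: the between-subjects sum of squares splits into the group
#' effect and subject-within-group error, the within-subjects sum of squares
#' into the within-factor main effect, its interaction with the group, and the
#' within residual. The group effect is tested against subject-within-group
#' variation; the within effect and the interaction against the within
#' residual. Unbalanced group sizes are handled by the same subject-level
#' projection decomposition. No sphericity correction is applied by default;
#' \code{gg = TRUE} adds Greenhouse-Geisser adjusted p values for the
#' within-stratum tests.
#'
#' @param formula \code{value ~ within_factor * between_factor} (order of the
#'   two factors is irrelevant: the factor constant within each subject is
#'   taken as the between factor).
#' @param data long data.frame, one row per subject x within level; only
#'   subjects with a complete set of within levels are analysed (incomplete
#'   subjects are dropped with a message).
#' @param subject name of the subject identifier column.
#' @param gg also report Greenhouse-Geisser adjusted p values.
#' @return object of class \code{mixed_anova} with the effects \code{table}
#'   (SS, df, MS, F, p), cell means, the subject-by-level response matrix and
#'   group vector.
#' @export
#' @examples
#' d <- expand.grid(id = factor(1:12), period = c("B", "W", "R1", "R2"))
#' d$group <- c("high", "medium", "low")[as.integer(d$id) %% 3 + 1]
#' set.seed(1); d$value <- rnorm(nrow(d))
#' mixed_anova(value ~ period * group, d, subject = "id")
mixed_anova <- function(formula, data, subject = "participant_id", gg = FALSE) {
  vars <- all.vars(formula)
  if (length(vars) != 3L)
    stop("formula must have the form value ~ factor1 * factor2")
  resp <- vars[1]; f1 <- vars[2]; f2 <- vars[3]
  for (v in c(resp, f1, f2, subject))
    if (!v %in% names(data)) stop("column not found in data: ", v)
  data <- data[!is.na(data[[resp]]), , drop = FALSE]
  sid <- as.character(data[[subject]])
  # the factor constant within every subject is the between factor
  const_within <- function(f) {
    all(tapply(as.character(data[[f]]), sid,
               function(z) length(unique(z)) == 1L))
  }
  if (const_within(f2) && !const_within(f1)) {
    within_f <- f1; between_f <- f2
  } else if (const_within(f1) && !const_within(f2)) {
    within_f <- f2; between_f <- f1
  } else stop("exactly one factor must be constant within subjects ",
              "(the between-subjects factor)")
  wl <- .order_levels(data[[within_f]])
  a <- length(wl)
  if (a < 2L) stop("the within-subjects factor needs at least 2 levels")
  # complete cases: subjects holding each within level exactly once
  tab <- table(sid, as.character(data[[within_f]]))
  if (any(tab > 1L)) stop("duplicated within-level measurements for subject(s) ",
                          paste(utils::head(rownames(tab)[apply(tab > 1, 1, any)], 3),
                                collapse = ", "))
  complete <- rownames(tab)[rowSums(tab[, wl, drop = FALSE] == 1L) == a]
  dropped <- setdiff(unique(sid), complete)
  if (length(dropped))
    message(length(dropped), " subject(s) dropped: incomplete within-level data")
  data <- data[sid %in% complete, , drop = FALSE]
  sid <- as.character(data[[subject]])
  S <- length(complete)
  Y <- matrix(NA_real_, S, a, dimnames = list(complete, wl))
  Y[cbind(match(sid, complete), match(as.character(data[[within_f]]), wl))] <-
    data[[resp]]
  grp <- tapply(as.character(data[[between_f]]), sid, `[`, 1L)[complete]
  gl <- .order_levels(data[[between_f]])
  gl <- gl[gl %in% grp]
  g <- length(gl)
  if (g < 2L) stop("the between-subjects factor needs at least 2 represented levels")
  n_g <- table(factor(grp, levels = gl))
  if (any(n_g < 2L))
    stop("group(s) with fewer than 2 complete cases: ",
         paste(gl[n_g < 2L], collapse = ", "),
         " -- test aborted (n = ", paste(n_g, collapse = "/"), ")")

  grand <- mean(Y)
  subj_m <- rowMeans(Y)
  grp_m <- c(tapply(subj_m, factor(grp, levels = gl), mean))  # drop 1-d dim
  per_m <- colMeans(Y)
  cell_m <- rowsum(Y, factor(grp, levels = gl)) / as.vector(n_g)

  ss_group <- a * sum(n_g * (grp_m - grand)^2)
  ss_subj <- a * sum((subj_m - grp_m[grp])^2)
  ss_period <- S * sum((per_m - grand)^2)
  fit_full <- subj_m + cell_m[cbind(rep(match(grp, gl), a),
                                    rep(seq_len(a), each = S))] - grp_m[grp]
  ss_resid <- sum((as.vector(Y) - fit_full)^2)
  rss2 <- sum(sweep(sweep(Y, 1, subj_m), 2, per_m - grand)^2)
  ss_inter <- rss2 - ss_resid
  ss_total <- sum((Y - grand)^2)

  df <- c(group = g - 1L, subject = S - g, period = a - 1L,
          interaction = (a - 1L) * (g - 1L), residual = (a - 1L) * (S - g))
  SS <- c(ss_group, ss_subj, ss_period, max(ss_inter, 0), ss_resid)
  MS <- SS / df
  Fv <- c(MS[1] / MS[2], NA, MS[3] / MS[5], MS[4] / MS[5], NA)
  pv <- c(stats::pf(Fv[1], df[1], df[2], lower.tail = FALSE), NA,
          stats::pf(Fv[3], df[3], df[5], lower.tail = FALSE),
          stats::pf(Fv[4], df[4], df[5], lower.tail = FALSE), NA)
  diagnostic <- NULL
  if (MS[5] == 0 || !is.finite(MS[5])) {
    diagnostic <- "zero within-subject residual variance; within-stratum F undefined"
    Fv[3:4] <- NA; pv[3:4] <- NA
  }
  if (MS[2] == 0 || !is.finite(MS[2])) {
    diagnostic <- c(diagnostic,
                    "zero subject-within-group variance; group F undefined")
    Fv[1] <- NA; pv[1] <- NA
  }
  tabout <- data.frame(
    effect = c("group", "subject(group)", "period", "period:group", "residual"),
    SS = SS, df = as.integer(df), MS = MS, F = Fv, p = pv,
    stringsAsFactors = FALSE)

  eps <- NA_real_
  if (gg) {
    dev <- Y - cell_m[match(grp, gl), , drop = FALSE]
    Sp <- crossprod(dev) / (S - g)
    Cc <- sweep(sweep(Sp, 1, rowMeans(Sp)), 2, colMeans(Sp)) + mean(Sp)
    denom <- (a - 1) * sum(Cc^2)
    eps <- if (denom > 0) sum(diag(Cc))^2 / denom else NA_real_
    eps <- min(max(eps, 1 / (a - 1)), 1)
    tabout$p_gg <- NA_real_
    tabout$p_gg[3] <- stats::pf(Fv[3], eps * df[3], eps * df[5],
                                lower.tail = FALSE)
    tabout$p_gg[4] <- stats::pf(Fv[4], eps * df[4], eps * df[5],
                                lower.tail = FALSE)
  }

  structure(list(table = tabout, ss_total = ss_total,
                 cell_means = cell_m, period_means = per_m,
                 group_means = grp_m, n_per_group = as.vector(n_g),
                 groups = gl, within_levels = wl,
                 y = Y, group = unname(grp),
                 gg_epsilon = eps, diagnostic = diagnostic,
                 vars = c(response = resp, within = within_f,
                          between = between_f, subject = subject),
                 call = match.call()),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, digits = 4, ...) {
  cat("Split-plot mixed ANOVA: ", x$vars[["response"]], " ~ ",
      x$vars[["within"]], " * ", x$vars[["between"]], "\n", sep = "")
  cat("Subjects: ", sum(x$n_per_group), " (",
      paste(sprintf("%s n=%d", x$groups, x$n_per_group), collapse = ", "),
      ")\n", sep = "")
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$F <- signif(tab$F, digits)
  tab$p <- format.pval(tab$p, digits = digits, eps = 1e-16)
  if ("p_gg" %in% names(tab))
    tab$p_gg <- format.pval(tab$p_gg, digits = digits, eps = 1e-16)
  print(tab, row.names = FALSE)
  if (!is.na(x$gg_epsilon))
    cat("Greenhouse-Geisser epsilon:", signif(x$gg_epsilon, digits), "\n")
  if (!is.null(x$diagnostic)) cat("note:", paste(x$diagnostic, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.mixed_anova <- function(object, ...) {
  print(object, ...)
  cat("\nCell means (", object$vars[["between"]], " x ",
      object$vars[["within"]], "):\n", sep = "")
  print(signif(object$cell_means, 4))
  invisible(object)
}

#' @export
coef.mixed_anova <- function(object, ...) {
  object$cell_means
}

#' Profile plot of cell means
#'
#' Group-by-period mean profiles, the standard display for a split-plot
#' design.
#'
#' @param x a \code{mixed_anova} fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mixed_anova <- function(x, ...) {
  graphics::matplot(seq_along(x$within_levels), t(x$cell_means), type = "b",
                    pch = 19, lty = 1:nrow(x$cell_means), xaxt = "n",
                    xlab = x$vars[["within"]],
                    ylab = paste("mean", x$vars[["response"]]), ...)
  graphics::axis(1, at = seq_along(x$within_levels), labels = x$within_levels)
  graphics::legend("topright", legend = rownames(x$cell_means),
                   lty = 1:nrow(x$cell_means), col = 1:nrow(x$cell_means),
                   pch = 19, bty = "n")
  invisible(x)
}
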