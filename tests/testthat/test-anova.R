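test_that("the split-plot decomposition matches the projection oracle", {
  for (seed in c(1, 2, 3)) {
    df <- random_split_plot(24, seed)
    fit <- mixed_anova(value ~ period * group, df, subject = "subject")
    orc <- oracle_split_plot(df)
    for (eff in c("group", "period", "interaction", "residual")) {
      row <- fit$table[fit$table$effect ==
                         c(group = "group", period = "period",
                           interaction = "period:group",
                           residual = "residual")[eff], ]
      expect_equal(row$SS, unname(orc[[eff]]["SS"]), tolerance = 1e-10,
                   label = paste(eff, "SS, seed", seed))
      expect_equal(row$df, unname(as.integer(orc[[eff]]["df"])),
                   label = paste(eff, "df, seed", seed))
    }
    expect_equal(fit$table$SS[fit$table$effect == "subject(group)"],
                 unname(orc$subject["SS"]), tolerance = 1e-10)
  }
})

test_that("the five sums of squares add exactly to the total", {
  for (seed in 11:14) {
    df <- random_split_plot(15 + seed, seed)
    fit <- mixed_anova(value ~ period * group, df, subject = "subject")
    expect_equal(sum(fit$table$SS), fit$ss_total, tolerance = 1e-12)
  }
})

test_that("unbalanced designs with dropped subjects still match the oracle", {
  df <- random_split_plot(30, 77)
  # remove one full subject per group and all of s001's R2 row (incomplete)
  df <- df[!(df$subject == "s001" & df$period == "R2"), ]
  expect_message(fit <- mixed_anova(value ~ period * group, df,
                                    subject = "subject"), "incomplete")
  complete <- setdiff(unique(df$subject), "s001")
  orc <- oracle_split_plot(df[df$subject %in% complete, ])
  expect_equal(fit$table$SS[fit$table$effect == "period:group"],
               unname(orc$interaction["SS"]), tolerance = 1e-10)
  expect_equal(fit$table$SS[fit$table$effect == "residual"],
               unname(orc$residual["SS"]), tolerance = 1e-10)
})

test_that("degenerate inputs produce diagnostics or errors, not wrong answers", {
  df <- random_split_plot(12, 5)
  # constant response: zero variance everywhere
  df0 <- df; df0$value <- 3
  fit0 <- mixed_anova(value ~ period * group, df0, subject = "subject")
  expect_true(all(is.na(fit0$table$F[c(1, 3, 4)])))
  expect_match(paste(fit0$diagnostic, collapse = "; "), "zero")

  # a group with fewer than 2 complete cases aborts with the counts
  keep_high <- df$subject[df$group == "high"][1]
  df1 <- df[df$group != "high" | df$subject == keep_high, ]
  expect_error(mixed_anova(value ~ period * group, df1, subject = "subject"),
               "fewer than 2 complete cases")

  # duplicated within-level measurements abort
  dfd <- rbind(df, df[df$subject == "s002" & df$period == "B", ])
  expect_error(mixed_anova(value ~ period * group, dfd, subject = "subject"),
               "duplicated")

  expect_error(mixed_anova(value ~ period, df, subject = "subject"),
               "form")
})

test_that("Greenhouse-Geisser epsilon respects its bounds", {
  df <- random_split_plot(24, 8)
  fit <- mixed_anova(value ~ period * group, df, subject = "subject", gg = TRUE)
  a <- length(fit$within_levels)
  expect_gte(fit$gg_epsilon, 1 / (a - 1))
  expect_lte(fit$gg_epsilon, 1)
  # adjusted p values are never smaller than the unadjusted ones
  expect_gte(fit$table$p_gg[3], fit$table$p[3] - 1e-12)
  expect_gte(fit$table$p_gg[4], fit$table$p[4] - 1e-12)
})

test_that("print, summary, coef and plot methods run", {
  df <- random_split_plot(12, 9)
  fit <- mixed_anova(value ~ period * group, df, subject = "subject")
  expect_output(print(fit), "Split-plot mixed ANOVA")
  expect_output(summary(fit), "Cell means")
  expect_equal(dim(coef(fit)), c(3L, 4L))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("Bonferroni correction multiplies, clamps and keeps direction", {
  set.seed(12)
  n <- 30
  base <- rnorm(n)
  df <- data.frame(
    subject = rep(sprintf("s%02d", 1:n), 4),
    period = rep(c("B", "W", "R1", "R2"), each = n),
    group = rep(rep(c("high", "low"), length.out = n), 4),
    value = c(base, base - 1 + rnorm(n, 0, 0.5), base + rnorm(n, 0, 0.5),
              base + rnorm(n, 0, 0.5)))
  fit <- mixed_anova(value ~ period * group, df, subject = "subject")
  ph <- bonferroni_posthoc(fit, m = 6)
  expect_equal(ph$pair, c("B & W", "B & R1", "B & R2"))
  expect_equal(ph$p_bonferroni, pmin(1, 6 * ph$p_uncorrected))
  expect_true(all(ph$p_bonferroni >= ph$p_uncorrected))
  bw <- ph[ph$pair == "B & W", ]
  expect_equal(bw$direction, "decrease")
  expect_lt(bw$cohens_d, 0)
  # the t test agrees with stats::t.test run directly on the matrix columns
  direct <- t.test(fit$y[, "W"], fit$y[, "B"], paired = TRUE)$p.value
  expect_equal(bw$p_uncorrected, direct)
  # by-group variant returns one block per group
  phg <- bonferroni_posthoc(fit, m = 6, by_group = TRUE)
  expect_equal(nrow(phg), 6L)
  expect_setequal(unique(phg$group), c("high", "low"))
  expect_error(bonferroni_posthoc(fit, pairs = list(c("B", "Z"))), "unknown")
})

test_that("paired Cohen's d follows its closed form and handles zero variance", {
  expect_equal(cohens_d_paired(c(1, 2, 3), c(2, 4, 6)),
               mean(c(1, 2, 3)) / sd(c(1, 2, 3)))
  expect_equal(cohens_d_paired(c(5, 5, 5), c(4, 3, 5)),
               mean(c(-1, -2, 0)) / sd(c(-1, -2, 0)))
  expect_warning(d0 <- cohens_d_paired(c(1, 2), c(2, 3)), "zero")
  expect_true(is.na(d0))
  # zero-variance, zero-difference post hoc row: p = 1, d = 0
  dfc <- data.frame(subject = rep(sprintf("s%02d", 1:8), 4),
                    period = rep(c("B", "W", "R1", "R2"), each = 8),
                    group = rep(rep(c("high", "low"), 4), 4),
                    value = rep(rnorm(8), 4) + rep(c(0, 0, 1, 2), each = 8))
  fit <- mixed_anova(value ~ period * group, dfc, subject = "subject")
  ph <- bonferroni_posthoc(fit)
  bw <- ph[ph$pair == "B & W", ]
  expect_equal(bw$p_bonferroni, 1)
  expect_equal(bw$cohens_d, 0)
  expect_match(bw$note, "zero variance")
})

test_that("subgroup factor derivation applies the documented splits", {
  prof <- data.frame(
    participant_id = c("P1", "P2", "P3", "P4"),
    age = c(59, 60, 45, 80),
    gender = c("female", "male", "female", "male"),
    income_level = c("below_average", "unspecified", "above_average",
                     "average"),
    stringsAsFactors = FALSE)
  agg <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                    indicator = "mood", period = "B",
                    work_mean = 0, free_mean = 0,
                    weighted_mean = c(1, 2, 3, 4),
                    n_work = 1L, n_free = 1L, stringsAsFactors = FALSE)
  expo <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                     group = c("high", "medium", "low", "high"),
                     stringsAsFactors = FALSE)
  expect_message(f <- derive_subgroup_factors(prof, agg, "mood", expo),
                 "unspecified income")
  expect_equal(f$age_group, c("younger", "older", "younger", "older"))
  expect_true(is.na(f$income_level[2]))
  # median of 1:4 is 2.5; ties at the median count as at-or-above
  expect_equal(f$baseline_level,
               c("below_median", "below_median", "at_or_above_median",
                 "at_or_above_median"))
})

test_that("constant deltas give a zero-SS subgroup table", {
  set.seed(3)
  n <- 40
  f <- data.frame(participant_id = sprintf("P%02d", 1:n),
                  exposure = rep(c("high", "medium"), n / 2),
                  age_group = rep(c("younger", "older"), each = n / 2),
                  gender = sample(c("female", "male"), n, TRUE),
                  income_level = sample(c("below_average", "average",
                                          "above_average"), n, TRUE),
                  baseline_level = sample(c("below_median",
                                            "at_or_above_median"), n, TRUE),
                  stringsAsFactors = FALSE)
  d <- data.frame(participant_id = f$participant_id, indicator = "mood",
                  delta = 0.7, stringsAsFactors = FALSE)
  fit <- subgroup_anova(d, f)
  expect_equal(fit$table$SS, rep(0, nrow(fit$table)), tolerance = 1e-20)
})

test_that("Type-III subgroup table matches the car::Anova oracle", {
  skip_if_not_installed("car")
  set.seed(6)
  n <- 120
  f <- data.frame(participant_id = sprintf("P%03d", 1:n),
                  exposure = sample(c("high", "medium"), n, TRUE, c(.3, .7)),
                  age_group = sample(c("younger", "older"), n, TRUE),
                  gender = sample(c("female", "male"), n, TRUE),
                  income_level = sample(c("below_average", "average",
                                          "above_average"), n, TRUE),
                  baseline_level = sample(c("below_median",
                                            "at_or_above_median"), n, TRUE),
                  stringsAsFactors = FALSE)
  d <- data.frame(participant_id = f$participant_id, indicator = "mood",
                  delta = rnorm(n) + (f$exposure == "high") * 0.8 +
                    (f$gender == "male") * 0.3,
                  stringsAsFactors = FALSE)
  fit <- subgroup_anova(d, f)
  md <- merge(d, f, by = "participant_id")
  lmfit <- lm(delta ~ exposure + age_group + gender + income_level +
                baseline_level, data = md,
              contrasts = list(exposure = "contr.sum", age_group = "contr.sum",
                               gender = "contr.sum",
                               income_level = "contr.sum",
                               baseline_level = "contr.sum"))
  oracle <- car::Anova(lmfit, type = 3)
  for (fac in fit$table$factor[fit$table$factor != "residuals"]) {
    expect_equal(fit$table$SS[fit$table$factor == fac],
                 oracle[fac, "Sum Sq"], tolerance = 1e-8, label = fac)
    expect_equal(fit$table$p[fit$table$factor == fac],
                 oracle[fac, "Pr(>F)"], tolerance = 1e-8, label = fac)
  }
})

test_that("an injected gender effect is recovered by the adjusted difference", {
  set.seed(19)
  n <- 600
  f <- data.frame(participant_id = sprintf("P%03d", 1:n),
                  exposure = sample(c("high", "medium"), n, TRUE),
                  age_group = sample(c("younger", "older"), n, TRUE),
                  gender = sample(c("female", "male"), n, TRUE),
                  income_level = sample(c("below_average", "average",
                                          "above_average"), n, TRUE),
                  baseline_level = sample(c("below_median",
                                            "at_or_above_median"), n, TRUE),
                  stringsAsFactors = FALSE)
  d <- data.frame(participant_id = f$participant_id, indicator = "mood",
                  delta = rnorm(n, 0, 0.5) + (f$gender == "male") * 0.4,
                  stringsAsFactors = FALSE)
  fit <- subgroup_anova(d, f)
  male <- fit$differences[fit$differences$factor == "gender" &
                            fit$differences$level == "male", ]
  expect_lt(abs(male$difference - 0.4), 0.1)
  expect_lt(fit$table$p[fit$table$factor == "gender"], 0.001)
})

test_that("subgroup power grows with the injected effect size", {
  # effect increments far exceed the coefficient's sampling noise, so the
  # p values must fall strictly as the effect grows
  pvals <- vapply(c(0, 0.6, 1.5), function(es) {
    set.seed(23)
    n <- 200
    f <- data.frame(participant_id = sprintf("P%03d", 1:n),
                    exposure = sample(c("high", "medium"), n, TRUE),
                    age_group = sample(c("younger", "older"), n, TRUE),
                    gender = sample(c("female", "male"), n, TRUE),
                    income_level = sample(c("below_average", "average",
                                            "above_average"), n, TRUE),
                    baseline_level = sample(c("below_median",
                                              "at_or_above_median"), n, TRUE),
                    stringsAsFactors = FALSE)
    set.seed(24)
    d <- data.frame(participant_id = f$participant_id, indicator = "mood",
                    delta = rnorm(n) + (f$exposure == "high") * es,
                    stringsAsFactors = FALSE)
    fit <- subgroup_anova(d, f)
    fit$table$p[fit$table$factor == "exposure"]
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("single-level factors are dropped with a diagnostic", {
  set.seed(4)
  n <- 30
  f <- data.frame(participant_id = sprintf("P%02d", 1:n),
                  exposure = rep(c("high", "medium"), n / 2),
                  age_group = "younger",  # only one level
                  gender = sample(c("female", "male"), n, TRUE),
                  income_level = sample(c("below_average", "average"), n, TRUE),
                  baseline_level = sample(c("below_median",
                                            "at_or_above_median"), n, TRUE),
                  stringsAsFactors = FALSE)
  d <- data.frame(participant_id = f$participant_id, indicator = "mood",
                  delta = rnorm(n), stringsAsFactors = FALSE)
  expect_message(fit <- subgroup_anova(d, f), "age_group")
  expect_equal(fit$dropped_factors, "age_group")
  expect_false("age_group" %in% fit$table$factor)
})

test_that("significance stars and direction arrows follow convention", {
  expect_equal(p_stars(c(0.0001, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
  expect_equal(.arrow(c("increase", "decrease", "none"), TRUE),
               c("↑", "↓", ""))
  expect_equal(.arrow("increase", FALSE), "")
})
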