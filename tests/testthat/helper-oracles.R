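# Independent oracles and fixture builders used across the suite.

# Brute-force split-plot decomposition via explicit least-squares projections:
# the within stratum from the sequential ANOVA of
# value ~ subject + period + period:group, the between stratum from the
# one-way ANOVA of subject means (scaled back by the number of periods).
oracle_split_plot <- function(df) {
  df$subject <- factor(df$subject)
  df$period <- factor(df$period)
  df$group <- factor(df$group)
  a <- nlevels(df$period)
  within <- anova(lm(value ~ subject + period + period:group, data = df))
  sm <- tapply(df$value, df$subject, mean)
  sg <- tapply(as.character(df$group), df$subject, `[`, 1L)[names(sm)]
  between <- anova(lm(sm ~ factor(sg)))
  list(
    group = c(SS = a * between[1, "Sum Sq"], df = between[1, "Df"]),
    subject = c(SS = a * between[2, "Sum Sq"], df = between[2, "Df"]),
    period = c(SS = within["period", "Sum Sq"], df = within["period", "Df"]),
    interaction = c(SS = within["period:group", "Sum Sq"],
                    df = within["period:group", "Df"]),
    residual = c(SS = within["Residuals", "Sum Sq"],
                 df = within["Residuals", "Df"]))
}

# Random split-plot design: 3 groups x 4 periods, possibly unbalanced,
# with arbitrary injected group/period/interaction structure.
random_split_plot <- function(n_subj, seed) {
  set.seed(seed)
  groups <- c("high", "medium", "low")
  g <- sample(rep(groups, length.out = n_subj))
  periods <- c("B", "W", "R1", "R2")
  df <- expand.grid(subject = sprintf("s%03d", seq_len(n_subj)),
                    period = periods, stringsAsFactors = FALSE)
  df$group <- g[as.integer(sub("s", "", df$subject))]
  eff_g <- stats::rnorm(3); names(eff_g) <- groups
  eff_p <- stats::rnorm(4); names(eff_p) <- periods
  eff_gp <- matrix(stats::rnorm(12), 3, 4, dimnames = list(groups, periods))
  subj_re <- stats::rnorm(n_subj); names(subj_re) <- sprintf("s%03d", seq_len(n_subj))
  df$value <- eff_g[df$group] + eff_p[df$period] +
    eff_gp[cbind(df$group, df$period)] + subj_re[df$subject] +
    stats::rnorm(nrow(df))
  df
}

# Spherical law of cosines great-circle distance (km), radius 6371 km.
oracle_great_circle_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(pmax(d, -1), 1))
}

# Minimal single-indicator config for fast simulation-based tests.
mood_only_config <- function(n, seed, d_high = 0, d_medium = 0, d_low = 0, ...) {
  ip <- default_indicator_params()
  sim_config(n_participants = n, seed = seed,
             indicator_params = ip[ip$indicator == "mood", ],
             war_effects = data.frame(indicator = "mood", high = d_high,
                                      medium = d_medium, low = d_low),
             ...)
}

# Daily indicator records labelled with day type and period, straight from the
# generator (no CSV round trip) -- the fast path for statistical checks.
labelled_records <- function(profiles, cfg) {
  rec <- generate_daily_indicators(profiles, cfg)
  rec$day_type <- label_day_type(rec$date, cfg$calendar)
  rec$period <- assign_period(rec$date, cfg$calendar)
  rec
}

# Aggregate one indicator, apply the four-period filter, attach groups, and
# return the long ANOVA input.
anova_input <- function(profiles, cfg, indicator = "mood") {
  rec <- labelled_records(profiles, cfg)
  agg <- period_aggregates(rec[rec$indicator == indicator, ])
  el <- apply_inclusion_filter(agg, c("B", "W", "R1", "R2"))
  a <- agg[agg$participant_id %in% el$participant_id, ]
  long <- data.frame(participant_id = a$participant_id, period = a$period,
                     value = a$weighted_mean, stringsAsFactors = FALSE)
  long$group <- profiles$true_group[match(long$participant_id,
                                          profiles$participant_id)]
  long
}

# Flat minute-level heart-rate series around an anchor time.
flat_hr <- function(anchor, from_min, to_min, bpm,
                    pid = "P1", tz = "Asia/Jerusalem") {
  ts <- anchor + seq(from_min, to_min) * 60
  data.frame(participant_id = pid, timestamp = ts,
             bpm = rep_len(bpm, length(ts)), stringsAsFactors = FALSE)
}

anchor_time <- function(clock = "03:00:00", date = "2021-05-12",
                        tz = "Asia/Jerusalem") {
  as.POSIXct(paste(date, clock), tz = tz)
}
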