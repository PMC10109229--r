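#' Default per-indicator generative parameters
#'
#' The 12 canonical wellbeing indicators with their data stream
#' (daily questionnaire vs device daily aggregate), units, baseline mean,
#' between-subject SD, within-subject (day-to-day) SD, free-day offset,
#' plausible bounds used for clipping, and the direction considered adverse
#' (+1 = an increase is adverse, -1 = a decrease is adverse).
#'
#' The published study does not print per-indicator baseline means/SDs in its
#' main text, so these values are plausible placeholders on each indicator's
#' natural scale; they set the noise background against which standardized
#' war shifts are injected.
#'
#' @return data.frame, one row per indicator.
#' @export
default_indicator_params <- function() {
  p <- read.csv(text = "
indicator,stream,unit,baseline,between_sd,within_sd,free_offset,lower,upper,adverse
mood,questionnaire,scale,0.4,0.45,0.6,0.10,-2,2,-1
stress,questionnaire,scale,-0.3,0.45,0.6,-0.05,-2,2,1
sleep_quality,questionnaire,scale,0.3,0.45,0.6,0.05,-2,2,-1
sleep_duration,questionnaire,hour,7.0,0.7,0.9,0.40,0,24,-1
sport_time,questionnaire,min,30,20,25,10,0,Inf,-1
encounters,questionnaire,count,5,2,2.5,1,0,Inf,-1
screen_on_time,device,hour,4.0,1.2,1.3,0.5,0,24,1
pct_time_still,device,pct,70,8,7,3,0,100,1
steps,device,count,7000,2200,2500,-800,0,Inf,-1
avg_heart_rate,device,bpm,68,6,3,-1,30,200,1
awake_time,device,sec,1800,600,700,100,0,Inf,1
sleep_start_hour,device,hour,-0.5,0.6,0.7,0.5,-6,6,1
", stringsAsFactors = FALSE, strip.white = TRUE)
  p
}

#' Canonical indicator names
#' @return character vector of the 12 indicator names.
#' @export
indicator_names <- function() default_indicator_params()$indicator

#' Default war-period standardized shifts per exposure group
#'
#' Effect sizes (Cohen's d, on the paired war-minus-baseline period-mean
#' scale) applied additively during the war period, by exposure group.
#' Defaults reproduce the magnitudes reported for the May 2021 cohort: where a
#' group-specific effect was reported (the six indicators with a significant
#' period-by-group interaction) those values are used; otherwise the overall
#' effect is applied equally to the two exposed groups and the low-exposure
#' group is left unshifted.
#'
#' @return data.frame with columns \code{indicator}, \code{high},
#'   \code{medium}, \code{low}.
#' @export
default_war_effects <- function() {
  read.csv(text = "
indicator,high,medium,low
mood,-1.21,-0.51,0
stress,1.33,0.50,0
sleep_quality,-1.23,-0.24,0
sleep_duration,-0.42,-0.20,0
sport_time,-0.48,-0.22,0
screen_on_time,0.48,0.28,0.17
encounters,-0.16,-0.16,0
steps,-0.19,-0.19,0
avg_heart_rate,-0.11,-0.11,0
pct_time_still,0.20,0.20,0
awake_time,0.32,0.32,0
sleep_start_hour,0.09,0.09,0
", stringsAsFactors = FALSE, strip.white = TRUE)
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: cohort size and composition, the study
#' calendar, per-indicator generative parameters, standardized war shifts per
#' exposure group, post-war persistence, stream fill probabilities, GPS trace
#' behaviour, and siren / heart-rate impulse parameters.
#'
#' Demographic and exposure-group proportions default to the published cohort
#' composition (N = 954; 68 high / 704 medium / 182 low exposure). Group
#' residence centres default to real localities whose great-circle distance to
#' the conflict reference point falls inside each exposure band.
#'
#' @param n_participants cohort size.
#' @param seed integer master seed; every generator derives its stream from it.
#' @param calendar a [study_calendar()].
#' @param group_proportions named fractions over \code{high}, \code{medium},
#'   \code{low}; must sum to 1.
#' @param age_band_proportions,gender_proportions,income_proportions named
#'   fractions, each summing to 1. Age bands are \code{40-49}, \code{50-59},
#'   \code{60-69}, \code{70+} (study inclusion requires age >= 40).
#' @param indicator_params data.frame as [default_indicator_params()].
#' @param war_effects data.frame as [default_war_effects()]: standardized
#'   shift (Cohen's d on the paired W-B period-mean scale) per indicator and
#'   exposure group, applied only during W.
#' @param recovery_fraction fraction of the war shift persisting in R1/R2
#'   (scalar or named per indicator; default 0 = full return to baseline).
#' @param fill_prob named daily fill probabilities for the
#'   \code{questionnaire} stream (one Bernoulli per participant-day covering
#'   all six self-report indicators; default 3/7, i.e. about three fills a
#'   week) and the \code{device} stream (per indicator-day).
#' @param duplicate_prob probability that a filled questionnaire day also
#'   carries an earlier, superseded submission (exercises deduplication).
#' @param gps list: \code{jitter_sd_deg} night-time positional jitter (degrees),
#'   \code{day_jitter_sd_deg} daytime jitter, \code{away_fraction} fraction of
#'   nights spent away from home, \code{no_gps_fraction} fraction of
#'   participants with no GPS at all (exercises the hometown fallback),
#'   \code{cadence_min} sampling cadence in minutes, \code{days} Date range
#'   covered (default the baseline period, the only window residence
#'   inference uses).
#' @param sirens list: \code{rate_per_night} named Poisson rates of siren
#'   events per night for \code{high} and \code{medium} areas (the
#'   low-exposure area has none), \code{hours} the overnight window sirens
#'   fall in.
#' @param hr list: heart-rate stream parameters -- personal baseline mean/SD
#'   (bpm), diurnal cosine amplitude (nadir 04:00), minute noise SD, siren
#'   impulse amplitude mean/SD (bpm), exponential decay time constant
#'   (minutes), \code{hours} the simulated daily observation window and
#'   \code{days} the Date range (default the war period).
#' @param group_centers 3x2 matrix (rows high/medium/low) of lat/lon residence
#'   centres; \code{center_jitter_sd_deg} scatters hometowns around them.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_participants = 954,
                       seed = 1L,
                       calendar = study_calendar(),
                       group_proportions = c(high = 68, medium = 704, low = 182) / 954,
                       age_band_proportions = c("40-49" = 89, "50-59" = 407,
                                                "60-69" = 311, "70+" = 147) / 954,
                       gender_proportions = c(man = 405, woman = 549) / 954,
                       income_proportions = c(above_median = 475, median = 185,
                                              below_median = 258, unspecified = 36) / 954,
                       indicator_params = default_indicator_params(),
                       war_effects = default_war_effects(),
                       recovery_fraction = 0,
                       fill_prob = c(questionnaire = 3 / 7, device = 0.9),
                       duplicate_prob = 0.1,
                       gps = list(),
                       sirens = list(),
                       hr = list(),
                       group_centers = rbind(high = c(31.67, 34.57),
                                             medium = c(32.08, 34.78),
                                             low = c(32.79, 34.99)),
                       center_jitter_sd_deg = 0.03) {
  gps_def <- list(jitter_sd_deg = 5e-4, day_jitter_sd_deg = 0.02,
                  away_fraction = 0.05, no_gps_fraction = 0.05,
                  cadence_min = 15, days = calendar$period_ranges$B)
  sir_def <- list(rate_per_night = c(high = 1.5, medium = 0.8), hours = c(0, 8))
  hr_def <- list(baseline_mean = 62, baseline_sd = 7, diurnal_amp = 2,
                 noise_sd = 3, amp_mean = 16, amp_sd = 6, decay_min = 6,
                 hours = c(0, 8), days = calendar$period_ranges$W)
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    calendar = calendar,
    group_proportions = group_proportions,
    age_band_proportions = age_band_proportions,
    gender_proportions = gender_proportions,
    income_proportions = income_proportions,
    indicator_params = indicator_params,
    war_effects = war_effects,
    recovery_fraction = recovery_fraction,
    fill_prob = fill_prob,
    duplicate_prob = duplicate_prob,
    gps = utils::modifyList(gps_def, gps),
    sirens = utils::modifyList(sir_def, sirens),
    hr = utils::modifyList(hr_def, hr),
    group_centers = group_centers,
    center_jitter_sd_deg = center_jitter_sd_deg
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks proportion sets sum to 1 (within 1e-9), SDs and probabilities are
#' nonnegative (probabilities at most 1), period ranges are ordered, and war
#' effect indicator names are known.
#'
#' @param cfg a [sim_config()].
#' @return \code{cfg}, invisibly; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_participants < 1L) stop("n_participants: must be at least 1")
  props <- list(group_proportions = c("high", "medium", "low"),
                age_band_proportions = NULL,
                gender_proportions = NULL,
                income_proportions = NULL)
  for (field in names(props)) {
    v <- cfg[[field]]
    if (any(v < 0)) stop(field, ": proportions must be nonnegative")
    if (abs(sum(v) - 1) > 1e-9) stop(field, ": proportions must sum to 1")
    need <- props[[field]]
    if (!is.null(need) && !setequal(names(v), need))
      stop(field, ": must be named over ", paste(need, collapse = ", "))
  }
  ip <- cfg$indicator_params
  need_cols <- c("indicator", "stream", "baseline", "between_sd", "within_sd",
                 "free_offset", "lower", "upper", "adverse")
  miss <- setdiff(need_cols, names(ip))
  if (length(miss)) stop("indicator_params: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(ip$between_sd < 0) || any(ip$within_sd < 0))
    stop("indicator_params: SDs must be nonnegative")
  unknown <- setdiff(cfg$war_effects$indicator, ip$indicator)
  if (length(unknown))
    stop("war_effects: unknown indicator name(s): ",
         paste(unknown, collapse = ", "))
  if (any(cfg$fill_prob < 0) || any(cfg$fill_prob > 1))
    stop("fill_prob: probabilities must lie in [0, 1]")
  if (cfg$duplicate_prob < 0 || cfg$duplicate_prob > 1)
    stop("duplicate_prob: must lie in [0, 1]")
  for (f in c("jitter_sd_deg", "day_jitter_sd_deg")) {
    if (cfg$gps[[f]] < 0) stop("gps$", f, ": must be nonnegative")
  }
  for (f in c("away_fraction", "no_gps_fraction")) {
    if (cfg$gps[[f]] < 0 || cfg$gps[[f]] > 1)
      stop("gps$", f, ": must lie in [0, 1]")
  }
  if (any(cfg$sirens$rate_per_night < 0))
    stop("sirens$rate_per_night: must be nonnegative")
  for (f in c("baseline_sd", "diurnal_amp", "noise_sd", "amp_sd")) {
    if (cfg$hr[[f]] < 0) stop("hr$", f, ": must be nonnegative")
  }
  if (cfg$hr$decay_min <= 0) stop("hr$decay_min: must be positive")
  gc <- cfg$group_centers
  if (any(abs(gc[, 1]) > 90) || any(abs(gc[, 2]) > 180))
    stop("group_centers: coordinates out of range")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  participants:", x$n_participants, " seed:", x$seed, "\n")
  cat("  groups:", paste(sprintf("%s %.3f", names(x$group_proportions),
                                 x$group_proportions), collapse = ", "), "\n")
  cat("  fill prob: questionnaire", signif(x$fill_prob[["questionnaire"]], 3),
      "/ device", signif(x$fill_prob[["device"]], 3), "\n")
  cat("  indicators:", nrow(x$indicator_params), "\n")
  invisible(x)
}

# E[1/N | N >= 1] for N ~ Binomial(n, p); used to size standardized shifts on
# the scale of the paired difference of weighted period means.
.e_inv_binom <- function(n, p) {
  if (n < 1L || p <= 0) return(NA_real_)
  k <- seq_len(n)
  w <- stats::dbinom(k, n, p)
  sum(w / k) / sum(w)
}

#' Standard deviation of the paired W-B weighted-mean difference
#'
#' The analytic scale on which standardized war shifts are injected. For a
#' participant with day-level noise SD \code{within_sd} and daily fill
#' probability \code{fill}, the weighted period mean (5/7 work + 2/7 free) has
#' variance \code{(5/7)^2 E[1/n_work] + (2/7)^2 E[1/n_free]} times
#' \code{within_sd^2}, with day counts binomial over the calendar's work/free
#' days of that period (conditioned on at least one of each, the analysis
#' inclusion rule). The paired difference adds the B and W variances.
#'
#' @param within_sd day-level noise SD of the indicator.
#' @param fill daily fill probability of its stream.
#' @param calendar a [study_calendar()].
#' @param periods the two periods being contrasted.
#' @return the SD (indicator units) of the paired period-mean difference.
#' @export
paired_diff_sd_ref <- function(within_sd, fill, calendar,
                               periods = c("B", "W")) {
  days <- study_days(calendar)
  v <- 0
  for (p in periods) {
    nw <- sum(days$period == p & days$day_type == "work")
    nf <- sum(days$period == p & days$day_type == "free")
    v <- v + (5 / 7)^2 * .e_inv_binom(nw, fill) +
      (2 / 7)^2 * .e_inv_binom(nf, fill)
  }
  within_sd * sqrt(v)
}
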