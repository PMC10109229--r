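# Synthetic cohort generator. Each generator derives its RNG stream from the
# master seed plus a fixed offset, so generators are deterministic whether
# called individually or through simulate_cohort().
.stream_seed <- function(cfg, offset) {
  set.seed((cfg$seed %% 2000000000L) + offset)
}

.age_band_range <- list("40-49" = c(40L, 49L), "50-59" = c(50L, 59L),
                        "60-69" = c(60L, 69L), "70+" = c(70L, 85L))

#' Generate participant enrollment profiles
#'
#' Samples exposure group, age band (uniform within band), gender and income
#' level from the configured proportions, and scatters hometown coordinates
#' around the group residence centres. \code{true_group} records the
#' simulation truth; the analysis pipeline never reads it.
#'
#' @param cfg a [sim_config()].
#' @return data.frame: \code{participant_id}, \code{age}, \code{gender},
#'   \code{income_level}, \code{hometown_lat}, \code{hometown_lon},
#'   \code{true_group}.
#' @export
generate_profiles <- function(cfg) {
  validate_sim_config(cfg)
  .stream_seed(cfg, 1L)
  n <- cfg$n_participants
  grp <- sample(names(cfg$group_proportions), n, replace = TRUE,
                prob = cfg$group_proportions)
  band <- sample(names(cfg$age_band_proportions), n, replace = TRUE,
                 prob = cfg$age_band_proportions)
  lo <- vapply(.age_band_range[band], `[`, integer(1), 1L)
  hi <- vapply(.age_band_range[band], `[`, integer(1), 2L)
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  gender <- sample(names(cfg$gender_proportions), n, replace = TRUE,
                   prob = cfg$gender_proportions)
  income <- sample(names(cfg$income_proportions), n, replace = TRUE,
                   prob = cfg$income_proportions)
  ctr <- cfg$group_centers[grp, , drop = FALSE]
  lat <- ctr[, 1] + stats::rnorm(n, 0, cfg$center_jitter_sd_deg)
  lon <- ctr[, 2] + stats::rnorm(n, 0, cfg$center_jitter_sd_deg)
  data.frame(participant_id = sprintf("P%05d", seq_len(n)),
             age = as.integer(age),
             gender = gender,
             income_level = income,
             hometown_lat = round(lat, 6),
             hometown_lon = round(lon, 6),
             true_group = grp,
             stringsAsFactors = FALSE)
}

# Standardized war shift (d, on the paired W-B aggregate scale) converted to
# an additive raw-scale shift for one indicator row.
.raw_shift <- function(ip_row, d, cfg) {
  fill <- cfg$fill_prob[[ip_row$stream]]
  d * paired_diff_sd_ref(ip_row$within_sd, fill, cfg$calendar)
}

.recovery_of <- function(cfg, indicator) {
  rf <- cfg$recovery_fraction
  if (length(rf) == 1L && is.null(names(rf))) return(rf)
  if (indicator %in% names(rf)) rf[[indicator]] else 0
}

#' Generate daily wellbeing indicator values
#'
#' For every participant, configured indicator and calendar day of the study
#' window, emits (subject to the stream's fill probability) the value
#' participant baseline + free-day offset + war shift + day noise, clipped to
#' the indicator's bounds. Questionnaire-stream indicators share one fill draw
#' per participant-day (a questionnaire is filled as a whole); device
#' indicators are filled independently per indicator-day. War shifts are
#' additive on the raw scale, sized as Cohen's d times the analytic SD of the
#' paired W-B weighted period-mean difference (see [paired_diff_sd_ref()]),
#' and persist into R1/R2 with the configured recovery fraction.
#'
#' @param profiles output of [generate_profiles()].
#' @param cfg a [sim_config()].
#' @return long data.frame: \code{participant_id}, \code{date},
#'   \code{indicator}, \code{value}.
#' @export
generate_daily_indicators <- function(profiles, cfg) {
  validate_sim_config(cfg)
  stopifnot(nrow(profiles) > 0)
  .stream_seed(cfg, 2L)
  days <- study_days(cfg$calendar)
  n <- nrow(profiles)
  m <- nrow(days)
  is_free <- days$day_type == "free"
  period <- days$period
  # one questionnaire fill draw per participant-day, shared by all
  # questionnaire indicators
  q_fill <- matrix(stats::runif(n * m) < cfg$fill_prob[["questionnaire"]], n, m)
  out <- vector("list", nrow(cfg$indicator_params))
  we <- cfg$war_effects
  for (i in seq_len(nrow(cfg$indicator_params))) {
    ip <- cfg$indicator_params[i, ]
    d_by_group <- c(high = 0, medium = 0, low = 0)
    wrow <- we[we$indicator == ip$indicator, ]
    if (nrow(wrow) == 1L)
      d_by_group[c("high", "medium", "low")] <-
        unlist(wrow[c("high", "medium", "low")])
    shift <- vapply(d_by_group, function(d) .raw_shift(ip, d, cfg), numeric(1))
    subj_base <- ip$baseline + stats::rnorm(n, 0, ip$between_sd)
    subj_shift <- shift[profiles$true_group]
    rec <- .recovery_of(cfg, ip$indicator)
    day_mult <- ifelse(period == "W", 1, ifelse(period %in% c("R1", "R2"), rec, 0))
    val <- outer(subj_base, rep(1, m)) +
      outer(rep(1, n), ip$free_offset * is_free) +
      outer(subj_shift, day_mult) +
      matrix(stats::rnorm(n * m, 0, ip$within_sd), n, m)
    val <- pmin(pmax(val, ip$lower), ip$upper)
    fill <- if (ip$stream == "questionnaire") q_fill else
      matrix(stats::runif(n * m) < cfg$fill_prob[["device"]], n, m)
    keep <- which(fill)
    out[[i]] <- data.frame(
      participant_id = profiles$participant_id[(keep - 1L) %% n + 1L],
      date = days$date[(keep - 1L) %/% n + 1L],
      indicator = ip$indicator,
      value = val[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$date, res$indicator), ]
  rownames(res) <- NULL
  res
}

.quest_fields <- c(mood = "mood", stress = "stress",
                   sleep_duration = "sleep_duration",
                   sleep_quality = "sleep_quality",
                   sport_time = "sport_time", encounters = "encounters")

#' Generate raw questionnaire submissions from daily indicator values
#'
#' Converts the questionnaire-stream rows of [generate_daily_indicators()]
#' output into wide submissions with ISO timestamps. The canonical submission
#' of a day is stamped in the evening; with probability \code{duplicate_prob}
#' an earlier, superseded submission with perturbed values is added, so that
#' keeping the latest submission per day recovers the canonical values.
#'
#' @param indicators long output of [generate_daily_indicators()].
#' @param cfg a [sim_config()].
#' @return data.frame: \code{participant_id}, \code{submitted_at} (POSIXct),
#'   and the six self-report fields.
#' @export
generate_questionnaires <- function(indicators, cfg) {
  validate_sim_config(cfg)
  .stream_seed(cfg, 6L)
  tz <- cfg$calendar$tz
  q <- indicators[indicators$indicator %in% .quest_fields, ]
  if (nrow(q) == 0L) {
    return(data.frame(participant_id = character(), submitted_at = as.POSIXct(character(), tz = tz),
                      mood = numeric(), stress = numeric(), sleep_duration = numeric(),
                      sleep_quality = numeric(), sport_time = numeric(),
                      encounters = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(q$participant_id, q$date)
  ids <- !duplicated(key)
  wide <- data.frame(participant_id = q$participant_id[ids],
                     date = q$date[ids], stringsAsFactors = FALSE)
  ukey <- key[ids]
  for (f in .quest_fields) {
    v <- rep(NA_real_, nrow(wide))
    rows <- q$indicator == f
    v[match(key[rows], ukey)] <- q$value[rows]
    wide[[f]] <- v
  }
  nw <- nrow(wide)
  wide$submitted_at <- as.POSIXct(paste(wide$date, "19:00:00"), tz = tz) +
    round(stats::runif(nw, 0, 7200))
  dup <- stats::runif(nw) < cfg$duplicate_prob
  out <- wide
  if (any(dup)) {
    ip <- cfg$indicator_params
    early <- wide[dup, , drop = FALSE]
    early$submitted_at <- as.POSIXct(paste(early$date, "08:00:00"), tz = tz) +
      round(stats::runif(nrow(early), 0, 36000))
    for (f in .quest_fields) {
      r <- ip[ip$indicator == f, ]
      if (nrow(r) == 0L) next  # field not simulated under this configuration
      pert <- early[[f]] + stats::rnorm(nrow(early), 0, r$within_sd / 2)
      early[[f]] <- pmin(pmax(pert, r$lower), r$upper)
    }
    out <- rbind(wide, early)
  }
  out <- out[order(out$participant_id, out$submitted_at), ]
  rownames(out) <- NULL
  out[, c("participant_id", "submitted_at", names(.quest_fields))]
}

#' Generate 15-minute GPS traces
#'
#' Emits fixed-cadence samples over the configured date range (default the
#' baseline period, the only window residence inference uses). Night samples
#' (local 21:00-06:00) scatter tightly around the participant's hometown --
#' or, for away-from-home nights, around a displaced location; daytime samples
#' get wider jitter. A configured fraction of participants has no GPS at all.
#'
#' @param profiles output of [generate_profiles()].
#' @param cfg a [sim_config()].
#' @return data.frame: \code{participant_id}, \code{timestamp} (POSIXct),
#'   \code{latitude}, \code{longitude}.
#' @export
generate_gps_traces <- function(profiles, cfg) {
  validate_sim_config(cfg)
  .stream_seed(cfg, 3L)
  g <- cfg$gps
  tz <- cfg$calendar$tz
  n <- nrow(profiles)
  has_gps <- stats::runif(n) >= g$no_gps_fraction
  days <- as.Date(as.integer(g$days[1]):as.integer(g$days[2]),
                  origin = "1970-01-01")
  mins <- seq(0, 24 * 60 - 1, by = g$cadence_min)
  hour_of <- (mins / 60)
  night <- hour_of < 6 | hour_of >= 21
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!has_gps[i]) next
    away <- stats::runif(length(days)) < g$away_fraction
    base_lat <- ifelse(away, profiles$hometown_lat[i] + stats::runif(length(days), -0.5, 0.5),
                       profiles$hometown_lat[i])
    base_lon <- ifelse(away, profiles$hometown_lon[i] + stats::runif(length(days), -0.5, 0.5),
                       profiles$hometown_lon[i])
    k <- length(days) * length(mins)
    di <- rep(seq_along(days), each = length(mins))
    sdv <- ifelse(rep(night, length(days)), g$jitter_sd_deg, g$day_jitter_sd_deg)
    ts <- as.POSIXct(paste(days[di], "00:00:00"), tz = tz) + rep(mins, length(days)) * 60
    out[[i]] <- data.frame(
      participant_id = profiles$participant_id[i],
      timestamp = ts,
      latitude = base_lat[di] + stats::rnorm(k, 0, sdv),
      longitude = base_lon[di] + stats::rnorm(k, 0, sdv),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(participant_id = character(),
                                      timestamp = as.POSIXct(character(), tz = tz),
                                      latitude = numeric(), longitude = numeric())
  rownames(res) <- NULL
  res
}

#' Generate siren events
#'
#' Poisson siren counts per war-period night for the high- and medium-exposure
#' areas (the low-exposure area is out of range of the attacks), with event
#' times uniform over the configured overnight window.
#'
#' @param cfg a [sim_config()].
#' @return data.frame: \code{area_id}, \code{start_time} (POSIXct), sorted.
#' @export
generate_sirens <- function(cfg) {
  validate_sim_config(cfg)
  .stream_seed(cfg, 4L)
  tz <- cfg$calendar$tz
  w <- cfg$calendar$period_ranges$W
  nights <- as.Date(as.integer(w[1]):as.integer(w[2]), origin = "1970-01-01")
  hrs <- cfg$sirens$hours
  out <- list()
  for (area in names(cfg$sirens$rate_per_night)) {
    counts <- stats::rpois(length(nights), cfg$sirens$rate_per_night[[area]])
    tot <- sum(counts)
    if (tot == 0L) next
    d <- rep(nights, counts)
    secs <- round(stats::runif(tot, hrs[1] * 3600, hrs[2] * 3600))
    out[[area]] <- data.frame(
      area_id = area,
      start_time = as.POSIXct(paste(d, "00:00:00"), tz = tz) + secs,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(area_id = character(),
                      start_time = as.POSIXct(character(), tz = tz))
  res <- res[order(res$start_time, res$area_id), ]
  rownames(res) <- NULL
  res
}

#' Generate minute-level heart-rate series with siren impulses
#'
#' Minute-level bpm = personal baseline + a diurnal cosine with nadir at
#' 04:00 + Gaussian noise + for each siren in the participant's area an
#' additive impulse of (truncated-normal) amplitude decaying exponentially
#' with the configured time constant. With the default 6-minute constant the
#' impulse is below 5\% of its amplitude 20 minutes after the siren,
#' reproducing the roughly 20-minute return to baseline seen in the field.
#'
#' @param profiles output of [generate_profiles()]; \code{true_group} is used
#'   as the participant's siren area.
#' @param sirens data.frame as [generate_sirens()]; events outside the
#'   simulated time range are skipped with a warning.
#' @param cfg a [sim_config()].
#' @return data.frame: \code{participant_id}, \code{timestamp} (POSIXct),
#'   \code{bpm}.
#' @export
generate_hr_series <- function(profiles, sirens, cfg) {
  validate_sim_config(cfg)
  .stream_seed(cfg, 5L)
  h <- cfg$hr
  tz <- cfg$calendar$tz
  days <- as.Date(as.integer(h$days[1]):as.integer(h$days[2]),
                  origin = "1970-01-01")
  mins <- seq(h$hours[1] * 60, h$hours[2] * 60 - 1)
  day0 <- as.POSIXct(paste(days, "00:00:00"), tz = tz)
  ts <- as.POSIXct(rep(day0, each = length(mins)) + rep(mins, length(days)) * 60,
                   tz = tz)
  hour_of_day <- rep(mins, length(days)) / 60
  diurnal <- -h$diurnal_amp * cos(2 * pi * (hour_of_day - 4) / 24)
  t0 <- min(ts); t1 <- max(ts)
  in_range <- sirens$start_time >= (t0 - 3600) & sirens$start_time <= t1
  if (any(!in_range)) {
    warning(sum(!in_range), " siren(s) outside the simulated heart-rate ",
            "time range; skipped")
    sirens <- sirens[in_range, , drop = FALSE]
  }
  n <- nrow(profiles)
  base <- stats::rnorm(n, h$baseline_mean, h$baseline_sd)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sirens[sirens$area_id == profiles$true_group[i], , drop = FALSE]
    bpm <- base[i] + diurnal + stats::rnorm(length(ts), 0, h$noise_sd)
    if (nrow(s)) {
      amps <- pmax(0, stats::rnorm(nrow(s), h$amp_mean, h$amp_sd))
      for (j in seq_len(nrow(s))) {
        dt <- as.numeric(difftime(ts, s$start_time[j], units = "mins"))
        hit <- dt >= 0 & dt < 12 * h$decay_min
        if (any(hit)) bpm[hit] <- bpm[hit] + amps[j] * exp(-dt[hit] / h$decay_min)
      }
    }
    out[[i]] <- data.frame(participant_id = profiles$participant_id[i],
                           timestamp = ts,
                           bpm = pmin(pmax(bpm, 30), 220),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator and returns the bundle of tables the analysis pipeline
#' consumes. Deterministic: identical configuration (including seed) yields
#' identical bundles, and [write_cohort()] then writes byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @return object of class \code{cohort_bundle}: a list with
#'   \code{profiles}, \code{daily_indicators} (device stream, long),
#'   \code{questionnaires} (wide submissions), \code{gps},
#'   \code{heart_rate}, \code{sirens}, and the \code{config}.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  profiles <- generate_profiles(cfg)
  indicators <- generate_daily_indicators(profiles, cfg)
  device <- cfg$indicator_params$indicator[cfg$indicator_params$stream == "device"]
  bundle <- list(
    profiles = profiles,
    daily_indicators = indicators[indicators$indicator %in% device, ],
    questionnaires = generate_questionnaires(indicators, cfg),
    gps = generate_gps_traces(profiles, cfg),
    sirens = generate_sirens(cfg),
    config = cfg)
  bundle$heart_rate <- generate_hr_series(profiles, bundle$sirens, cfg)
  rownames(bundle$daily_indicators) <- NULL
  structure(bundle, class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle\n")
  for (nm in c("profiles", "daily_indicators", "questionnaires", "gps",
               "heart_rate", "sirens"))
    if (!is.null(x[[nm]])) cat(sprintf("  %-17s %8d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

.fmt_ts <- function(x, tz) format(x, "%Y-%m-%dT%H:%M:%S%z", tz = tz)

#' Write a cohort bundle to CSV files
#'
#' Writes \code{profiles.csv}, \code{daily_indicators.csv},
#' \code{questionnaires.csv}, \code{gps.csv}, \code{heart_rate.csv} and
#' \code{sirens.csv} into \code{dir}, UTF-8, comma-separated, with ISO-8601
#' timestamps carrying the UTC offset.
#'
#' @param bundle a \code{cohort_bundle} (or a compatible list of data.frames).
#' @param dir output directory, created if missing.
#' @param tz timezone for timestamp formatting (default: the bundle config's
#'   calendar timezone).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(bundle, dir, tz = NULL) {
  if (is.null(tz))
    tz <- if (!is.null(bundle$config)) bundle$config$calendar$tz else "Asia/Jerusalem"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name, ts_cols = character()) {
    for (cc in ts_cols) df[[cc]] <- .fmt_ts(df[[cc]], tz)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(bundle$profiles, "profiles.csv")
  w(bundle$daily_indicators, "daily_indicators.csv")
  w(bundle$questionnaires, "questionnaires.csv", "submitted_at")
  w(bundle$gps, "gps.csv", "timestamp")
  w(bundle$heart_rate, "heart_rate.csv", "timestamp")
  w(bundle$sirens, "sirens.csv", "start_time")
  invisible(dir)
}
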