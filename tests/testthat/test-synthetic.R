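test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_participants = 6, seed = 99)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$profiles, b2$profiles)
  expect_identical(b1$daily_indicators, b2$daily_indicators)
  expect_identical(b1$heart_rate, b2$heart_rate)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(b1, d1); write_cohort(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("profiles honour the configured composition", {
  cfg <- sim_config(n_participants = 954, seed = 5)
  p <- generate_profiles(cfg)
  expect_equal(nrow(p), 954L)
  expect_true(all(p$age >= 40))
  expect_false(anyDuplicated(p$participant_id) > 0)
  expect_true(all(abs(p$hometown_lat) <= 90), all(abs(p$hometown_lon) <= 180))

  # empirical group fractions within 3 binomial SDs of the target
  cfg2 <- sim_config(n_participants = 10000, seed = 6,
                     group_proportions = c(high = .25, medium = .5, low = .25))
  p2 <- generate_profiles(cfg2)
  frac <- table(p2$true_group)[c("high", "medium", "low")] / 10000
  tol <- 3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 10000)
  expect_true(all(abs(frac - c(.25, .5, .25)) < tol))
})

test_that("full fill probability yields one record per participant-day-indicator", {
  cfg <- sim_config(n_participants = 4, seed = 2,
                    fill_prob = c(questionnaire = 1, device = 1))
  rec <- generate_daily_indicators(generate_profiles(cfg), cfg)
  n_days <- nrow(study_days(cfg$calendar))
  expect_equal(nrow(rec), 4L * n_days * 12L)
})

test_that("a null configuration leaves population means flat across periods", {
  cfg <- mood_only_config(300, seed = 8,
                          fill_prob = c(questionnaire = 1, device = 1))
  rec <- labelled_records(generate_profiles(cfg), cfg)
  work <- rec[rec$day_type == "work", ]
  m <- tapply(work$value, work$period, mean)
  n <- tapply(work$value, work$period, length)
  s <- tapply(work$value, work$period, sd)
  for (p in c("W", "R1", "R2")) {
    se <- sqrt(s["B"]^2 / n["B"] + s[p]^2 / n[p])
    expect_lt(abs(m[p] - m["B"]), 4 * se)
  }
})

test_that("the free-day offset is recoverable from generated data", {
  cfg <- mood_only_config(400, seed = 13,
                          fill_prob = c(questionnaire = 1, device = 1))
  rec <- labelled_records(generate_profiles(cfg), cfg)
  b <- rec[rec$period == "B", ]
  # between-subject variance cancels by differencing within participant
  wm <- tapply(b$value[b$day_type == "work"], b$participant_id[b$day_type == "work"], mean)
  fm <- tapply(b$value[b$day_type == "free"], b$participant_id[b$day_type == "free"], mean)
  diff <- fm[names(wm)] - wm
  se <- sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff) - 0.10), 3 * se)
})

test_that("GPS traces place nights at home and respect cadence and dropout", {
  cfg <- sim_config(n_participants = 5, seed = 21,
                    gps = list(jitter_sd_deg = 0, day_jitter_sd_deg = 0,
                               away_fraction = 0, no_gps_fraction = 0))
  p <- generate_profiles(cfg)
  g <- generate_gps_traces(p, cfg)
  # 24h / 15 min = 96 samples per participant-day over the 14-day baseline
  expect_equal(nrow(g), 5L * 14L * 96L)
  at4 <- g[format(g$timestamp, "%H:%M") == "04:00", ]
  expect_equal(at4$latitude,
               p$hometown_lat[match(at4$participant_id, p$participant_id)])

  cfg2 <- sim_config(n_participants = 400, seed = 22,
                     gps = list(no_gps_fraction = 0.1))
  g2 <- generate_gps_traces(generate_profiles(cfg2), cfg2)
  n_with <- length(unique(g2$participant_id))
  expect_lt(abs((400 - n_with) - 40), 3 * sqrt(400 * 0.1 * 0.9))
})

test_that("heart-rate impulses have the configured amplitude and decay", {
  cfg <- sim_config(n_participants = 1, seed = 4,
                    group_proportions = c(high = 1, medium = 0, low = 0),
                    hr = list(baseline_mean = 50, baseline_sd = 0,
                              diurnal_amp = 0, noise_sd = 0,
                              amp_mean = 26, amp_sd = 0, decay_min = 6))
  p <- generate_profiles(cfg)
  siren <- data.frame(area_id = "high",
                      start_time = anchor_time("03:00:00"))
  hr <- generate_hr_series(p, siren, cfg)
  dt <- as.numeric(difftime(hr$timestamp, siren$start_time, units = "mins"))
  expect_equal(max(hr$bpm[dt >= 0 & dt <= 15]), 76)
  # below 5% of the amplitude by +20 min: exp(-20/6) < 0.05
  expect_lt(hr$bpm[dt == 20] - 50, 0.05 * 26)
  # zero amplitude reproduces the siren-free series exactly
  cfg0 <- sim_config(n_participants = 1, seed = 4,
                     group_proportions = c(high = 1, medium = 0, low = 0),
                     hr = list(baseline_mean = 50, baseline_sd = 0,
                               diurnal_amp = 0, noise_sd = 0,
                               amp_mean = 0, amp_sd = 0, decay_min = 6))
  hr0 <- generate_hr_series(p, siren, cfg0)
  hr_none <- generate_hr_series(p, siren[0, ], cfg0)
  expect_equal(hr0$bpm, hr_none$bpm)
})

test_that("sirens outside the simulated heart-rate range are skipped with a warning", {
  cfg <- sim_config(n_participants = 1, seed = 4,
                    group_proportions = c(high = 1, medium = 0, low = 0))
  p <- generate_profiles(cfg)
  siren <- data.frame(area_id = "high",
                      start_time = anchor_time("03:00:00", date = "2021-08-01"))
  expect_warning(hr <- generate_hr_series(p, siren, cfg), "skipped")
})

test_that("questionnaire duplicates are earlier submissions superseded by dedup", {
  cfg <- sim_config(n_participants = 30, seed = 17, duplicate_prob = 0.5)
  prof <- generate_profiles(cfg)
  ind <- generate_daily_indicators(prof, cfg)
  q <- generate_questionnaires(ind, cfg)
  key <- paste(q$participant_id, as.Date(q$submitted_at, tz = cfg$calendar$tz))
  expect_gt(sum(duplicated(key)), 0)  # duplicates were generated
  dedup <- deduplicate_questionnaires(q, cfg$calendar$tz)
  long <- questionnaires_to_indicators(dedup, cfg$calendar$tz)
  m <- merge(long, ind, by = c("participant_id", "date", "indicator"))
  # deduplicated values equal the canonical daily values
  expect_equal(m$value.x, m$value.y)
})

test_that("configuration validation names the offending field", {
  expect_error(sim_config(group_proportions = c(high = .5, medium = .4, low = .2)),
               "group_proportions")
  expect_error(sim_config(fill_prob = c(questionnaire = 1.2, device = .9)),
               "fill_prob")
  expect_error(sim_config(war_effects = data.frame(indicator = "vibes",
                                                   high = 1, medium = 0, low = 0)),
               "vibes")
})
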