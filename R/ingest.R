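# Ingestion and cleaning of the per-participant CSV tables.

.parse_ts <- function(x, tz, file, col) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  # fall back to space-separated local timestamps without offset
  retry <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(retry))
    out[retry] <- as.POSIXct(x[retry], tz = tz,
                             tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                            "%Y-%m-%dT%H:%M:%OS"))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("schema error in ", file, ", row ", bad[1], ", field '", col,
         "': unparseable timestamp '", x[bad[1]], "'")
  out
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

.check_range <- function(df, col, lo, hi, file, closed = TRUE) {
  v <- df[[col]]
  bad <- if (closed) which(!is.na(v) & (v < lo | v > hi))
         else which(!is.na(v) & (v <= lo | v >= hi))
  if (length(bad))
    stop("schema error in ", file, ", row ", bad[1], ", field '", col,
         "': value ", v[bad[1]], " outside ",
         if (closed) sprintf("[%s, %s]", lo, hi) else sprintf("(%s, %s)", lo, hi))
}

#' Read and validate a cohort bundle from a directory of CSV files
#'
#' Reads the six tables written by [write_cohort()] (or a deposited data set
#' in the same layout), validates schemas -- required columns, parseable
#' ISO-8601 timestamps, self-report scales in -2..2, nonnegative durations and
#' counts, physiological bpm bounds, valid coordinates -- and returns a
#' \code{cohort_bundle}. Validation failures are errors naming file, row and
#' field; empty optional tables produce a warning and an empty data.frame.
#'
#' @param dir directory containing the CSV files.
#' @param tz timezone for timestamp interpretation.
#' @param quiet suppress the per-table row-count messages.
#' @return object of class \code{cohort_bundle}.
#' @export
read_cohort <- function(dir, tz = "Asia/Jerusalem", quiet = FALSE) {
  rd <- function(name) {
    f <- file.path(dir, name)
    if (!file.exists(f)) stop("missing input file: ", f)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  profiles <- rd("profiles.csv")
  .require_cols(profiles, c("participant_id", "age", "gender", "income_level",
                            "hometown_lat", "hometown_lon"), "profiles.csv")
  if (anyDuplicated(profiles$participant_id))
    stop("schema error in profiles.csv: duplicated participant_id")
  .check_range(profiles, "hometown_lat", -90, 90, "profiles.csv")
  .check_range(profiles, "hometown_lon", -180, 180, "profiles.csv")

  daily <- rd("daily_indicators.csv")
  .require_cols(daily, c("participant_id", "date", "indicator", "value"),
                "daily_indicators.csv")
  daily$date <- as.Date(daily$date)
  unknown <- setdiff(unique(daily$indicator), indicator_names())
  if (length(unknown))
    stop("schema error in daily_indicators.csv: unknown indicator(s) ",
         paste(unknown, collapse = ", "))

  quest <- rd("questionnaires.csv")
  if (nrow(quest) == 0L) {
    warning("questionnaires.csv is empty")
    quest <- data.frame(participant_id = character(),
                        submitted_at = as.POSIXct(character(), tz = tz),
                        mood = numeric(), stress = numeric(),
                        sleep_duration = numeric(), sleep_quality = numeric(),
                        sport_time = numeric(), encounters = numeric())
  } else {
    .require_cols(quest, c("participant_id", "submitted_at", "mood", "stress",
                           "sleep_duration", "sleep_quality", "sport_time",
                           "encounters"), "questionnaires.csv")
    quest$submitted_at <- .parse_ts(quest$submitted_at, tz,
                                    "questionnaires.csv", "submitted_at")
    for (f in c("mood", "stress", "sleep_quality"))
      .check_range(quest, f, -2, 2, "questionnaires.csv")
    for (f in c("sleep_duration", "sport_time", "encounters"))
      .check_range(quest, f, 0, Inf, "questionnaires.csv")
  }

  gps <- rd("gps.csv")
  if (nrow(gps)) {
    .require_cols(gps, c("participant_id", "timestamp", "latitude", "longitude"),
                  "gps.csv")
    gps$timestamp <- .parse_ts(gps$timestamp, tz, "gps.csv", "timestamp")
    .check_range(gps, "latitude", -90, 90, "gps.csv")
    .check_range(gps, "longitude", -180, 180, "gps.csv")
  }

  hr <- rd("heart_rate.csv")
  if (nrow(hr)) {
    .require_cols(hr, c("participant_id", "timestamp", "bpm"), "heart_rate.csv")
    hr$timestamp <- .parse_ts(hr$timestamp, tz, "heart_rate.csv", "timestamp")
    .check_range(hr, "bpm", 20, 250, "heart_rate.csv", closed = FALSE)
  }

  sirens <- rd("sirens.csv")
  if (nrow(sirens)) {
    .require_cols(sirens, c("area_id", "start_time"), "sirens.csv")
    sirens$start_time <- .parse_ts(sirens$start_time, tz, "sirens.csv",
                                   "start_time")
  }

  bundle <- structure(list(profiles = profiles, daily_indicators = daily,
                           questionnaires = quest, gps = gps, heart_rate = hr,
                           sirens = sirens, tz = tz),
                      class = "cohort_bundle")
  if (!quiet)
    message("read cohort: ", nrow(profiles), " profiles, ", nrow(daily),
            " daily indicator rows, ", nrow(quest), " questionnaire rows, ",
            nrow(gps), " GPS rows, ", nrow(hr), " heart-rate rows, ",
            nrow(sirens), " sirens")
  bundle
}

#' Keep only the latest questionnaire submission per participant-day
#'
#' A questionnaire, once submitted, cannot be edited; re-fills supersede the
#' earlier submission, so for each participant and local calendar day only the
#' entry with the maximal \code{submitted_at} is retained. Two entries with an
#' identical timestamp on the same day keep the later one in input order, with
#' a warning. Idempotent, and the identity on already-unique input.
#'
#' @param entries data.frame with \code{participant_id} and POSIXct
#'   \code{submitted_at}.
#' @param tz timezone defining the local calendar-day boundary.
#' @return the deduplicated entries, in (participant, time) order.
#' @export
deduplicate_questionnaires <- function(entries, tz = "Asia/Jerusalem") {
  if (nrow(entries) == 0L) return(entries)
  stopifnot(inherits(entries$submitted_at, "POSIXct"))
  day <- as.Date(entries$submitted_at, tz = tz)
  key <- paste(entries$participant_id, day)
  # stable sort: ties in submitted_at keep input order, so fromLast picks the
  # later entry in input order
  ord <- order(key, entries$submitted_at, method = "radix")
  sorted <- entries[ord, , drop = FALSE]
  skey <- key[ord]
  st <- sorted$submitted_at
  dup_ts <- duplicated(data.frame(skey, st)) |
    duplicated(data.frame(skey, st), fromLast = TRUE)
  if (any(dup_ts))
    warning("identical submission timestamps on the same day for ",
            length(unique(skey[dup_ts])),
            " participant-day(s); keeping the later entry in input order")
  keep <- !duplicated(skey, fromLast = TRUE)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reshape deduplicated questionnaires into long daily indicator records
#'
#' @param quest deduplicated questionnaire data.frame.
#' @param tz timezone defining the local calendar day of each submission.
#' @return long data.frame: \code{participant_id}, \code{date},
#'   \code{indicator}, \code{value} (NA-valued fields dropped).
#' @export
questionnaires_to_indicators <- function(quest, tz = "Asia/Jerusalem") {
  if (nrow(quest) == 0L)
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      indicator = character(), value = numeric()))
  day <- as.Date(quest$submitted_at, tz = tz)
  out <- lapply(names(.quest_fields), function(f) {
    data.frame(participant_id = quest$participant_id, date = day,
               indicator = f, value = quest[[f]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[!is.na(res$value), ]
  rownames(res) <- NULL
  res
}

#' Build the full labelled daily record table
#'
#' Merges the device daily aggregates with the deduplicated questionnaire
#' indicators and labels every row with its day type (work/free) and study
#' period; rows outside the four study periods are dropped.
#'
#' @param bundle a \code{cohort_bundle}.
#' @param calendar a [study_calendar()].
#' @return data.frame: \code{participant_id}, \code{date}, \code{indicator},
#'   \code{value}, \code{day_type}, \code{period}.
#' @export
daily_records <- function(bundle, calendar = study_calendar()) {
  quest <- deduplicate_questionnaires(bundle$questionnaires, calendar$tz)
  qlong <- questionnaires_to_indicators(quest, calendar$tz)
  rec <- rbind(bundle$daily_indicators[, c("participant_id", "date",
                                           "indicator", "value")],
               qlong)
  rec$date <- as.Date(rec$date)
  rec$day_type <- label_day_type(rec$date, calendar)
  rec$period <- assign_period(rec$date, calendar)
  rec <- rec[rec$period != "none", ]
  rownames(rec) <- NULL
  rec
}
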