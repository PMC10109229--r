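# Period-weighted aggregation, inclusion filters, deltas, non-recovery flags.

#' Work/free weighted mean of two day-type means
#'
#' Averages values within day type, then combines with weight 5/7 on work days
#' and 2/7 on free days (correcting for the uneven share of free days across
#' the short study periods). Missing either component makes the weighted mean
#' missing.
#'
#' @param work_values,free_values numeric vectors of daily values.
#' @return list: \code{work_mean}, \code{free_mean}, \code{weighted_mean},
#'   \code{n_work}, \code{n_free}.
#' @export
#' @examples
#' weighted_period_mean(c(1, 1, 1), 8)$weighted_mean  # 3
weighted_period_mean <- function(work_values, free_values) {
  work_values <- work_values[!is.na(work_values)]
  free_values <- free_values[!is.na(free_values)]
  wm <- if (length(work_values)) mean(work_values) else NA_real_
  fm <- if (length(free_values)) mean(free_values) else NA_real_
  list(work_mean = wm, free_mean = fm,
       weighted_mean = if (is.na(wm) || is.na(fm)) NA_real_
                       else 5 / 7 * wm + 2 / 7 * fm,
       n_work = length(work_values), n_free = length(free_values))
}

#' Period aggregates for every participant, indicator and period
#'
#' @param records labelled daily records from [daily_records()] (columns
#'   \code{participant_id}, \code{indicator}, \code{period}, \code{day_type},
#'   \code{value}).
#' @return data.frame: one row per participant x indicator x period present in
#'   the data, with \code{work_mean}, \code{free_mean}, \code{weighted_mean},
#'   \code{n_work}, \code{n_free}.
#' @export
period_aggregates <- function(records) {
  records <- records[records$period %in% c("B", "W", "R1", "R2"), ]
  if (nrow(records) == 0L)
    return(data.frame(participant_id = character(), indicator = character(),
                      period = character(), work_mean = numeric(),
                      free_mean = numeric(), weighted_mean = numeric(),
                      n_work = integer(), n_free = integer()))
  key <- interaction(records$participant_id, records$indicator, records$period,
                     drop = TRUE, sep = "\r")
  sums <- rowsum(cbind(v = records$value, n = 1,
                       vw = records$value * (records$day_type == "work"),
                       nw = as.numeric(records$day_type == "work")),
                 key)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  n_work <- sums[, "nw"]
  n_free <- sums[, "n"] - n_work
  work_mean <- ifelse(n_work > 0, sums[, "vw"] / n_work, NA_real_)
  free_mean <- ifelse(n_free > 0, (sums[, "v"] - sums[, "vw"]) / n_free,
                      NA_real_)
  out <- data.frame(participant_id = parts[, 1], indicator = parts[, 2],
                    period = parts[, 3], work_mean = work_mean,
                    free_mean = free_mean,
                    weighted_mean = 5 / 7 * work_mean + 2 / 7 * free_mean,
                    n_work = as.integer(n_work), n_free = as.integer(n_free),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$indicator, out$period), ]
  rownames(out) <- NULL
  out
}

#' Per-indicator test inclusion filter
#'
#' A participant enters an indicator's test only with at least one work-day
#' and at least one free-day value in every required period, so eligibility is
#' computed independently per indicator and the n of each test may differ.
#'
#' @param aggregates output of [period_aggregates()].
#' @param required_periods periods that must each have both day-type
#'   components.
#' @return data.frame of eligible \code{participant_id} x \code{indicator}
#'   pairs.
#' @export
apply_inclusion_filter <- function(aggregates,
                                   required_periods = c("B", "W", "R1", "R2")) {
  a <- aggregates[aggregates$period %in% required_periods, ]
  ok <- a$n_work >= 1L & a$n_free >= 1L
  key <- paste(a$participant_id, a$indicator, sep = "\r")
  n_ok <- rowsum(as.numeric(ok), key)
  eligible <- rownames(n_ok)[n_ok[, 1] == length(required_periods)]
  if (length(eligible) == 0L)
    return(data.frame(participant_id = character(), indicator = character()))
  parts <- do.call(rbind, strsplit(eligible, "\r", fixed = TRUE))
  out <- data.frame(participant_id = parts[, 1], indicator = parts[, 2],
                    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$indicator), , drop = FALSE]
}

#' Between-period change per participant
#'
#' @param aggregates output of [period_aggregates()].
#' @param p1,p2 the two periods; the delta is \code{p2 - p1} on the weighted
#'   means.
#' @param indicator optional single indicator to restrict to.
#' @return data.frame: \code{participant_id}, \code{indicator}, \code{delta}.
#'   Participants missing either period's weighted mean are skipped with a
#'   message.
#' @export
period_delta <- function(aggregates, p1, p2, indicator = NULL) {
  a <- aggregates
  if (!is.null(indicator)) a <- a[a$indicator == indicator, ]
  x1 <- a[a$period == p1, c("participant_id", "indicator", "weighted_mean")]
  x2 <- a[a$period == p2, c("participant_id", "indicator", "weighted_mean")]
  m <- merge(x1, x2, by = c("participant_id", "indicator"),
             suffixes = c("_1", "_2"))
  skipped <- is.na(m$weighted_mean_1) | is.na(m$weighted_mean_2)
  if (any(skipped))
    message(sum(skipped), " participant-indicator pair(s) skipped: missing ",
            "period value")
  m <- m[!skipped, ]
  data.frame(participant_id = m$participant_id, indicator = m$indicator,
             delta = m$weighted_mean_2 - m$weighted_mean_1,
             stringsAsFactors = FALSE)
}

#' Flag participants who did not return to baseline
#'
#' Operationalizes the qualitative non-recovery observation as a robust
#' outlier rule on the cohort's baseline-to-R1 change distribution (which is
#' roughly normal around zero): a participant is flagged when their delta lies
#' beyond \code{k} robust SDs (median + k * 1.4826 * MAD) from the cohort
#' median, in the indicator's adverse direction.
#'
#' @param deltas data.frame from [period_delta()] for one indicator
#'   (B to R1).
#' @param adverse +1 if an increase is adverse for this indicator, -1 if a
#'   decrease is.
#' @param k robust-SD multiplier (default 2).
#' @return the input with a logical \code{non_recovered} column.
#' @export
flag_non_recovered <- function(deltas, adverse, k = 2) {
  stopifnot(adverse %in% c(-1, 1))
  if (nrow(deltas) < 10L)
    stop("refusing to flag non-recovery with fewer than 10 participants: ",
         "the delta distribution is unstable")
  ctr <- stats::median(deltas$delta)
  scl <- stats::mad(deltas$delta)  # already scaled by 1.4826
  deltas$non_recovered <- adverse * (deltas$delta - ctr) > k * scl
  deltas
}
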