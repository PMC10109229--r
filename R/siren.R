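# Siren heart-rate response statistic: windowed baseline-vs-max delta with
# the night-time eligibility and isolation filters.

#' Filter sirens to the eligible night-time, isolated events
#'
#' Keeps sirens in the participant's area whose local clock time lies in the
#' night window (default 02:00--06:00, minimizing physical-activity
#' confounding) and for which no other siren of the same area fell inside the
#' baseline time frame, i.e. the open interval (t - 45 min, t - 15 min);
#' such sirens would contaminate the baseline and are excluded.
#'
#' @param sirens data.frame (\code{area_id}, POSIXct \code{start_time}),
#'   time-sorted.
#' @param area the participant's residence-area label.
#' @param tz timezone for the local clock.
#' @param night_hours numeric length-2, half-open local-hour window.
#' @param baseline_window minutes before the siren delimiting the baseline
#'   frame scanned for disqualifying neighbours.
#' @return the eligible subset of \code{sirens}.
#' @export
eligible_sirens <- function(sirens, area, tz = "Asia/Jerusalem",
                            night_hours = c(2, 6),
                            baseline_window = c(45, 15)) {
  s <- sirens[sirens$area_id == area, , drop = FALSE]
  if (nrow(s) == 0L) return(s)
  lt <- as.POSIXlt(s$start_time, tz = tz)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  in_night <- hour >= night_hours[1] & hour < night_hours[2]
  t <- as.numeric(s$start_time)
  clean <- vapply(seq_len(nrow(s)), function(i) {
    others <- t[-i]
    !any(others > t[i] - baseline_window[1] * 60 &
           others < t[i] - baseline_window[2] * 60)
  }, logical(1))
  out <- s[in_night & clean, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heart-rate response to a single siren
#'
#' Baseline = mean bpm over [t - 45 min, t - 15 min); affected = maximum bpm
#' over the closed window [t - 5 min, t + 15 min]; delta = affected -
#' baseline. The delta is invariant under level shifts of the whole series.
#' As a max-minus-mean statistic it carries a positive bias on impulse-free
#' noisy series; this is a property of the estimator, documented rather than
#' corrected.
#'
#' @param hr_series one participant's heart-rate data.frame (POSIXct
#'   \code{timestamp}, \code{bpm}).
#' @param siren_time POSIXct siren start.
#' @param baseline_window,affected_window window bounds in minutes relative to
#'   the siren.
#' @return list: \code{baseline_bpm}, \code{affected_bpm}, \code{delta_bpm},
#'   \code{n_baseline}, \code{n_affected}; all NA (with a message) if either
#'   window holds no samples.
#' @export
siren_delta <- function(hr_series, siren_time,
                        baseline_window = c(-45, -15),
                        affected_window = c(-5, 15)) {
  dt <- as.numeric(difftime(hr_series$timestamp, siren_time, units = "mins"))
  base <- hr_series$bpm[dt >= baseline_window[1] & dt < baseline_window[2]]
  aff <- hr_series$bpm[dt >= affected_window[1] & dt <= affected_window[2]]
  if (length(base) == 0L || length(aff) == 0L) {
    message("siren at ", format(siren_time), " skipped: empty ",
            if (length(base) == 0L) "baseline" else "affected", " window")
    return(list(baseline_bpm = NA_real_, affected_bpm = NA_real_,
                delta_bpm = NA_real_, n_baseline = length(base),
                n_affected = length(aff)))
  }
  b <- mean(base); a <- max(aff)
  list(baseline_bpm = b, affected_bpm = a, delta_bpm = a - b,
       n_baseline = length(base), n_affected = length(aff))
}

#' All per-participant, per-siren heart-rate responses
#'
#' Matches sirens to participants by residence-area label (the exposure
#' group), applies the eligibility filters, and computes the windowed response
#' for each remaining siren.
#'
#' @param heart_rate cohort heart-rate data.frame.
#' @param sirens siren events data.frame.
#' @param exposure data.frame with \code{participant_id} and \code{group}
#'   (e.g. from [assign_exposure()]), used as the area label.
#' @param tz timezone for the local clock filters.
#' @param ... passed to [eligible_sirens()].
#' @return data.frame: \code{participant_id}, \code{siren_time},
#'   \code{baseline_bpm}, \code{affected_bpm}, \code{delta_bpm}.
#' @export
siren_responses <- function(heart_rate, sirens, exposure,
                            tz = "Asia/Jerusalem", ...) {
  idx <- split(seq_len(nrow(heart_rate)), heart_rate$participant_id)
  out <- list()
  for (pid in names(idx)) {
    area <- exposure$group[match(pid, exposure$participant_id)]
    if (is.na(area)) next
    elig <- eligible_sirens(sirens, area, tz = tz, ...)
    if (nrow(elig) == 0L) next
    hr <- heart_rate[idx[[pid]], , drop = FALSE]
    resp <- lapply(seq_len(nrow(elig)), function(j) {
      d <- suppressMessages(siren_delta(hr, elig$start_time[j]))
      data.frame(participant_id = pid, siren_time = elig$start_time[j],
                 baseline_bpm = d$baseline_bpm, affected_bpm = d$affected_bpm,
                 delta_bpm = d$delta_bpm, stringsAsFactors = FALSE)
    })
    out[[pid]] <- do.call(rbind, resp)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(participant_id = character(),
                      siren_time = as.POSIXct(character(), tz = tz),
                      baseline_bpm = numeric(), affected_bpm = numeric(),
                      delta_bpm = numeric())
  res <- res[!is.na(res$delta_bpm), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mean heart-rate response per participant
#'
#' Since a participant can experience several sirens, each participant is
#' summarized by the arithmetic mean of their per-siren deltas.
#'
#' @param responses output of [siren_responses()].
#' @return data.frame: \code{participant_id}, \code{mean_delta_bpm},
#'   \code{n_sirens}.
#' @export
participant_mean_delta <- function(responses) {
  if (nrow(responses) == 0L)
    return(data.frame(participant_id = character(), mean_delta_bpm = numeric(),
                      n_sirens = integer()))
  agg <- rowsum(cbind(d = responses$delta_bpm, n = 1),
                responses$participant_id)
  data.frame(participant_id = rownames(agg),
             mean_delta_bpm = agg[, "d"] / agg[, "n"],
             n_sirens = as.integer(agg[, "n"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort median of per-participant mean responses
#'
#' @param participant_means output of [participant_mean_delta()].
#' @return the median mean-delta (bpm) over participants.
#' @export
cohort_median_delta <- function(participant_means) {
  if (nrow(participant_means) == 0L)
    stop("no eligible participants with siren responses")
  stats::median(participant_means$mean_delta_bpm)
}
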