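#' Study calendar: periods, weekends and holidays
#'
#' Defines the four contiguous study periods -- baseline (B), war (W) and the
#' two "back to routine" windows (R1, R2) -- together with the weekly free-day
#' pattern and national holidays that drive the work/free day-type labelling.
#'
#' Defaults follow the May 2021 conflict study design: B = 2021-04-26 to
#' 2021-05-09, W = 2021-05-10 to 2021-05-20, R1 = 2021-05-21 to 2021-06-03,
#' R2 = 2021-06-04 to 2021-06-17; the weekend is Friday--Saturday and the one
#' national holiday inside the window is Shavuot (2021-05-17).
#'
#' @param period_ranges named list mapping \code{B}, \code{W}, \code{R1},
#'   \code{R2} to length-2 Date vectors (closed ranges), in calendar order and
#'   non-overlapping.
#' @param weekend_days character vector of English weekday names treated as
#'   free days every week.
#' @param holidays Date vector of national holidays (also free days).
#' @param tz Olson timezone in which calendar days and clock windows are
#'   interpreted.
#' @return An object of class \code{study_calendar}.
#' @export
#' @examples
#' cal <- study_calendar()
#' assign_period(as.Date("2021-05-15"), cal)  # "W"
study_calendar <- function(period_ranges = list(
                             B  = as.Date(c("2021-04-26", "2021-05-09")),
                             W  = as.Date(c("2021-05-10", "2021-05-20")),
                             R1 = as.Date(c("2021-05-21", "2021-06-03")),
                             R2 = as.Date(c("2021-06-04", "2021-06-17"))),
                           weekend_days = c("Friday", "Saturday"),
                           holidays = as.Date("2021-05-17"),
                           tz = "Asia/Jerusalem") {
  stopifnot(is.list(period_ranges),
            setequal(names(period_ranges), c("B", "W", "R1", "R2")))
  for (p in c("B", "W", "R1", "R2")) {
    r <- period_ranges[[p]]
    if (!inherits(r, "Date") || length(r) != 2L || r[1] > r[2])
      stop("period_ranges$", p, " must be a length-2 ascending Date range")
  }
  ord <- c("B", "W", "R1", "R2")
  for (i in seq_len(3L)) {
    if (period_ranges[[ord[i]]][2] >= period_ranges[[ord[i + 1L]]][1])
      stop("period ranges must be non-overlapping and in order B, W, R1, R2")
  }
  bad <- setdiff(weekend_days, .weekday_names)
  if (length(bad)) stop("unknown weekday name(s): ", paste(bad, collapse = ", "))
  structure(list(period_ranges = period_ranges[ord],
                 weekend_days = weekend_days,
                 holidays = as.Date(holidays),
                 tz = tz),
            class = "study_calendar")
}

# locale-independent weekday lookup (0 = Sunday, as POSIXlt$wday)
.weekday_names <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
                    "Friday", "Saturday")

.weekday_of <- function(dates) {
  .weekday_names[as.POSIXlt(dates)$wday + 1L]
}

#' Label calendar days as work or free
#'
#' A day is free iff its weekday is a weekend day or the date is a national
#' holiday; all other days are work days.
#'
#' @param dates Date vector.
#' @param calendar a [study_calendar()].
#' @return character vector of \code{"work"} / \code{"free"}.
#' @export
label_day_type <- function(dates, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  dates <- as.Date(dates)
  free <- .weekday_of(dates) %in% calendar$weekend_days |
    dates %in% calendar$holidays
  ifelse(free, "free", "work")
}

#' Assign study periods to calendar days
#'
#' @param dates Date vector.
#' @param calendar a [study_calendar()].
#' @return character vector over \code{"B"}, \code{"W"}, \code{"R1"},
#'   \code{"R2"}, or \code{"none"} for days outside all four closed ranges.
#' @export
assign_period <- function(dates, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  dates <- as.Date(dates)
  out <- rep("none", length(dates))
  for (p in names(calendar$period_ranges)) {
    r <- calendar$period_ranges[[p]]
    out[dates >= r[1] & dates <= r[2]] <- p
  }
  out
}

#' All study days with their period and day type
#'
#' @param calendar a [study_calendar()].
#' @return data.frame with columns \code{date}, \code{period},
#'   \code{day_type}, one row per day in B..R2.
#' @export
study_days <- function(calendar) {
  rng <- range(unlist(lapply(calendar$period_ranges, as.integer)))
  dates <- as.Date(rng[1]:rng[2], origin = "1970-01-01")
  data.frame(date = dates,
             period = assign_period(dates, calendar),
             day_type = label_day_type(dates, calendar))
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("Study calendar (tz ", x$tz, ")\n", sep = "")
  for (p in names(x$period_ranges))
    cat(sprintf("  %-3s %s .. %s\n", p,
                x$period_ranges[[p]][1], x$period_ranges[[p]][2]))
  cat("  weekend:", paste(x$weekend_days, collapse = ", "), "\n")
  if (length(x$holidays))
    cat("  holidays:", paste(format(x$holidays), collapse = ", "), "\n")
  invisible(x)
}
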