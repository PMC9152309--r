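# Episode-timestamp preprocessing: time-of-day bins, day-level
# morning/evening indicators, and the study-specific binary outcome.

.BIN_LEVELS <- c("midnight", "morning", "early_afternoon", "late_afternoon",
                 "early_evening", "late_evening")

# Accepts "HH:MM"/"HH:MM:SS" strings, POSIXt, or numeric hours; returns
# fractional hours in [0, 24).
.as_hours <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    return(lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    return(vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p)) || length(p) < 2L)
        stop("cannot parse time of day", call. = FALSE)
      sum(p * c(1, 1 / 60, 1 / 3600)[seq_along(p)])
    }, numeric(1)))
  }
  if (is.numeric(x)) return(x)
  stop("unsupported time-of-day representation", call. = FALSE)
}

#' Classify an episode start time into a time-of-day bin
#'
#' Brushing episodes are binned by their starting clock time into six
#' categories with half-open boundaries \code{[start, end)}:
#' morning 5:00-12:00, early afternoon 12:00-15:00, late afternoon
#' 15:00-19:00, early evening 19:00-21:00, late evening 21:00-24:00,
#' and midnight 0:00-5:00.
#'
#' @param time time of day: \code{"HH:MM"} / \code{"HH:MM:SS"} strings,
#'   \code{POSIXt} values, or numeric fractional hours. Vectorized.
#' @return Character vector of bin labels.
#' @examples
#' bin_episode(c("06:30", "13:00", "04:59"))
#' @export
bin_episode <- function(time) {
  h <- .as_hours(time) %% 24
  cut_points <- c(0, 5, 12, 15, 19, 21, 24)
  labels <- c("midnight", "morning", "early_afternoon", "late_afternoon",
              "early_evening", "late_evening")
  labels[findInterval(h, cut_points, rightmost.closed = FALSE)]
}

#' Day-level morning/evening brushing indicators
#'
#' Derives the two context-specific indicators from a day's episode
#' times. Morning brushing searches the \emph{morning} bin first and
#' falls back to \emph{early afternoon}; evening brushing searches
#' \emph{late evening} together with the following night's
#' \emph{midnight} bin first and falls back to \emph{early evening}.
#' Late-afternoon episodes are mid-day brushing unrelated to either
#' context and never count. Midnight episodes are attributed to the
#' evening of the \emph{previous} calendar date, so they are passed via
#' \code{next_day_times}.
#'
#' @param times episode start times on the calendar date being
#'   classified (any representation accepted by
#'   \code{\link{bin_episode}}); may be empty.
#' @param next_day_times episode start times on the following calendar
#'   date; only its midnight bin (0:00-5:00) is consulted.
#' @return Named integer vector \code{c(morning = 0/1, evening = 0/1)}.
#' @examples
#' classify_day(c("07:00", "22:30"))         # c(morning = 1, evening = 1)
#' classify_day("16:00")                     # mid-day episode: c(0, 0)
#' classify_day(character(0), "00:30")       # late-night brush: c(0, 1)
#' @export
classify_day <- function(times = character(0), next_day_times = character(0)) {
  bins <- if (length(times)) bin_episode(times) else character(0)
  next_bins <- if (length(next_day_times)) bin_episode(next_day_times) else character(0)
  morning <- if (any(bins == "morning")) 1L
             else if (any(bins == "early_afternoon")) 1L else 0L
  evening <- if (any(bins == "late_evening") || any(next_bins == "midnight")) 1L
             else if (any(bins == "early_evening")) 1L else 0L
  c(morning = morning, evening = evening)
}

#' Day-level outcome from the two session indicators
#'
#' Collapses the morning and evening indicators into the study's binary
#' outcome. Mode \code{"brush_twice"} requires both sessions;
#' \code{"target_morning"} / \code{"target_evening"} select the single
#' target session (the session the participant did not habitually
#' perform before the intervention). Missing inputs propagate.
#'
#' @param morning,evening binary indicators (0/1, \code{NA} allowed).
#'   Vectorized.
#' @param mode one of \code{"brush_twice"}, \code{"target_morning"},
#'   \code{"target_evening"}.
#' @return Binary outcome vector (with \code{NA} where inputs are
#'   missing).
#' @export
day_outcome <- function(morning, evening, mode = c("brush_twice",
                                                   "target_morning",
                                                   "target_evening")) {
  mode <- match.arg(mode)
  switch(mode,
         brush_twice = as.integer(morning & evening),
         target_morning = as.integer(morning == 1L),
         target_evening = as.integer(evening == 1L))
}

#' Convert timestamped episodes into day-level records
#'
#' Full preprocessing step from a table of brushing-episode timestamps
#' to one record per participant-day with morning/evening indicators
#' and the study outcome. The date range covered is, per participant,
#' the span from the first to the last episode date unless
#' \code{dates} is given. Externally supplied missing-data windows can
#' be injected afterwards by setting indicators to \code{NA}.
#'
#' @param episodes data frame with columns \code{participant_id} and
#'   \code{start} (ISO 8601 date-times, \code{POSIXct} or
#'   \code{"YYYY-MM-DD HH:MM[:SS]"} strings).
#' @param mode outcome mode passed to \code{\link{day_outcome}}.
#' @param dates optional \code{Date} vector of days to cover for every
#'   participant.
#' @return Data frame with columns \code{participant_id}, \code{date},
#'   \code{morning}, \code{evening}, \code{outcome}.
#' @export
episodes_to_days <- function(episodes, mode = "brush_twice", dates = NULL) {
  stopifnot(is.data.frame(episodes),
            all(c("participant_id", "start") %in% names(episodes)))
  start <- episodes$start
  if (!inherits(start, "POSIXt"))
    start <- as.POSIXct(as.character(start), tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                       "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(start)) stop("unparseable episode timestamps", call. = FALSE)
  lt <- as.POSIXlt(start)
  hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  date <- as.Date(start, tz = "UTC")
  out <- lapply(split(seq_along(date), episodes$participant_id), function(idx) {
    d <- date[idx]; h <- hours[idx]
    days <- if (is.null(dates)) seq(min(d), max(d), by = "day") else dates
    rows <- lapply(days, function(day) {
      ind <- classify_day(h[d == day], h[d == day + 1])
      data.frame(date = day, morning = ind[["morning"]],
                 evening = ind[["evening"]])
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, Map(function(pid, df) cbind(participant_id = pid, df),
                            names(out), out))
  rownames(res) <- NULL
  res$outcome <- day_outcome(res$morning, res$evening, mode)
  res
}
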