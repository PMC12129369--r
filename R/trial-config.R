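#' Default catalog of prompt messages
#'
#' Five short encouragements to move; one is chosen uniformly at random each
#' time a prompt is delivered.
#'
#' @return Character vector of length 5.
#' @export
default_messages <- function() {
  c(
    "Time for a quick walk?",
    "How about some exercise?",
    "Get up and move your body!",
    "Let's do some exercise!",
    "Let's move a little!"
  )
}

#' Trial configuration
#'
#' Bundles the decision schedule, the wear-time validity threshold, the
#' message catalog and the seed used for message selection. The default
#' schedule evaluates the preceding hour at minute :34 of every hour from
#' 8 AM to 10 PM, giving 14 decision epochs per day (08:34, ..., 21:34).
#'
#' @param start_hour,end_hour Scheduled waking span, whole hours on the 24 h
#'   clock; decisions are made at epochs in `[start_hour, end_hour)`.
#' @param decision_minute Minute of the hour at which each decision is made.
#' @param min_wear_min Minimum worn minutes (out of 60) for an hour window to
#'   count as valid in criteria derivation, decisions and analysis.
#' @param messages Character vector of prompt messages.
#' @param seed Integer seed driving random message selection.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(start_hour = 8L, end_hour = 22L, decision_minute = 34L,
                         min_wear_min = 50L, messages = default_messages(),
                         seed = 1L) {
  start_hour <- as.integer(start_hour)
  end_hour <- as.integer(end_hour)
  decision_minute <- as.integer(decision_minute)
  if (is.na(start_hour) || is.na(end_hour) || start_hour < 0L || end_hour > 24L) {
    stop("schedule hours must lie in [0, 24]", call. = FALSE)
  }
  if (end_hour <= start_hour) {
    stop("configuration error: end_hour must exceed start_hour", call. = FALSE)
  }
  if (decision_minute < 0L || decision_minute > 59L) {
    stop("decision_minute must lie in [0, 59]", call. = FALSE)
  }
  if (min_wear_min < 0 || min_wear_min > 60) {
    stop("min_wear_min must lie in [0, 60]", call. = FALSE)
  }
  if (!is.character(messages) || length(messages) < 1L) {
    stop("configuration error: message catalog must be a non-empty character vector",
         call. = FALSE)
  }
  structure(
    list(
      start_hour = start_hour, end_hour = end_hour,
      decision_minute = decision_minute,
      min_wear_min = as.numeric(min_wear_min),
      messages = messages, seed = as.integer(seed)
    ),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf(
    "<trial_config> decisions at :%02d from %02d:00 to %02d:00 (%d epochs/day), min wear %g/60 min, %d messages\n",
    x$decision_minute, x$start_hour, x$end_hour,
    x$end_hour - x$start_hour, x$min_wear_min, length(x$messages)
  ))
  invisible(x)
}

#' Read / write a trial configuration as JSON
#'
#' The on-disk layout nests the schedule:
#' `{"schedule": {"start_hour", "end_hour", "decision_minute"},
#'   "min_wear_min", "messages", "seed"}`.
#'
#' @param path File path.
#' @param config A [trial_config()] object.
#' @return `read_trial_config()` returns a `trial_config`;
#'   `write_trial_config()` returns `path` invisibly.
#' @export
read_trial_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_config(
    start_hour = x$schedule$start_hour,
    end_hour = x$schedule$end_hour,
    decision_minute = x$schedule$decision_minute,
    min_wear_min = x$min_wear_min,
    messages = x$messages,
    seed = x$seed
  )
}

#' @rdname read_trial_config
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  jsonlite::write_json(
    list(
      schedule = list(
        start_hour = config$start_hour,
        end_hour = config$end_hour,
        decision_minute = config$decision_minute
      ),
      min_wear_min = config$min_wear_min,
      messages = config$messages,
      seed = config$seed
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Decision epochs for one day
#'
#' Enumerates the scheduled decision epochs of a calendar day: one per hour at
#' the configured decision minute, from `start_hour` up to (excluding)
#' `end_hour`. Each epoch evaluates the 60 minutes `[epoch - 60 min,
#' epoch - 1 min]`.
#'
#' @param date A `Date` (or string coercible to one).
#' @param config A [trial_config()].
#' @return A `POSIXct` vector (UTC used as a naive local clock).
#' @export
decision_grid <- function(date, config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  date <- as.Date(date)
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  hours <- seq.int(config$start_hour, config$end_hour - 1L)
  midnight + hours * 3600 + config$decision_minute * 60
}
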