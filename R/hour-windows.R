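# Hourly decision windows on the :34-minute grid.
#
# An hour window starting at h:34 aggregates the 60 minutes [h:34, h+1:33].
# Minutes absent from the stream are treated as nonwear and contribute zeros,
# so window aggregates are additive over any partition of their minutes.

window_start_of <- function(time, decision_minute = 34L) {
  sec <- as.numeric(time)
  off <- decision_minute * 60
  as.POSIXct(floor((sec - off) / 3600) * 3600 + off,
             tz = "UTC", origin = "1970-01-01")
}

window_sums <- function(dt) {
  dt[, .(
    sedentary_min = sum(wear == "worn" & intensity == "sedentary"),
    lightly_min   = sum(wear == "worn" & intensity == "lightly"),
    fairly_min    = sum(wear == "worn" & intensity == "fairly"),
    very_min      = sum(wear == "worn" & intensity == "very"),
    calories_kcal = sum(calories_kcal),
    steps         = sum(steps),
    distance_m    = sum(distance_m),
    worn_min      = sum(wear == "worn"),
    n_present     = .N
  ), by = .(participant_id, start = wstart)]
}

#' Aggregate one :34-aligned hour of minute records
#'
#' Sums a single participant's minute records over one decision window. At
#' most 60 minute slots may be supplied; missing slots are treated as nonwear
#' (they contribute zeros to every aggregate). Intensity minutes are counted
#' only while the device is worn.
#'
#' @param minutes Minute-stream rows covering (part of) one window.
#' @param decision_minute Minute of the hour anchoring the window grid.
#' @return A one-row data.frame: `participant_id`, `start`, the four intensity
#'   minute counts, `calories_kcal`, `steps`, `distance_m`, `worn_min`.
#' @export
aggregate_hour <- function(minutes, decision_minute = 34L) {
  if (nrow(minutes) < 1L || nrow(minutes) > 60L) {
    stop("invalid input: expected 1-60 minute rows", call. = FALSE)
  }
  if (length(unique(minutes$participant_id)) != 1L) {
    stop("invalid input: minutes mix participants", call. = FALSE)
  }
  if (anyDuplicated(as.numeric(minutes$timestamp))) {
    stop("invalid input: duplicated minute timestamps", call. = FALSE)
  }
  ws <- window_start_of(minutes$timestamp, decision_minute)
  if (length(unique(as.numeric(ws))) != 1L) {
    stop("invalid input: minutes span more than one window", call. = FALSE)
  }
  dt <- data.table::as.data.table(minutes)
  dt[, wstart := ws]
  out <- as.data.frame(window_sums(dt))
  out$n_present <- NULL
  out
}

#' Aggregate a minute stream into hourly decision windows
#'
#' Vectorised form of [aggregate_hour()]: every minute is assigned to its
#' :34-aligned window and aggregates are summed per participant and window.
#' When `starts` is supplied the result contains exactly one row per
#' participant x start, with all-zero (fully nonwear) windows filled in where
#' the stream has no minutes.
#'
#' @param stream Minute-stream data.frame (possibly several participants).
#' @param config A [trial_config()]; supplies the grid anchor minute.
#' @param starts Optional `POSIXct` of window starts to restrict/complete to.
#' @return Data.frame of hour windows sorted by participant then start.
#' @export
hour_windows <- function(stream, config = trial_config(), starts = NULL) {
  dt <- data.table::as.data.table(stream)
  dt[, wstart := window_start_of(timestamp, config$decision_minute)]
  win <- window_sums(dt)
  if (!is.null(starts)) {
    grid <- data.table::CJ(participant_id = unique(dt$participant_id),
                           start = unique(starts))
    win <- win[grid, on = c("participant_id", "start")]
    for (col in setdiff(names(win), c("participant_id", "start"))) {
      data.table::set(win, which(is.na(win[[col]])), col, 0)
    }
  }
  data.table::setorder(win, participant_id, start)
  win[, n_present := NULL]
  as.data.frame(win)
}

#' Wear-time validity of an hour window
#'
#' An hour enters criteria derivation, prompt decisions and analysis only if
#' the device was worn for at least `min_wear` of its 60 minutes. The paper's
#' analyses exclude sleep and nonwear time; the 50-minute default is this
#' package's operationalisation of that exclusion at the hour level.
#'
#' @param window Hour-window data.frame (one or more rows).
#' @param min_wear Minimum worn minutes in `[0, 60]`; comparison is `>=`.
#' @return Logical vector, one element per row.
#' @export
valid_hour <- function(window, min_wear = 50) {
  if (min_wear < 0 || min_wear > 60) {
    stop("min_wear must lie in [0, 60]", call. = FALSE)
  }
  window$worn_min >= min_wear
}
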