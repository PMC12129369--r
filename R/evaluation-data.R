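# Builders for the two analysis datasets:
#   pre/post  - one before/after hour pair per delivered prompt (proximal
#               effect of a prompt);
#   weekly    - per-participant hourly means over valid decision-grid hours,
#               week 1 (baseline) vs week 2 (intervention).

OUTCOMES <- c("sedentary_min", "lightly_min", "fairly_min", "very_min",
              "calories_kcal", "steps", "distance_m")

#' Build the pre/post-hour dataset from an intervention log
#'
#' For every delivered prompt the *before* hour is the decision window
#' `[epoch - 60 min, epoch - 1 min]` that triggered it and the *after* hour is
#' `[epoch, epoch + 59 min]`. Pairs whose after-hour fails the wear-time
#' validity check (or is not covered by the streams) are dropped and counted.
#' Consecutive prompts are retained even though one event's after-hour is the
#' next event's before-hour.
#'
#' @param log Intervention log (from [run_trial()] or [simulate_trial()]).
#' @param x Minute streams or precomputed hour windows.
#' @param config A [trial_config()].
#' @return Long data.frame: `participant_id`, `epoch`, `phase`
#'   (`before`/`after`) and the seven hourly outcomes. Attribute `dropped`
#'   counts discarded pairs.
#' @export
build_prepost <- function(log, x, config = trial_config()) {
  win <- if ("timestamp" %in% names(x)) hour_windows(x, config) else x
  wdt <- data.table::as.data.table(win)
  cols <- c(OUTCOMES, "worn_min")
  empty <- data.frame(
    participant_id = character(0),
    epoch = as.POSIXct(character(0), tz = "UTC"),
    phase = factor(character(0), levels = c("before", "after"))
  )
  for (cc in OUTCOMES) empty[[cc]] <- numeric(0)
  if (!nrow(log)) {
    attr(empty, "dropped") <- 0L
    return(empty)
  }
  ldt <- data.table::data.table(participant_id = log$participant_id,
                                epoch = log$epoch)
  pull <- function(starts) {
    q <- data.table::data.table(participant_id = ldt$participant_id,
                                start = starts)
    wdt[q, on = c("participant_id", "start")][, cols, with = FALSE]
  }
  before <- pull(ldt$epoch - 3600)
  after <- pull(ldt$epoch)
  ok <- !is.na(before$worn_min) & !is.na(after$worn_min) &
    after$worn_min >= config$min_wear_min
  dropped <- sum(!ok)
  mk <- function(block, phase) {
    out <- data.frame(participant_id = ldt$participant_id[ok],
                      epoch = ldt$epoch[ok],
                      phase = factor(rep(phase, sum(ok)),
                                     levels = c("before", "after")))
    cbind(out, as.data.frame(block)[ok, OUTCOMES, drop = FALSE])
  }
  out <- rbind(mk(before, "before"), mk(after, "after"))
  out <- out[order(out$participant_id, out$epoch, out$phase), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Build the weekly hourly-mean dataset
#'
#' Per participant, week and outcome: the mean over valid decision-grid hour
#' windows (the same windows the prompt rule evaluates). Participants with
#' fewer than 3 valid days in either week are flagged (attribute `flagged`),
#' mirroring exclusion of low-participation subjects.
#'
#' @param x Minute streams or precomputed hour windows.
#' @param config A [trial_config()].
#' @param week1_dates Dates belonging to week 1; by default the first seven
#'   calendar days present.
#' @return Data.frame: `participant_id`, `week` (1/2), `n_hours`, `n_days`
#'   and the seven hourly-mean outcomes.
#' @export
build_weekly <- function(x, config = trial_config(), week1_dates = NULL) {
  win <- if ("timestamp" %in% names(x)) hour_windows(x, config) else x
  all_pids <- unique(win$participant_id)
  win <- grid_valid_windows(win, config)
  if (!nrow(win)) {
    out <- data.frame(participant_id = character(0), week = integer(0),
                      n_hours = integer(0), n_days = integer(0))
    for (cc in OUTCOMES) out[[cc]] <- numeric(0)
    attr(out, "flagged") <- all_pids
    return(out)
  }
  date <- as.Date(win$start, tz = "UTC")
  if (is.null(week1_dates)) {
    week1_dates <- seq(min(date), by = "day", length.out = 7L)
  }
  win$week <- ifelse(date %in% as.Date(week1_dates), 1L, 2L)
  win$date <- date
  dt <- data.table::as.data.table(win)
  out <- dt[, c(list(n_hours = .N, n_days = data.table::uniqueN(date)),
                lapply(.SD, mean)),
            by = .(participant_id, week), .SDcols = OUTCOMES]
  data.table::setorder(out, participant_id, week)
  out <- as.data.frame(out)
  cover <- aggregate(n_days ~ participant_id, out, min)
  low <- cover$participant_id[cover$n_days < 3]
  both <- table(out$participant_id)
  flagged <- sort(unique(c(
    low,
    names(both)[both < 2L],          # a whole week missing
    setdiff(all_pids, out$participant_id)
  )))
  attr(out, "flagged") <- flagged
  out
}
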