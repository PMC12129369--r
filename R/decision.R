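# Hourly prompt-decision engine. At each scheduled epoch (minute :34) the
# preceding hour window is compared against the participant's intervention
# criteria; both conditions are strict inequalities, so an hour exactly at a
# threshold never triggers a prompt.

#' Evaluate the prompt rule for one epoch
#'
#' @param window Hour-window rows (the decision window(s) ending one minute
#'   before the epoch).
#' @param criteria An `intervention_criteria` object.
#' @return Logical vector: `TRUE` where `distance_m < theta_distance` AND
#'   `sedentary_min > theta_sedentary` (both strict).
#' @export
evaluate_epoch <- function(window, criteria) {
  stopifnot(inherits(criteria, "intervention_criteria"))
  window$distance_m < criteria$theta_distance &
    window$sedentary_min > criteria$theta_sedentary
}

#' Draw prompt message ids
#'
#' Messages are chosen uniformly at random from the catalog, independently
#' across prompts, using R's global RNG stream.
#'
#' @param n Number of draws.
#' @param catalog Character vector of messages.
#' @return Integer vector of message ids in `0:(length(catalog) - 1)`.
#' @export
select_message <- function(n = 1L, catalog = default_messages()) {
  if (length(catalog) < 1L) {
    stop("configuration error: empty message catalog", call. = FALSE)
  }
  sample.int(length(catalog), n, replace = TRUE) - 1L
}

#' Replay the hourly decision rule over minute streams
#'
#' Iterates every participant over every scheduled epoch of the requested
#' dates, aggregates the preceding hour, skips hours failing the wear-time
#' validity check, and logs one intervention event per (participant, epoch)
#' whose window satisfies the criteria. Message ids are assigned to the
#' (participant, epoch)-sorted log from the configuration seed, so replays
#' are bit-identical.
#'
#' @param streams Minute-stream data.frame covering the decision period.
#' @param criteria Named list mapping `participant_id` to
#'   `intervention_criteria`; an entry named `"UIC"` (or any single shared
#'   entry) can be referenced by several participants via `criteria_for`.
#' @param config A [trial_config()].
#' @param dates Dates to evaluate; default all dates present in the streams.
#' @return Intervention-log data.frame with columns `participant_id`,
#'   `epoch`, `window_distance_m`, `window_sedentary_min`, `message_id`,
#'   sorted by participant then epoch. Attributes: `skipped_invalid` (number
#'   of on-grid windows skipped for low wear), `n_epochs` (epochs evaluated).
#' @export
run_trial <- function(streams, criteria, config = trial_config(), dates = NULL) {
  pids <- sort(unique(streams$participant_id))
  missing <- pids[!pids %in% names(criteria)]
  if (length(missing)) {
    stop("missing criteria for participant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(dates)) {
    dates <- sort(unique(as.Date(streams$timestamp, tz = "UTC")))
  }
  epochs <- do.call(c, lapply(dates, decision_grid, config = config))
  starts <- epochs - 3600
  win <- hour_windows(streams, config, starts = starts)
  win <- win[win$participant_id %in% pids, , drop = FALSE]

  valid <- valid_hour(win, config$min_wear_min)
  trig <- logical(nrow(win))
  for (pid in pids) {
    sel <- win$participant_id == pid
    trig[sel] <- evaluate_epoch(win[sel, , drop = FALSE], criteria[[pid]])
  }
  hit <- valid & trig
  log <- data.frame(
    participant_id = win$participant_id[hit],
    epoch = win$start[hit] + 3600,
    window_distance_m = win$distance_m[hit],
    window_sedentary_min = win$sedentary_min[hit]
  )
  log <- log[order(log$participant_id, log$epoch), , drop = FALSE]
  rownames(log) <- NULL
  set.seed(config$seed)
  log$message_id <- if (nrow(log)) select_message(nrow(log), config$messages) else integer(0)
  attr(log, "skipped_invalid") <- sum(!valid)
  attr(log, "n_epochs") <- nrow(win)
  log
}

#' Look up the criteria applying to a participant
#'
#' @param criteria Named criteria list (per-participant and/or `"UIC"`).
#' @param participant_id Participant identifier.
#' @return The participant's own entry if present, else the shared `"UIC"`
#'   entry.
#' @export
criteria_for <- function(criteria, participant_id) {
  if (participant_id %in% names(criteria)) return(criteria[[participant_id]])
  if ("UIC" %in% names(criteria)) return(criteria[["UIC"]])
  stop("no criteria for participant ", participant_id, call. = FALSE)
}

#' Read / write an intervention log as CSV
#'
#' Header: `participant_id,epoch,window_distance_m,window_sedentary_min,message_id`.
#'
#' @param log Intervention-log data.frame.
#' @param path File path.
#' @export
write_intervention_log <- function(log, path) {
  out <- data.table::data.table(
    participant_id = log$participant_id,
    epoch = format(log$epoch, "%Y-%m-%dT%H:%M", tz = "UTC"),
    window_distance_m = sprintf("%.17g", log$window_distance_m),
    window_sedentary_min = log$window_sedentary_min,
    message_id = log$message_id
  )
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervention_log
#' @export
read_intervention_log <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  dt[, epoch := as.POSIXct(epoch, tz = "UTC", format = "%Y-%m-%dT%H:%M")]
  as.data.frame(dt)
}

#' Intervention frequency summaries
#'
#' Per-participant prompts per day and the per-group mean, sample SD and
#' range, presented the way pilot JITAI reports usually quote them
#' ("mean (SD; range)").
#'
#' @param log Intervention log.
#' @param n_days Number of intervention days the rates are scaled by.
#' @param roster Participant roster (defines the population, including
#'   participants who never triggered a prompt).
#' @return List with `per_participant` (id, group, n_events, per_day) and
#'   `by_group` (group, mean, sd, min, max, formatted label).
#' @export
interventions_per_day <- function(log, n_days, roster) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  roster <- validate_roster(roster)
  extra <- setdiff(unique(log$participant_id), roster$participant_id)
  if (length(extra)) {
    stop("log has participants absent from roster: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(log$participant_id, levels = roster$participant_id))
  per <- data.frame(
    participant_id = roster$participant_id,
    group = roster$group,
    n_events = as.integer(counts),
    per_day = as.numeric(counts) / n_days
  )
  by_group <- do.call(rbind, lapply(split(per, per$group), function(d) {
    data.frame(
      group = d$group[1], n = nrow(d),
      mean = mean(d$per_day), sd = stats::sd(d$per_day),
      min = min(d$per_day), max = max(d$per_day)
    )
  }))
  by_group$label <- sprintf("%.1f (SD %.1f; range %.1f-%.1f)",
                            by_group$mean, by_group$sd, by_group$min, by_group$max)
  rownames(by_group) <- NULL
  list(per_participant = per, by_group = by_group)
}
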