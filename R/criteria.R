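# Intervention criteria: the (distance, sedentary) threshold pair that arms
# the hourly prompt rule. A prompt requires the past hour's distance to fall
# strictly below theta_distance AND its sedentary minutes to rise strictly
# above theta_sedentary. Thresholds are set one SD away from the mean so that
# ordinary fluctuation around the mean does not trigger prompts.

new_intervention_criteria <- function(theta_distance, theta_sedentary,
                                      provenance, n_hours_used) {
  stopifnot(theta_distance >= 0, theta_sedentary >= 0, theta_sedentary <= 60)
  structure(
    list(
      theta_distance = as.numeric(theta_distance),
      theta_sedentary = as.numeric(theta_sedentary),
      provenance = provenance,
      n_hours_used = as.integer(n_hours_used)
    ),
    class = "intervention_criteria"
  )
}

#' @export
print.intervention_criteria <- function(x, ...) {
  cat(sprintf("<intervention_criteria> %s: distance < %.1f m & sedentary > %.1f min (from %d hours)\n",
              x$provenance, x$theta_distance, x$theta_sedentary, x$n_hours_used))
  invisible(x)
}

insufficient_data <- function(msg) {
  stop(structure(class = c("jitaipa_insufficient_data", "error", "condition"),
                 list(message = msg, call = NULL)))
}

derive_thresholds <- function(distance, sedentary) {
  theta_d <- max(0, mean(distance) - stats::sd(distance))
  theta_s <- min(60, mean(sedentary) + stats::sd(sedentary))
  c(theta_d, theta_s)
}

#' Derive personalized intervention criteria (PIC)
#'
#' Personalized thresholds are computed from one participant's valid week-1
#' hour windows: the distance threshold is the hourly mean minus one sample
#' SD (floored at 0 m), the sedentary threshold the hourly mean plus one
#' sample SD (capped at 60 min).
#'
#' @param windows Valid week-1 hour windows for a single participant.
#' @return An `intervention_criteria` object.
#' @export
derive_pic <- function(windows) {
  pid <- unique(windows$participant_id)
  if (length(pid) != 1L) {
    stop("invalid input: derive_pic() expects one participant", call. = FALSE)
  }
  if (nrow(windows) < 2L) {
    insufficient_data(sprintf(
      "participant %s: need >= 2 valid hours to derive criteria (got %d)",
      pid, nrow(windows)))
  }
  th <- derive_thresholds(windows$distance_m, windows$sedentary_min)
  new_intervention_criteria(th[1], th[2], provenance = paste0("PIC:", pid),
                            n_hours_used = nrow(windows))
}

#' Derive uniform intervention criteria (UIC)
#'
#' Uniform thresholds apply the same mean +/- SD formulas to the pooled
#' person-hours of a reference cohort, yielding one threshold pair shared by
#' every participant in the UIC arm.
#'
#' @param windows Valid hour windows pooled over >= 2 reference participants.
#' @param label Provenance label for the reference cohort.
#' @return An `intervention_criteria` object.
#' @export
derive_uic <- function(windows, label = "UIC") {
  if (nrow(windows) < 2L || length(unique(windows$participant_id)) < 2L) {
    insufficient_data("need >= 2 hours from >= 2 participants to derive UIC")
  }
  th <- derive_thresholds(windows$distance_m, windows$sedentary_min)
  new_intervention_criteria(th[1], th[2], provenance = label,
                            n_hours_used = nrow(windows))
}

grid_valid_windows <- function(windows, config, dates = NULL) {
  h <- as.integer(format(windows$start, "%H", tz = "UTC"))
  m <- as.integer(format(windows$start, "%M", tz = "UTC"))
  on_grid <- m == config$decision_minute &
    h >= config$start_hour - 1L & h <= config$end_hour - 2L
  keep <- on_grid & valid_hour(windows, config$min_wear_min)
  if (!is.null(dates)) {
    keep <- keep & as.Date(windows$start, tz = "UTC") %in% as.Date(dates)
  }
  windows[keep, , drop = FALSE]
}

#' Derive a criteria map from streams or windows
#'
#' Orchestrates threshold derivation for a whole cohort: restricts to valid
#' hour windows on the decision grid (the same windows the prompt rule later
#' evaluates), optionally to given dates (e.g. week 1), then derives either
#' one PIC per participant or a single pooled UIC.
#'
#' @param x Minute-stream or hour-window data.frame.
#' @param config A [trial_config()].
#' @param mode `"pic"` (one criteria per participant) or `"uic"` (pooled).
#' @param dates Optional `Date` vector restricting which days are used.
#' @return Named list of `intervention_criteria` (per participant for PIC;
#'   a single `"UIC"` entry for UIC).
#' @export
derive_criteria <- function(x, config = trial_config(),
                            mode = c("pic", "uic"), dates = NULL) {
  mode <- match.arg(mode)
  windows <- if ("timestamp" %in% names(x)) hour_windows(x, config) else x
  windows <- grid_valid_windows(windows, config, dates)
  if (mode == "pic") {
    split_w <- split(windows, windows$participant_id)
    lapply(split_w, derive_pic)
  } else {
    list(UIC = derive_uic(windows))
  }
}

#' Render a criteria map as an integer-rounded report table
#'
#' @param criteria Named list of `intervention_criteria`.
#' @return Data.frame with columns `id`, `distance_m`, `sedentary_min`
#'   (thresholds rounded to integers for reporting; full precision is kept
#'   internally).
#' @export
criteria_table <- function(criteria) {
  data.frame(
    id = vapply(criteria, function(cr) cr$provenance, character(1)),
    distance_m = vapply(criteria, function(cr) round(cr$theta_distance), numeric(1)),
    sedentary_min = vapply(criteria, function(cr) round(cr$theta_sedentary), numeric(1)),
    row.names = NULL
  )
}

#' Read / write a criteria map as JSON
#'
#' Layout: `{"<id>": {"theta_distance_m", "theta_sedentary_min",
#' "n_hours_used"}}`.
#'
#' @param criteria Named list of `intervention_criteria`.
#' @param path File path.
#' @export
write_criteria <- function(criteria, path) {
  out <- lapply(criteria, function(cr) {
    list(theta_distance_m = cr$theta_distance,
         theta_sedentary_min = cr$theta_sedentary,
         n_hours_used = cr$n_hours_used,
         provenance = cr$provenance)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    cr <- raw[[nm]]
    new_intervention_criteria(cr$theta_distance_m, cr$theta_sedentary_min,
                              provenance = cr$provenance,
                              n_hours_used = cr$n_hours_used)
  })
  names(out) <- names(raw)
  out
}
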