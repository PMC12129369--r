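INTENSITY_LEVELS <- c("sedentary", "lightly", "fairly", "very")
WEAR_LEVELS <- c("worn", "sleep", "nonwear")

#' Validate a minute-level activity stream
#'
#' A minute stream is a data.frame with columns `participant_id`, `timestamp`
#' (minute resolution, naive local clock stored as UTC), `steps`,
#' `distance_m`, `calories_kcal`, `intensity` (`sedentary`/`lightly`/`fairly`/
#' `very`) and `wear` (`worn`/`sleep`/`nonwear`). Invariants checked:
#' non-negative counts, zero steps whenever the device is not worn, zero
#' distance whenever steps are zero, and unique minute-aligned timestamps
#' within each participant.
#'
#' @param stream A minute-stream data.frame.
#' @return `stream`, invisibly, if valid; otherwise an error.
#' @export
validate_minute_stream <- function(stream) {
  need <- c("participant_id", "timestamp", "steps", "distance_m",
            "calories_kcal", "intensity", "wear")
  miss <- setdiff(need, names(stream))
  if (length(miss)) {
    stop("minute stream is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(stream$timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  if (any(!stream$intensity %in% INTENSITY_LEVELS)) {
    stop("intensity must be one of ", paste(INTENSITY_LEVELS, collapse = "/"),
         call. = FALSE)
  }
  if (any(!stream$wear %in% WEAR_LEVELS)) {
    stop("wear must be one of ", paste(WEAR_LEVELS, collapse = "/"), call. = FALSE)
  }
  if (any(stream$steps < 0) || any(stream$distance_m < 0) ||
      any(stream$calories_kcal < 0)) {
    stop("steps, distance and calories must be non-negative", call. = FALSE)
  }
  if (any(stream$steps[stream$wear != "worn"] != 0)) {
    stop("steps must be 0 whenever wear != worn", call. = FALSE)
  }
  if (any(stream$distance_m[stream$steps == 0] != 0)) {
    stop("distance must be 0 whenever steps = 0", call. = FALSE)
  }
  if (any(as.numeric(stream$timestamp) %% 60 != 0)) {
    stop("timestamps must be minute-aligned", call. = FALSE)
  }
  dt <- data.table::as.data.table(stream)
  dup <- dt[, any(duplicated(timestamp)), by = participant_id]$V1
  if (any(dup)) {
    stop("timestamps within a participant's stream must be unique", call. = FALSE)
  }
  invisible(stream)
}

#' Read / write minute-level activity streams as CSV
#'
#' The CSV dialect has header
#' `participant_id,timestamp,steps,distance_m,calories_kcal,intensity,wear`
#' with ISO 8601 timestamps at minute precision. Continuous fields are written
#' with round-trip precision so that re-reading a stream reproduces every
#' hourly aggregate bit-identically.
#'
#' @param path File path.
#' @param stream A validated minute-stream data.frame.
#' @return `read_minute_stream()` returns the stream as a data.frame.
#' @export
read_minute_stream <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  dt[, timestamp := as.POSIXct(timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M")]
  dt[, steps := as.integer(steps)]
  out <- as.data.frame(dt)
  validate_minute_stream(out)
  out
}

#' @rdname read_minute_stream
#' @export
write_minute_stream <- function(stream, path) {
  validate_minute_stream(stream)
  out <- data.table::data.table(
    participant_id = stream$participant_id,
    timestamp = format(stream$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC"),
    steps = stream$steps,
    # %.17g guarantees doubles survive the text round trip unchanged
    distance_m = sprintf("%.17g", stream$distance_m),
    calories_kcal = sprintf("%.17g", stream$calories_kcal),
    intensity = stream$intensity,
    wear = stream$wear
  )
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Participant roster
#'
#' Reads or writes the roster CSV
#' (`participant_id,age,sex,height_cm,weight_kg,group`) and attaches the
#' derived BMI column (`weight / (height/100)^2`).
#'
#' @param path File path.
#' @param roster Roster data.frame.
#' @return `read_roster()` returns a data.frame with a `bmi` column.
#' @export
read_roster <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  roster <- as.data.frame(dt)
  validate_roster(roster)
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  keep <- c("participant_id", "age", "sex", "height_cm", "weight_kg", "group")
  data.table::fwrite(data.table::as.data.table(roster)[, keep, with = FALSE],
                     path, quote = FALSE)
  invisible(path)
}

#' @rdname read_roster
#' @export
validate_roster <- function(roster) {
  need <- c("participant_id", "age", "sex", "height_cm", "weight_kg", "group")
  miss <- setdiff(need, names(roster))
  if (length(miss)) {
    stop("roster is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!roster$sex %in% c("male", "female"))) {
    stop("sex must be male/female", call. = FALSE)
  }
  if (any(!roster$group %in% c("PIC", "UIC"))) {
    stop("group must be PIC/UIC", call. = FALSE)
  }
  bmi <- roster$weight_kg / (roster$height_cm / 100)^2
  if (!is.null(roster$bmi) && any(abs(roster$bmi - bmi) > 0.1)) {
    stop("bmi inconsistent with weight/height", call. = FALSE)
  }
  roster$bmi <- bmi
  roster
}
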