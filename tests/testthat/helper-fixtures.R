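# In-code fixtures shared across the suite.

# Minute rows with per-minute overrides; distance/calories default to a
# fixed stride and the linear calorie link unless given explicitly.
make_minutes <- function(pid = "P01",
                         start = as.POSIXct("2023-01-09 09:34", tz = "UTC"),
                         n = 60, steps = 0L, intensity = "sedentary",
                         wear = "worn", distance = NULL, calories = NULL,
                         stride = 0.75) {
  steps <- rep_len(as.integer(steps), n)
  intensity <- rep_len(intensity, n)
  wear <- rep_len(wear, n)
  steps[wear != "worn"] <- 0L
  if (is.null(distance)) distance <- steps * stride
  if (is.null(calories)) {
    calories <- ifelse(wear == "nonwear", 0, 1.1 + 0.04 * steps)
  }
  data.frame(
    participant_id = pid,
    timestamp = start + (seq_len(n) - 1) * 60,
    steps = steps,
    distance_m = rep_len(distance, n),
    calories_kcal = rep_len(calories, n),
    intensity = intensity,
    wear = wear
  )
}

# Hour-window rows on the decision grid (start hours 7:34, 8:34, ... by
# default), one participant, constant or per-window outcomes.
make_windows <- function(pid = "P01", distance, sedentary = 50,
                         date = as.Date("2023-01-09"), start_hours = NULL,
                         worn = 60) {
  n <- max(length(distance), length(sedentary))
  if (is.null(start_hours)) start_hours <- 7 + (seq_len(n) - 1) %% 14
  distance <- rep_len(distance, n)
  sedentary <- rep_len(sedentary, n)
  day_off <- (seq_len(n) - 1) %/% 14
  data.frame(
    participant_id = pid,
    start = as.POSIXct(date, tz = "UTC") + day_off * 86400 +
      start_hours * 3600 + 34 * 60,
    sedentary_min = sedentary,
    lightly_min = pmax(0, rep_len(worn, n) - sedentary),
    fairly_min = 0L, very_min = 0L,
    calories_kcal = 66 + 0.04 * distance / 0.75,
    steps = round(distance / 0.75),
    distance_m = distance,
    worn_min = rep_len(worn, n)
  )
}

# Small two-arm roster without collinearity between sex and group.
make_roster <- function(n = 6) {
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    age = 19 + seq_len(n) %% 4,
    sex = rep_len(c("male", "female", "female", "male"), n),
    height_cm = 160 + seq_len(n),
    weight_kg = 52 + seq_len(n),
    group = rep_len(c("PIC", "UIC"), n)
  )
}

# Pre/post pairs with exact group changes (zero noise unless sd > 0):
# y(before) = base, y(after) = base + d_pic or d_uic.
make_prepost <- function(roster, d_pic, d_uic, base = 100, sd = 0,
                         pairs_per_person = 1) {
  n <- nrow(roster)
  pid <- rep(roster$participant_id, each = 2 * pairs_per_person)
  phase <- factor(rep(c("before", "after"), n * pairs_per_person),
                  levels = c("before", "after"))
  grp <- rep(roster$group, each = 2 * pairs_per_person)
  y <- base + ifelse(phase == "after",
                     ifelse(grp == "PIC", d_pic, d_uic), 0)
  if (sd > 0) y <- y + rnorm(length(y), 0, sd)
  data.frame(
    participant_id = pid,
    epoch = as.POSIXct("2023-01-16 10:34", tz = "UTC") +
      rep(seq_len(pairs_per_person) - 1, each = 2) * 3600,
    phase = phase,
    distance_m = y
  )
}

# tiny quick-to-simulate study configuration
small_config <- function(seed = 1, n_days = 4L, ...) {
  cohort_config(n_participants = 6L, n_reference = 5L, n_days = n_days,
                seed = seed, ...)
}
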