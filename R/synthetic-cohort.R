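# Synthetic two-week cohort generator.
#
# Latent hourly activity lives on the :34-aligned window grid (the same grid
# the prompt rule evaluates), so an intervention response applied to "the
# next hour" lands exactly on one analysis window. Per participant i and
# waking window t:
#
#   a_ti = max(0, b_i * diurnal(hour) + e_ti) + response increment,
#   b_i ~ Normal(mu_distance, sigma_between^2),  e_ti ~ Normal(0, sigma_within^2)
#
# a_ti (metres) is realized as minute-level steps via the participant's
# stride, active minutes via the sedentary link (one active minute per
# `pace` metres), intensity classes via step-rate cut points, and calories
# via a linear link. All randomness is pre-drawn per participant from a
# child seed, so identical seeds give bit-identical cohorts and the
# closed-loop week-2 stream differs from the open-loop one only through the
# response increments.

#' Default diurnal multipliers
#'
#' Hour-of-day multipliers on baseline activity for window start hours 0-23:
#' a morning ramp, midday plateau and early-evening peak over the waking
#' hours, normalised to mean 1 so `mu_distance` keeps its interpretation as
#' the mean hourly distance. Non-waking hours are zero (unused; the sleep
#' window overrides them).
#'
#' @return Numeric vector of length 24.
#' @export
default_diurnal <- function() {
  d <- numeric(24)
  raw <- c(0.70, 0.85, 0.95, 1.00, 1.03, 1.00, 0.97, 0.96, 0.98,
           1.02, 1.08, 1.12, 1.10, 1.00, 0.85)
  d[7:21 + 1L] <- raw / mean(raw)
  d
}

#' Cohort simulation configuration
#'
#' Defines the study conditions for the synthetic two-week trial: cohort
#' sizes matching the study design (28 trial participants in a 1:1 PIC/UIC
#' split, a 47-person reference cohort for the uniform criteria), the
#' hierarchical activity model, the sedentary link, sleep/nonwear structure
#' and the next-hour behavioural response to prompts.
#'
#' @param n_participants Trial cohort size.
#' @param n_reference Reference cohort size (uniform-criteria derivation).
#' @param n_days Study length in days (week 1 = baseline, week 2 =
#'   intervention); must be >= 2.
#' @param seed Integer master seed; drives a per-participant child-seed
#'   sequence so changing the cohort size does not reshuffle earlier
#'   participants.
#' @param mu_distance Population mean hourly distance, m/h.
#' @param sigma_between SD of person baselines, m/h.
#' @param sigma_within SD of hourly noise around the person baseline, m/h.
#' @param sedentary_link List with `pace_m_per_min`: metres of hourly
#'   distance per active (non-sedentary) minute; sedentary minutes are
#'   60 minus the implied active minutes.
#' @param diurnal Length-24 multipliers by window start hour.
#' @param sleep_window `c(onset_hour, offset_hour)` crossing midnight;
#'   minutes inside it are recorded as `sleep`.
#' @param p_nonwear Probability that a waking hour window is nonwear.
#' @param response_pic,response_uic Next-hour latent activity increment
#'   (m/h) after a delivered prompt, by arm.
#' @param stride_coef Stride length as a fraction of height (stride_m =
#'   stride_coef x height).
#' @param start_date First study day.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 28L, n_reference = 47L,
                          n_days = 14L, seed = 1L,
                          mu_distance = 250, sigma_between = 30,
                          sigma_within = 100,
                          sedentary_link = list(pace_m_per_min = 15),
                          diurnal = default_diurnal(),
                          sleep_window = c(23L, 7L), p_nonwear = 0.05,
                          response_pic = 150, response_uic = 75,
                          stride_coef = 0.414,
                          start_date = as.Date("2023-01-09")) {
  if (n_days < 2L) stop("configuration error: n_days must be >= 2", call. = FALSE)
  if (n_participants < 2L || n_reference < 2L) {
    stop("configuration error: cohort sizes must be >= 2", call. = FALSE)
  }
  if (sigma_between < 0 || sigma_within < 0) {
    stop("configuration error: SDs must be >= 0", call. = FALSE)
  }
  if (p_nonwear < 0 || p_nonwear > 1) {
    stop("configuration error: p_nonwear must lie in [0, 1]", call. = FALSE)
  }
  if (length(diurnal) != 24L || any(diurnal < 0)) {
    stop("configuration error: diurnal must be 24 non-negative multipliers",
         call. = FALSE)
  }
  if (is.null(sedentary_link$pace_m_per_min) || sedentary_link$pace_m_per_min <= 0) {
    stop("configuration error: sedentary_link$pace_m_per_min must be > 0",
         call. = FALSE)
  }
  if (length(sleep_window) != 2L || sleep_window[1] <= sleep_window[2]) {
    stop("configuration error: sleep_window must be c(onset, offset) crossing midnight",
         call. = FALSE)
  }
  if (mu_distance < 0 || stride_coef <= 0) {
    stop("configuration error: mu_distance and stride_coef must be positive",
         call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_reference = as.integer(n_reference),
      n_days = as.integer(n_days), seed = as.integer(seed),
      mu_distance = mu_distance, sigma_between = sigma_between,
      sigma_within = sigma_within, sedentary_link = sedentary_link,
      diurnal = diurnal, sleep_window = as.numeric(sleep_window),
      p_nonwear = p_nonwear,
      response_pic = response_pic, response_uic = response_uic,
      stride_coef = stride_coef, start_date = as.Date(start_date)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n=%d (+%d reference), %d days, seed %d\n  activity ~ max(0, N(%g, %g^2 between) + N(0, %g^2 within)) m/h, response PIC +%g / UIC +%g m/h\n",
    x$n_participants, x$n_reference, x$n_days, x$seed,
    x$mu_distance, x$sigma_between, x$sigma_within,
    x$response_pic, x$response_uic
  ))
  invisible(x)
}

# deterministic child seed; stream 0 = trial cohort, 1 = reference,
# 2 = group assignment; always < 2^31
child_seed <- function(seed, stream, i) {
  as.integer(((as.double(seed) %% 1e6) * 1009 + stream * 499979 + i * 7919) %%
               2147483646) + 1L
}

# waking window start hours: :34-aligned windows lying fully outside the
# sleep interval [onset, 24) U [0, offset)
waking_slots <- function(config, trial) {
  dm <- trial$decision_minute / 60
  h <- 0:23
  h[h + dm >= config$sleep_window[2] & h + 1 + dm <= config$sleep_window[1]]
}

# fast data.frame constructor for hot paths (skips data.frame()'s checks)
fast_df <- function(lst, n) {
  structure(lst, class = "data.frame", row.names = c(NA_integer_, -n))
}

# All randomness one participant's activity will ever need, in a fixed draw
# order; step weights are Exp(1) (drawn as -log(U)). Minute-placement draws
# live on a separate child seed consumed only at materialisation time, so
# hourly aggregates and decisions are unaffected by whether minutes are
# materialised.
participant_draws <- function(cseed, config, n_slots) {
  set.seed(cseed)
  sex <- sample(c("male", "female"), 1L)
  age <- sample(18:23, 1L)
  height <- round(rnorm(1, if (sex == "male") 171 else 158,
                        if (sex == "male") 5.5 else 5.0), 1)
  bmi_t <- rnorm(1, 20.5, 1.8)
  weight <- round(bmi_t * (height / 100)^2, 1)
  nw <- n_slots * config$n_days
  b <- rnorm(1, config$mu_distance, config$sigma_between)
  e <- matrix(rnorm(nw, 0, config$sigma_within), n_slots, config$n_days)
  u_nw <- matrix(runif(nw), n_slots, config$n_days)
  gam <- matrix(-log(runif(60L * nw)), 60L, nw)
  list(sex = sex, age = age, height = height, weight = weight, b = b,
       e = e, u_nw = u_nw, gam = gam,
       stride = round(config$stride_coef * height / 100, 3))
}

# Realize worn hour windows from latent activity.
#   a: latent m/h per window; gam: 60 x length(a) step-weight draws;
#   stride: m/step (scalar or per window); pace: m per active minute.
# Steps are split over the active minutes proportionally to the gamma
# weights with an exact-sum correction (the remainder goes to the
# largest-weight minute), so hourly steps always sum to round(a / stride).
realize_windows <- function(a, gam, stride, pace) {
  n <- length(a)
  empty <- list(agg = NULL, s = integer(0), grp = integer(0), m = integer(0))
  if (n == 0L) return(empty)
  stride <- rep_len(stride, n)
  S <- as.integer(round(a / stride))
  m <- pmin(60L, as.integer(round(a / pace)))
  m[S > 0L & m < 1L] <- 1L
  m[S == 0L] <- 0L
  grp <- rep.int(seq_len(n), m)
  s <- integer(length(grp))
  sed0 <- integer(n); li <- integer(n); fa <- integer(n); ve <- integer(n)
  if (length(grp)) {
    gidx <- which(m > 0L)
    rows <- sequence(m[gidx])
    w <- gam[rows + (grp - 1L) * 60L]
    wsum <- as.numeric(rowsum(w, grp))
    p <- w / wsum[match(grp, gidx)]
    base <- as.integer(floor(S[grp] * p))
    rem <- S[gidx] - as.integer(rowsum(base, grp))
    o <- order(grp, -w)
    first <- o[!duplicated(grp[o])]
    s <- base
    s[first] <- s[first] + rem
    sed0[gidx] <- as.integer(rowsum((s == 0L) + 0L, grp))
    li[gidx] <- as.integer(rowsum((s >= 1L & s < 80L) + 0L, grp))
    fa[gidx] <- as.integer(rowsum((s >= 80L & s < 120L) + 0L, grp))
    ve[gidx] <- as.integer(rowsum((s >= 120L) + 0L, grp))
  }
  agg <- fast_df(list(
    sedentary_min = 60L - m + sed0,
    lightly_min = li, fairly_min = fa, very_min = ve,
    calories_kcal = 66 + 0.04 * S,
    steps = S,
    distance_m = S * stride,
    worn_min = rep.int(60L, n)
  ), n)
  list(agg = agg, s = s, grp = grp, m = m)
}

zero_window <- function(n) {
  fast_df(list(
    sedentary_min = rep.int(0L, n), lightly_min = rep.int(0L, n),
    fairly_min = rep.int(0L, n), very_min = rep.int(0L, n),
    calories_kcal = rep.int(0, n), steps = rep.int(0L, n),
    distance_m = rep.int(0, n), worn_min = rep.int(0L, n)
  ), n)
}

# open-loop realization of one participant over the given days
open_loop_participant <- function(pd, config, slots, days) {
  ns <- length(slots)
  dcol <- rep(days, each = ns)
  kcol <- rep(seq_len(ns), times = length(days))
  scol <- slots[kcol]
  cols <- (dcol - 1L) * ns + kcol
  a <- pmax(0, pd$b * config$diurnal[scol + 1L] + pd$e[cols])
  worn <- pd$u_nw[cols] >= config$p_nonwear
  res <- realize_windows(a[worn], pd$gam[, cols[worn], drop = FALSE],
                         pd$stride, config$sedentary_link$pace_m_per_min)
  agg <- zero_window(length(a))
  if (any(worn)) agg[worn, ] <- res$agg
  win <- cbind(fast_df(list(day = dcol, k = kcol, slot = scol, worn = worn),
                       length(a)), agg)
  wsub <- which(worn)
  active <- fast_df(list(
    day = dcol[wsub][res$grp], k = kcol[wsub][res$grp],
    rank = sequence(res$m), s = res$s
  ), length(res$grp))
  list(win = win, active = active)
}

window_start_time <- function(start_date, day, slot, decision_minute) {
  as.POSIXct(start_date, tz = "UTC") + (day - 1) * 86400 +
    slot * 3600 + decision_minute * 60
}

# expand a participant's realized windows into the full minute stream;
# place_seed drives the (aggregate-neutral) placement of active minutes
materialize_participant <- function(pid, pd, win, active, config, trial,
                                    place_seed) {
  nmin <- config$n_days * 1440L
  wear <- rep("sleep", nmin)
  steps <- integer(nmin)
  cal <- rep(1.1, nmin)
  dm <- trial$decision_minute
  ns <- nrow(win) / config$n_days # slots per day
  set.seed(place_seed)
  u_place <- matrix(runif(60L * ns * config$n_days), 60L)
  base <- (win$day - 1L) * 1440L + win$slot * 60L + dm # 0-based window start
  wi <- which(win$worn)
  if (length(wi)) {
    pos <- as.vector(outer(1:60, base[wi], "+")) # 1-based minute indices
    wear[pos] <- "worn"
    cal[pos] <- 1.1
  }
  ni <- which(!win$worn)
  if (length(ni)) {
    pos <- as.vector(outer(1:60, base[ni], "+"))
    wear[pos] <- "nonwear"
    cal[pos] <- 0
  }
  if (nrow(active)) {
    act_by <- split(active$s, (active$day - 1L) * ns + active$k)
    for (key in names(act_by)) {
      col <- as.integer(key)
      sv <- act_by[[key]]
      u <- u_place[, col]
      mpos <- order(u)[seq_along(sv)]
      d <- (col - 1L) %/% ns + 1L
      k <- col - (d - 1L) * ns
      b0 <- (d - 1L) * 1440L + win$slot[win$day == d & win$k == k] * 60L + dm
      steps[b0 + mpos] <- sv
    }
  }
  worn_mask <- wear == "worn"
  cal[worn_mask] <- 1.1 + 0.04 * steps[worn_mask]
  intensity <- rep("sedentary", nmin)
  intensity[worn_mask & steps >= 1L & steps < 80L] <- "lightly"
  intensity[worn_mask & steps >= 80L & steps < 120L] <- "fairly"
  intensity[worn_mask & steps >= 120L] <- "very"
  data.frame(
    participant_id = pid,
    timestamp = as.POSIXct(config$start_date, tz = "UTC") +
      (seq_len(nmin) - 1) * 60,
    steps = steps,
    distance_m = steps * pd$stride,
    calories_kcal = cal,
    intensity = intensity,
    wear = wear
  )
}

assemble_windows <- function(pids, wins, config, trial) {
  out <- data.table::rbindlist(Map(function(pid, w) {
    w$participant_id <- pid
    w
  }, pids, wins))
  out[, start := window_start_time(config$start_date, day, slot,
                                   trial$decision_minute)]
  cols <- c("participant_id", "start", "sedentary_min", "lightly_min",
            "fairly_min", "very_min", "calories_kcal", "steps",
            "distance_m", "worn_min")
  data.table::setorder(out, participant_id, start)
  as.data.frame(out[, cols, with = FALSE])
}

generate_arm <- function(config, trial, ids, stream_tag, keep_minutes) {
  slots <- waking_slots(config, trial)
  need <- seq.int(trial$start_hour - 1L, trial$end_hour - 1L)
  if (!all(need %in% slots)) {
    stop("configuration error: the decision schedule extends into the sleep window",
         call. = FALSE)
  }
  n <- length(ids)
  pds <- lapply(seq_len(n), function(i) {
    participant_draws(child_seed(config$seed, stream_tag, i), config,
                      length(slots))
  })
  ol <- lapply(pds, open_loop_participant, config = config, slots = slots,
               days = seq_len(config$n_days))
  windows <- assemble_windows(ids, lapply(ol, `[[`, "win"), config, trial)
  streams <- NULL
  if (keep_minutes) {
    streams <- do.call(rbind, lapply(seq_len(n), function(i) {
      materialize_participant(ids[i], pds[[i]], ol[[i]]$win, ol[[i]]$active,
                              config, trial,
                              child_seed(config$seed, stream_tag + 10L, i))
    }))
  }
  list(pds = pds, windows = windows, streams = streams, slots = slots)
}

cohort_roster <- function(config, ids, pds) {
  set.seed(child_seed(config$seed, 2L, 0L))
  group <- sample(rep_len(c("PIC", "UIC"), length(ids)))
  validate_roster(data.frame(
    participant_id = ids,
    age = vapply(pds, `[[`, numeric(1), "age"),
    sex = vapply(pds, `[[`, character(1), "sex"),
    height_cm = vapply(pds, `[[`, numeric(1), "height"),
    weight_kg = vapply(pds, `[[`, numeric(1), "weight"),
    group = group
  ))
}

#' Generate an open-loop synthetic cohort
#'
#' Simulates the trial cohort without any prompt being delivered (the
#' response model never fires): minute streams, a roster with a seeded 1:1
#' PIC/UIC assignment, and the ground-truth person parameters. Identical
#' configurations and seeds give bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param trial A [trial_config()]; defines the waking/decision grid.
#' @param keep_minutes Materialise minute-level streams (set `FALSE` to keep
#'   only hourly windows, e.g. inside simulation studies).
#' @return List of class `jitaipa_cohort`: `roster`, `streams` (minute
#'   records or `NULL`), `windows` (hourly aggregates on the waking grid),
#'   `truth` (participant, baseline m/h, response increment m/h, group).
#' @export
generate_cohort <- function(config = cohort_config(),
                            trial = trial_config(seed = config$seed),
                            keep_minutes = TRUE) {
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  arm <- generate_arm(config, trial, ids, 0L, keep_minutes)
  roster <- cohort_roster(config, ids, arm$pds)
  truth <- data.frame(
    participant_id = ids,
    baseline_m_per_h = vapply(arm$pds, `[[`, numeric(1), "b"),
    response_m_per_h = ifelse(roster$group == "PIC", config$response_pic,
                              config$response_uic),
    group = roster$group
  )
  structure(list(roster = roster, streams = arm$streams,
                 windows = arm$windows, truth = truth,
                 config = config, trial = trial),
            class = "jitaipa_cohort")
}

#' Generate the reference cohort for uniform criteria
#'
#' Same generative model as [generate_cohort()] with `n_reference`
#' participants and no prompts ever delivered; its pooled person-hours are
#' the input to [derive_uic()].
#'
#' @inheritParams generate_cohort
#' @return List of class `jitaipa_cohort` (no roster groups; ids `R01`...).
#' @export
generate_reference <- function(config = cohort_config(),
                               trial = trial_config(seed = config$seed),
                               keep_minutes = TRUE) {
  ids <- sprintf("R%02d", seq_len(config$n_reference))
  arm <- generate_arm(config, trial, ids, 1L, keep_minutes)
  structure(list(streams = arm$streams, windows = arm$windows,
                 config = config, trial = trial),
            class = "jitaipa_cohort")
}

#' Simulate the full closed-loop trial
#'
#' Runs the complete study: generates the reference cohort and derives the
#' uniform criteria from its pooled valid decision-grid hours; generates
#' week 1 of the trial cohort and derives personalized criteria for the PIC
#' arm; then simulates week 2 hour by hour, delivering prompts at scheduled
#' epochs whose decision window meets the applicable criteria and adding the
#' arm's response increment to the following hour's latent activity.
#' Message ids are assigned from the trial seed over the sorted log, so a
#' [run_trial()] replay on the emitted streams reproduces the log exactly.
#'
#' @inheritParams generate_cohort
#' @return List of class `jitaipa_study`: `roster`, `truth`, `criteria`
#'   (named per participant, plus `"UIC"`), `log` (intervention events),
#'   `windows`, `streams` (or `NULL`), `reference_windows`, `week1_dates`,
#'   `week2_dates`, `config`, `trial`.
#' @export
simulate_trial <- function(config = cohort_config(),
                           trial = trial_config(seed = config$seed),
                           keep_minutes = TRUE) {
  slots <- waking_slots(config, trial)
  ns <- length(slots)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  n <- length(ids)
  week1 <- seq_len(min(7L, config$n_days - 1L))
  week2 <- seq.int(max(week1) + 1L, config$n_days)
  week1_dates <- config$start_date + week1 - 1L
  week2_dates <- config$start_date + week2 - 1L

  ref <- generate_reference(config, trial, keep_minutes = FALSE)
  uic <- derive_uic(grid_valid_windows(ref$windows, trial))

  pds <- lapply(seq_len(n), function(i) {
    participant_draws(child_seed(config$seed, 0L, i), config, ns)
  })
  roster <- cohort_roster(config, ids, pds)
  pic_arm <- roster$group == "PIC"
  response <- ifelse(pic_arm, config$response_pic, config$response_uic)
  strides <- vapply(pds, `[[`, numeric(1), "stride")
  pace <- config$sedentary_link$pace_m_per_min

  # week 1: open loop
  ol <- lapply(pds, open_loop_participant, config = config, slots = slots,
               days = week1)
  w1_windows <- assemble_windows(ids, lapply(ol, `[[`, "win"), config, trial)

  criteria <- vector("list", n)
  names(criteria) <- ids
  w1_valid <- grid_valid_windows(w1_windows, trial, dates = week1_dates)
  for (i in seq_len(n)) {
    criteria[[i]] <- if (pic_arm[i]) {
      derive_pic(w1_valid[w1_valid$participant_id == ids[i], , drop = FALSE])
    } else {
      uic
    }
  }

  # week 2: closed loop, slot by slot across participants
  dws_last <- trial$end_hour - 2L # last decision-window start hour
  theta_d <- vapply(criteria, `[[`, numeric(1), "theta_distance")
  theta_s <- vapply(criteria, `[[`, numeric(1), "theta_sedentary")
  b_all <- vapply(pds, `[[`, numeric(1), "b")
  e_all <- vapply(pds, function(pd) as.vector(pd$e), numeric(ns * config$n_days))
  u_all <- vapply(pds, function(pd) as.vector(pd$u_nw), numeric(ns * config$n_days))
  gam_all <- vapply(pds, function(pd) as.vector(pd$gam),
                    numeric(60L * ns * config$n_days))
  w2_win <- vector("list", length(week2) * ns)
  w2_act <- vector("list", length(week2) * ns)
  events <- vector("list", length(week2) * ns)
  ii <- 0L
  for (d in week2) {
    incr <- numeric(n)
    for (k in seq_len(ns)) {
      ii <- ii + 1L
      h <- slots[k]
      col <- (d - 1L) * ns + k
      a <- pmax(0, b_all * config$diurnal[h + 1L] + e_all[col, ]) + incr
      worn <- u_all[col, ] >= config$p_nonwear
      gam_k <- matrix(gam_all[((col - 1L) * 60L + 1L):(col * 60L), ], 60L)
      res <- realize_windows(a[worn], gam_k[, worn, drop = FALSE],
                             strides[worn], pace)
      agg <- zero_window(n)
      if (any(worn)) agg[worn, ] <- res$agg
      w2_win[[ii]] <- cbind(
        fast_df(list(pid = ids, day = rep.int(d, n), k = rep.int(k, n),
                     slot = rep.int(h, n), worn = worn), n), agg)
      wsub <- which(worn)
      if (length(res$grp)) {
        nact <- length(res$grp)
        w2_act[[ii]] <- fast_df(list(
          pid = ids[wsub][res$grp], day = rep.int(d, nact),
          k = rep.int(k, nact), rank = sequence(res$m), s = res$s), nact)
      }
      if (h >= trial$start_hour - 1L && h <= dws_last) {
        trig <- worn & agg$distance_m < theta_d & agg$sedentary_min > theta_s
        incr <- ifelse(trig, response, 0)
        if (any(trig)) {
          events[[ii]] <- data.frame(
            participant_id = ids[trig],
            epoch = window_start_time(config$start_date, d, h + 1L,
                                      trial$decision_minute),
            window_distance_m = agg$distance_m[trig],
            window_sedentary_min = agg$sedentary_min[trig])
        }
      } else {
        incr <- numeric(n)
      }
    }
  }

  w2_all <- data.table::rbindlist(w2_win)
  log <- data.table::rbindlist(events[!vapply(events, is.null, logical(1))])
  log <- as.data.frame(log)
  log <- log[order(log$participant_id, log$epoch), , drop = FALSE]
  rownames(log) <- NULL
  set.seed(trial$seed)
  log$message_id <- if (nrow(log)) select_message(nrow(log), trial$messages) else integer(0)

  w2_by_pid <- split(as.data.frame(w2_all), w2_all$pid)
  w2_windows <- assemble_windows(
    names(w2_by_pid),
    lapply(w2_by_pid, function(w) w[, setdiff(names(w), "pid")]),
    config, trial)
  windows <- rbind(w1_windows, w2_windows)
  windows <- windows[order(windows$participant_id, windows$start), , drop = FALSE]
  rownames(windows) <- NULL

  streams <- NULL
  if (keep_minutes) {
    act2 <- as.data.frame(data.table::rbindlist(w2_act))
    if (!nrow(act2)) {
      act2 <- data.frame(pid = character(0), day = integer(0),
                         k = integer(0), rank = integer(0), s = integer(0))
    }
    streams <- do.call(rbind, lapply(seq_len(n), function(i) {
      win_i <- rbind(
        ol[[i]]$win,
        {
          w <- as.data.frame(w2_all[w2_all$pid == ids[i]])
          w[, setdiff(names(w), "pid")]
        })
      act_i <- rbind(ol[[i]]$active,
                     act2[act2$pid == ids[i],
                          c("day", "k", "rank", "s"), drop = FALSE])
      materialize_participant(ids[i], pds[[i]], win_i, act_i, config, trial,
                              child_seed(config$seed, 10L, i))
    }))
  }

  truth <- data.frame(
    participant_id = ids,
    baseline_m_per_h = vapply(pds, `[[`, numeric(1), "b"),
    response_m_per_h = response,
    group = roster$group
  )

  structure(
    list(roster = roster, truth = truth, criteria = c(criteria, list(UIC = uic)),
         log = log, windows = windows, streams = streams,
         reference_windows = ref$windows,
         week1_dates = week1_dates, week2_dates = week2_dates,
         config = config, trial = trial),
    class = "jitaipa_study"
  )
}

#' @export
print.jitaipa_study <- function(x, ...) {
  cat(sprintf(
    "<jitaipa_study> %d participants (%d PIC / %d UIC), %d days, %d prompts delivered\n",
    nrow(x$roster), sum(x$roster$group == "PIC"), sum(x$roster$group == "UIC"),
    x$config$n_days, nrow(x$log)))
  invisible(x)
}

#' Write ground-truth parameters as JSON
#'
#' @param truth Truth data.frame from [generate_cohort()] / [simulate_trial()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    list(baseline_m_per_h = truth$baseline_m_per_h[i],
         response_m_per_h = truth$response_m_per_h[i],
         group = truth$group[i])
  })
  names(out) <- truth$participant_id
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
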