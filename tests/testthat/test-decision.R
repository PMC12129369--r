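uic_139_52 <- function() {
  derive_uic(rbind(make_windows(pid = "R1", distance = 139, sedentary = 52),
                   make_windows(pid = "R2", distance = 139, sedentary = 52)))
}

test_that("the prompt rule is a strict double inequality", {
  cr <- uic_139_52() # thresholds (139 m, 52 min)
  expect_true(evaluate_epoch(make_windows(distance = 100, sedentary = 55), cr))
  # boundary: equality on either margin never triggers
  expect_false(evaluate_epoch(make_windows(distance = 139, sedentary = 55), cr))
  expect_false(evaluate_epoch(make_windows(distance = 100, sedentary = 52), cr))
  # an utterly inactive hour triggers against any interior thresholds
  expect_true(evaluate_epoch(make_windows(distance = 0, sedentary = 60), cr))
})

full_day_sedentary <- function(pid = "P01", date = as.Date("2023-01-16")) {
  make_minutes(pid = pid, start = as.POSIXct(paste(date, "00:00"), tz = "UTC"),
               n = 1440, steps = 0, intensity = "sedentary")
}

test_that("always-on criteria deliver one prompt per scheduled epoch", {
  st <- full_day_sedentary()
  always <- list(P01 = structure(
    list(theta_distance = 1e9, theta_sedentary = 0, provenance = "UIC",
         n_hours_used = 2L), class = "intervention_criteria"))
  log <- run_trial(st, always, dates = as.Date("2023-01-16"))
  expect_equal(nrow(log), 14)
  expect_equal(format(log$epoch[1], "%H:%M"), "08:34")
  expect_equal(format(log$epoch[14], "%H:%M"), "21:34")
  # impossible criteria: distance < 0 can never hold
  never <- list(P01 = structure(
    list(theta_distance = 0, theta_sedentary = 0, provenance = "UIC",
         n_hours_used = 2L), class = "intervention_criteria"))
  expect_equal(nrow(run_trial(st, never, dates = as.Date("2023-01-16"))), 0)
})

test_that("event counts are monotone in the thresholds", {
  st <- simulate_trial(small_config(seed = 31), keep_minutes = FALSE)
  mk <- function(d, s) {
    crs <- lapply(st$roster$participant_id, function(p) structure(
      list(theta_distance = d, theta_sedentary = s, provenance = "UIC",
           n_hours_used = 2L), class = "intervention_criteria"))
    names(crs) <- st$roster$participant_id
    crs
  }
  count <- function(d, s) {
    w <- st$windows
    n <- 0L
    for (p in st$roster$participant_id) {
      ww <- w[w$participant_id == p & valid_hour(w, 50), ]
      n <- n + sum(evaluate_epoch(ww, mk(d, s)[[p]]))
    }
    n
  }
  ds <- c(50, 150, 250, 400)
  cnt_d <- vapply(ds, count, integer(1), s = 40)
  expect_true(all(diff(cnt_d) >= 0)) # raising theta_distance never loses events
  ss <- c(30, 45, 55, 59)
  cnt_s <- vapply(ss, count, integer(1), d = 250)
  expect_true(all(diff(cnt_s) <= 0)) # raising theta_sedentary never adds events
})

test_that("no event falls outside the schedule and replays are bit-identical", {
  st <- simulate_trial(small_config(seed = 32), keep_minutes = TRUE)
  hrs <- as.integer(format(st$log$epoch, "%H"))
  mins <- as.integer(format(st$log$epoch, "%M"))
  expect_true(all(mins == 34))
  expect_true(all(hrs >= 8 & hrs <= 21))
  expect_true(all(as.Date(st$log$epoch, tz = "UTC") %in% st$week2_dates))
  # at most one event per participant-epoch
  expect_false(any(duplicated(paste(st$log$participant_id, st$log$epoch))))
  # replaying streams + criteria + seed reproduces the closed-loop log
  replay <- run_trial(st$streams, st$criteria, st$trial, dates = st$week2_dates)
  expect_identical(replay$participant_id, st$log$participant_id)
  expect_identical(replay$epoch, st$log$epoch)
  expect_identical(replay$message_id, st$log$message_id)
  expect_equal(replay$window_distance_m, st$log$window_distance_m)
  # and the run itself is reproducible
  st2 <- simulate_trial(small_config(seed = 32), keep_minutes = FALSE)
  expect_identical(st2$log, st$log)
})

test_that("messages are drawn uniformly and reproducibly from the catalog", {
  set.seed(1)
  ids <- select_message(10000)
  freq <- tabulate(ids + 1L, 5) / 10000
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(freq - 0.2) < 5 * se))
  expect_true(all(select_message(100, catalog = "only one") == 0))
  expect_error(select_message(1, catalog = character(0)), "configuration")
  set.seed(99); a <- select_message(50)
  set.seed(99); b <- select_message(50)
  expect_identical(a, b)
})

test_that("interventions per day summarise counts over the roster", {
  ros <- make_roster(4)
  empty <- data.frame(participant_id = character(0),
                      epoch = as.POSIXct(character(0), tz = "UTC"))
  out <- interventions_per_day(empty, 7, ros)
  expect_true(all(out$per_participant$per_day == 0))
  log <- data.frame(
    participant_id = rep("P01", 14),
    epoch = as.POSIXct("2023-01-16 10:34", tz = "UTC") + (1:14) * 86400)
  out <- interventions_per_day(log, 7, ros)
  expect_equal(out$per_participant$per_day[out$per_participant$participant_id == "P01"], 2)
  expect_match(out$by_group$label[out$by_group$group == "PIC"],
               "^2?\\d?\\.\\d \\(SD \\d+\\.\\d; range")
  stray <- data.frame(participant_id = "ZZ",
                      epoch = as.POSIXct("2023-01-16 10:34", tz = "UTC"))
  expect_error(interventions_per_day(stray, 7, ros), "absent")
})

test_that("run_trial demands criteria for every participant", {
  st <- full_day_sedentary()
  expect_error(run_trial(st, list(), dates = as.Date("2023-01-16")),
               "missing criteria.*P01")
})
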