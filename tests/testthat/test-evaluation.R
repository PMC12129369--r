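test_that("pre/post pairs align on the decision and following hours", {
  w <- rbind(
    make_windows(distance = 10, sedentary = 55, start_hours = 9),  # 09:34
    make_windows(distance = 200, sedentary = 30, start_hours = 10), # 10:34
    make_windows(distance = 300, sedentary = 20, start_hours = 11)) # 11:34
  log <- data.frame(participant_id = "P01",
                    epoch = as.POSIXct("2023-01-09 10:34", tz = "UTC"))
  pp <- build_prepost(log, w)
  expect_equal(nrow(pp), 2)
  expect_equal(pp$distance_m[pp$phase == "before"], 10)
  expect_equal(pp$distance_m[pp$phase == "after"], 200)
  # consecutive events: the earlier event's after-hour is the later's before-hour
  log2 <- rbind(log, data.frame(participant_id = "P01",
                                epoch = as.POSIXct("2023-01-09 11:34", tz = "UTC")))
  pp2 <- build_prepost(log2, w)
  expect_equal(nrow(pp2), 4)
  expect_equal(pp2$distance_m[pp2$phase == "before" &
                                pp2$epoch == log2$epoch[2]], 200)
  # empty log -> empty dataset
  empty <- build_prepost(log[0, ], w)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "dropped"), 0L)
})

test_that("pairs with unusable after-hours are dropped and counted", {
  w <- rbind(make_windows(distance = 10, sedentary = 55, start_hours = 9),
             make_windows(distance = 0, sedentary = 0, start_hours = 10,
                          worn = 20)) # low-wear after hour
  log <- data.frame(participant_id = "P01",
                    epoch = as.POSIXct("2023-01-09 10:34", tz = "UTC"))
  pp <- build_prepost(log, w)
  expect_equal(nrow(pp), 0)
  expect_equal(attr(pp, "dropped"), 1L)
  # no stream coverage at all for the after hour
  pp2 <- build_prepost(log, w[1, ])
  expect_equal(attr(pp2, "dropped"), 1L)
})

test_that("weekly means average valid grid hours and reflect post-prompt gains", {
  # week 1: 14 grid hours/day at 200 m; week 2: 4 of 14 hours at 300 m
  mk_day <- function(day, boosted) {
    d <- rep(200, 14)
    if (boosted) d[3:6] <- 300
    w <- make_windows(distance = d, sedentary = 45,
                      start_hours = 7:20,
                      date = as.Date("2023-01-09") + day - 1)
    w
  }
  w <- do.call(rbind, c(lapply(1:7, mk_day, boosted = FALSE),
                        lapply(8:14, mk_day, boosted = TRUE)))
  wk <- build_weekly(w)
  expect_equal(nrow(wk), 2)
  expect_equal(wk$distance_m[wk$week == 1], 200)
  expect_equal(wk$distance_m[wk$week == 2] - wk$distance_m[wk$week == 1],
               4 / 14 * 100, tolerance = 1e-12)
  expect_equal(wk$n_hours, c(98, 98))
  expect_length(attr(wk, "flagged"), 0)
})

test_that("all-invalid streams yield an empty flagged weekly dataset", {
  w <- make_windows(distance = rep(100, 20), worn = 0)
  wk <- build_weekly(w)
  expect_equal(nrow(wk), 0)
  expect_equal(attr(wk, "flagged"), "P01")
})

test_that("zero-noise two-group data recover the change parameters exactly", {
  ros <- make_roster(6)
  pp <- make_prepost(ros, d_pic = 50, d_uic = 20)
  fit <- fit_mlm(pp, "distance_m", ros, time_var = "phase",
                 random_slope = "fixed")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$effect)
  expect_equal(est[["gamma10"]], 20, tolerance = 1e-6) # reference (UIC) change
  expect_equal(est[["gamma11"]], 30, tolerance = 1e-6) # PIC excess
  # cell means reproduce the constructed group x phase means
  cells <- cell_means(fit)
  pick <- function(g, t) cells$mean[cells$group == g & cells$time == t]
  expect_equal(pick("UIC", "before"), 100, tolerance = 1e-6)
  expect_equal(pick("UIC", "after"), 120, tolerance = 1e-6)
  expect_equal(pick("PIC", "after") - pick("PIC", "before"), 50,
               tolerance = 1e-6)
  gc <- group_contrast(fit)
  expect_equal(gc$estimate, gc$from_cells, tolerance = 1e-8)
})

test_that("with one observation per phase the fit matches the OLS oracle", {
  set.seed(17)
  ros <- make_roster(20)
  pp <- make_prepost(ros, d_pic = 30, d_uic = 10, sd = 10)
  fit <- fit_mlm(pp, "distance_m", ros, time_var = "phase",
                 random_slope = "fixed")
  ros$bmi <- ros$weight_kg / (ros$height_cm / 100)^2
  idx <- match(pp$participant_id, ros$participant_id)
  d <- data.frame(y = pp$distance_m,
                  t = as.numeric(pp$phase == "after"),
                  g = as.numeric(ros$group[idx] == "PIC"),
                  bmi_c = ros$bmi[idx] - mean(ros$bmi),
                  sex01 = as.numeric(ros$sex[idx] == "female"))
  ols <- lm(y ~ t * g + bmi_c + sex01, d)
  co <- coef(ols)[c("(Intercept)", "g", "bmi_c", "sex01", "t", "t:g")]
  eff <- c("gamma00", "gamma01", "gamma02", "gamma03", "gamma10", "gamma11")
  est <- fit$coefficients$estimate[match(eff, fit$coefficients$effect)]
  expect_equal(unname(est), unname(co), tolerance = 1e-8)
})

test_that("a constant outcome yields a degenerate but well-formed fit", {
  ros <- make_roster(4)
  pp <- make_prepost(ros, d_pic = 0, d_uic = 0, base = 7)
  fit <- fit_mlm(pp, "distance_m", ros, time_var = "phase")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$effect)
  expect_equal(unname(est["gamma00"]), 7)
  expect_true(all(est[c("gamma10", "gamma11", "gamma01")] == 0))
  expect_equal(unname(fit$varcomp["var_eps"]), 0)
  expect_true(all(cell_means(fit)$mean == 7))
})

test_that("AIC slope selection is deterministic and refits are bit-identical", {
  st <- simulate_trial(small_config(seed = 41, n_days = 6), keep_minutes = FALSE)
  pp <- build_prepost(st$log, st$windows, st$trial)
  f1 <- fit_mlm(pp, "distance_m", st$roster, "phase", "auto")
  f2 <- fit_mlm(pp, "distance_m", st$roster, "phase", "auto")
  expect_identical(f1$slope, f2$slope)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$aic, f2$aic)
})

test_that("Tukey-Kramer with two cells equals the pooled t-test p-value", {
  # numeric-integration oracle for the k = 2 studentized-range tail
  oracle_p <- function(q, df) {
    f <- function(s) {
      (2 * pnorm(q * s / sqrt(2)) - 1) * 2 * s * df * dchisq(s^2 * df, df)
    }
    1 - integrate(f, 0, Inf, rel.tol = 1e-10)$value
  }
  set.seed(5)
  for (rep in 1:5) {
    est <- rnorm(2, 10, 3)
    ses <- runif(2, 0.5, 2)
    df <- sample(5:60, 1)
    adj <- adjust_tukey_kramer(est, ses, df)
    tstat <- abs(diff(est)) / sqrt(sum(ses^2))
    expect_equal(adj$p_adj, 2 * pt(-tstat, df), tolerance = 1e-8)
    expect_equal(adj$p_adj, oracle_p(sqrt(2) * tstat, df), tolerance = 1e-5)
  }
})

test_that("Tukey-Kramer adjustment is conservative and handles ties", {
  adj <- adjust_tukey_kramer(c(5, 5), c(1, 1), df = 10)
  expect_gt(adj$p_adj, 0.999)
  set.seed(6)
  est <- rnorm(4, 0, 2)
  ses <- runif(4, 0.5, 1.5)
  adj4 <- adjust_tukey_kramer(est, ses, df = 24)
  expect_true(all(adj4$p_adj >= adj4$p_unadj - 1e-12))
  expect_error(adjust_tukey_kramer(est, ses, df = 0), "df")
  expect_error(adjust_tukey_kramer(1, 1, df = 5), "2 cells")
})

test_that("descriptives reproduce textbook group comparisons", {
  # identical groups: all statistics vanish
  ros <- make_roster(8)
  ros$age <- rep(c(20, 21, 22, 23), 2)
  same <- ros
  same$age <- rep(20, 8)
  d0 <- descriptives(same)
  expect_equal(d0$statistic[d0$variable == "age"], 0)
  # 9/5 vs 7/7 males/females: chi-square 0.583 (df 1, p .445), no correction
  ros28 <- make_roster(28)
  ros28$group <- rep(c("PIC", "UIC"), each = 14)
  ros28$sex <- c(rep("male", 9), rep("female", 5), rep("male", 7), rep("female", 7))
  d <- descriptives(ros28)
  sexrow <- d[d$variable == "sex_female", ]
  expect_equal(sexrow$statistic, 7 / 12, tolerance = 1e-6) # = 0.5833
  expect_equal(sexrow$df, 1)
  expect_equal(sexrow$p, 0.445, tolerance = 0.001)
  expect_error(descriptives(make_roster(3)), "n >= 2")
})

test_that("group contrast equals the cell-mean difference-in-change on noisy fits", {
  set.seed(8)
  ros <- make_roster(10)
  pp <- make_prepost(ros, d_pic = 40, d_uic = 15, sd = 8, pairs_per_person = 4)
  for (slope in c("fixed", "random")) {
    fit <- fit_mlm(pp, "distance_m", ros, "phase", slope)
    gc <- group_contrast(fit)
    expect_equal(gc$estimate, gc$from_cells, tolerance = 1e-8)
    ch <- group_changes(fit)
    expect_equal(ch$estimate[ch$group == "PIC"] - ch$estimate[ch$group == "UIC"],
                 gc$estimate, tolerance = 1e-8)
  }
})

test_that("weekly model finds no week effect when the response is off", {
  ros <- make_roster(8)
  wk <- data.frame(
    participant_id = rep(ros$participant_id, each = 2),
    week = rep(1:2, 8),
    distance_m = rep(c(180, 180, 220, 220, 200, 200, 240, 240), 2))
  fit <- fit_mlm(wk, "distance_m", ros, time_var = "week", random_slope = "fixed")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$effect)
  expect_equal(unname(est["gamma10"]), 0, tolerance = 1e-6)
  expect_equal(unname(est["gamma11"]), 0, tolerance = 1e-6)
})
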