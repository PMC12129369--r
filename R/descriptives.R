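# Baseline group comparisons (roster characteristics).

#' Group comparison of participant characteristics
#'
#' Compares the PIC and UIC arms on the roster covariates: pooled-variance
#' two-sample t tests (df = n1 + n2 - 2) for age, height, weight and BMI, and
#' a chi-square test without continuity correction (df = 1) for the sex
#' distribution. t statistics are oriented PIC minus UIC.
#'
#' @param roster Participant roster with both groups, n >= 2 each.
#' @return Data.frame with per-group mean (SD) — or counts for sex — plus the
#'   test statistic, df and p-value per characteristic.
#' @export
descriptives <- function(roster) {
  roster <- validate_roster(roster)
  pic <- roster[roster$group == "PIC", ]
  uic <- roster[roster$group == "UIC", ]
  if (nrow(pic) < 2L || nrow(uic) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  vars <- c(age = "age", height_cm = "height_cm", weight_kg = "weight_kg",
            bmi = "bmi")
  rows <- lapply(names(vars), function(v) {
    tt <- t_from_summary(mean(pic[[v]]), sd(pic[[v]]), nrow(pic),
                         mean(uic[[v]]), sd(uic[[v]]), nrow(uic))
    data.frame(
      variable = v, test = "t",
      all_mean = mean(roster[[v]]), all_sd = sd(roster[[v]]),
      pic_mean = mean(pic[[v]]), pic_sd = sd(pic[[v]]),
      uic_mean = mean(uic[[v]]), uic_sd = sd(uic[[v]]),
      statistic = tt$t, df = tt$df, p = tt$p
    )
  })
  tab <- table(factor(roster$group, c("PIC", "UIC")),
               factor(roster$sex, c("male", "female")))
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  rows[[length(rows) + 1L]] <- data.frame(
    variable = "sex_female", test = "chisq",
    all_mean = mean(roster$sex == "female"), all_sd = NA_real_,
    pic_mean = mean(pic$sex == "female"), pic_sd = NA_real_,
    uic_mean = mean(uic$sex == "female"), uic_sd = NA_real_,
    statistic = unname(cs$statistic), df = unname(cs$parameter),
    p = cs$p.value
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-sample t test from summary statistics
#'
#' Recomputes the two-sample pooled-variance t statistic from published
#' group means, SDs and sizes (useful for checking reported baseline
#' comparisons without raw data).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return One-row data.frame: `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  t <- if (sp2 == 0) {
    if (diff == 0) 0 else sign(diff) * Inf # degenerate zero-variance groups
  } else {
    diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  data.frame(t = t, df = df, p = 2 * pt(-abs(t), df))
}
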