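# Two-level linear mixed models for the intervention contrasts.
#
# Level 1 (within person):   y_ti = beta_0i + beta_1i * time_ti + eps_ti
# Level 2 (between persons): beta_0i = g00 + g01*group_i + g02*BMI_i
#                                      + g03*sex_i + u_0i
#                            beta_1i = g10 + g11*group_i [+ u_1i]
#
# time is the pre/post-prompt phase (Model Set A) or the study week (Model
# Set B), coded 0/1 with before/week-1 as reference; group is coded UIC = 0,
# PIC = 1, so g10 is the UIC change and g11 the PIC excess
# (difference-in-change). BMI is centred at the sample mean and sex coded
# male = 0 / female = 1. Estimation is REML via lme4; the random-vs-fixed
# slope choice can be made automatically by AIC. Test degrees of freedom use
# the between/within partition: person-level effects get N - 4, time-varying
# effects get n - N - 2.

GAMMA_MAP <- c("(Intercept)" = "gamma00", "group01" = "gamma01",
               "bmi_c" = "gamma02", "sex01" = "gamma03",
               "time01" = "gamma10", "time01:group01" = "gamma11")

#' Fit a two-level mixed model for an intervention contrast
#'
#' @param data Long dataset from [build_prepost()] (`time_var = "phase"`) or
#'   [build_weekly()] (`time_var = "week"`).
#' @param outcome Name of the outcome column (one of the seven activity
#'   measures).
#' @param roster Participant roster supplying group, BMI and sex.
#' @param time_var `"phase"` or `"week"`.
#' @param random_slope `"auto"` (fit both slope structures, keep the lower
#'   AIC, ties to fixed), `"random"`, or `"fixed"`.
#' @return An object of class `jitai_mlm`: coefficient table (gamma00 ...
#'   gamma11 with SE, between/within df, t, p), variance components, AICs and
#'   chosen slope structure, estimated group x time cell means with SEs,
#'   within-group change contrasts (Tukey-Kramer adjusted over the four
#'   cells), and the interaction contrast.
#' @export
fit_mlm <- function(data, outcome, roster,
                    time_var = c("phase", "week"),
                    random_slope = c("auto", "random", "fixed")) {
  time_var <- match.arg(time_var)
  random_slope <- match.arg(random_slope)
  if (!outcome %in% names(data)) stop("unknown outcome: ", outcome, call. = FALSE)
  roster <- validate_roster(roster)
  time01 <- if (time_var == "phase") {
    as.numeric(data$phase == "after")
  } else {
    as.numeric(data$week == 2L)
  }
  idx <- match(data$participant_id, roster$participant_id)
  if (anyNA(idx)) stop("data contains participants absent from roster", call. = FALSE)
  d <- data.frame(
    pid = data$participant_id,
    y = as.numeric(data[[outcome]]),
    time01 = time01,
    group01 = as.numeric(roster$group[idx] == "PIC"),
    bmi = roster$bmi[idx],
    sex01 = as.numeric(roster$sex[idx] == "female")
  )
  pids <- unique(d$pid)
  N <- length(pids)
  if (N < 2L) stop("need >= 2 participants", call. = FALSE)
  if (length(unique(d$time01)) < 2L) stop("need both time levels", call. = FALSE)
  per <- d[!duplicated(d$pid), ]
  bmi_ref <- mean(per$bmi)
  sex_ref <- mean(per$sex01)
  d$bmi_c <- d$bmi - bmi_ref
  nobs <- nrow(d)
  df_between <- max(1L, N - 4L)
  df_within <- max(1L, nobs - N - 2L)

  if (stats::var(d$y) == 0) {
    fit <- degenerate_fit(d$y[1], df_between, df_within, nobs, N)
  } else {
    fit <- reml_fit(d, random_slope)
  }

  beta <- fit$beta
  V <- fit$V
  eff <- GAMMA_MAP[names(beta)]
  df_vec <- ifelse(eff %in% c("gamma10", "gamma11"), df_within, df_between)
  se <- sqrt(pmax(0, diag(V)))
  stat <- ifelse(se > 0, beta / se, NA_real_)
  coefs <- data.frame(
    effect = unname(eff), estimate = unname(beta), se = se, df = df_vec,
    stat = unname(stat), p = unname(2 * pt(-abs(stat), df_vec)),
    row.names = NULL
  )

  time_labels <- if (time_var == "phase") c("before", "after") else c("week1", "week2")
  cells <- compute_cells(beta, V, sex_ref, time_labels)
  changes <- compute_changes(beta, V, df_within, time_labels)
  g11 <- which(eff == "gamma11")
  contrast <- data.frame(
    effect = "gamma11", estimate = beta[[g11]], se = se[[g11]],
    df = df_within, stat = stat[[g11]], p = coefs$p[g11], row.names = NULL
  )

  structure(
    list(coefficients = coefs, vcov = V, varcomp = fit$varcomp,
         aic = fit$aic, slope = fit$slope, singular = fit$singular,
         cells = cells, changes = changes, contrast = contrast,
         df = c(between = df_between, within = df_within),
         nobs = nobs, n_participants = N, outcome = outcome,
         time_var = time_var, time_labels = time_labels,
         covariate_reference = c(bmi = bmi_ref, sex = sex_ref)),
    class = "jitai_mlm"
  )
}

reml_fit <- function(d, random_slope) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  quiet <- function(expr) suppressWarnings(suppressMessages(expr))
  f_fixed <- y ~ time01 * group01 + bmi_c + sex01 + (1 | pid)
  f_rand <- y ~ time01 * group01 + bmi_c + sex01 + (1 + time01 | pid)
  fits <- list()
  if (random_slope %in% c("auto", "fixed")) {
    fits$fixed <- quiet(try(lme4::lmer(f_fixed, data = d, REML = TRUE,
                                       control = ctrl), silent = TRUE))
  }
  if (random_slope %in% c("auto", "random")) {
    fits$random <- quiet(try(lme4::lmer(f_rand, data = d, REML = TRUE,
                                        control = ctrl), silent = TRUE))
  }
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) {
    stop("mixed-model fit did not converge: ",
         paste(vapply(fits, function(x) attr(x, "condition")$message,
                      character(1)), collapse = "; "),
         call. = FALSE)
  }
  aic <- c(fixed = NA_real_, random = NA_real_)
  for (nm in names(fits)) if (ok[[nm]]) aic[[nm]] <- stats::AIC(fits[[nm]])
  slope <- if (random_slope == "auto") {
    # ties (and a failed random fit) resolve to the simpler fixed slope
    if (ok["random"] && !is.na(aic["random"]) &&
        (!ok["fixed"] || aic[["random"]] < aic[["fixed"]] - 1e-8)) "random" else "fixed"
  } else {
    random_slope
  }
  if (!ok[[slope]]) {
    stop("mixed-model fit did not converge for slope structure '", slope, "'",
         call. = FALSE)
  }
  fit <- fits[[slope]]
  if (length(lme4::fixef(fit)) < length(GAMMA_MAP)) {
    aliased <- setdiff(names(GAMMA_MAP), names(lme4::fixef(fit)))
    stop("fixed-effect design is rank deficient (aliased: ",
         paste(aliased, collapse = ", "), ")", call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp, v1, v2 = NA) {
    i <- which(vc$grp == grp & vc$var1 %in% v1 &
                 (is.na(v2) & is.na(vc$var2) | !is.na(v2) & vc$var2 %in% v2))
    if (length(i)) vc$vcov[i[1]] else NA_real_
  }
  varcomp <- c(
    var_u0 = pick("pid", "(Intercept)"),
    var_u1 = if (slope == "random") pick("pid", "time01") else NA_real_,
    var_eps = vc$vcov[vc$grp == "Residual"][1]
  )
  list(beta = lme4::fixef(fit), V = as.matrix(vcov(fit)), varcomp = varcomp,
       aic = aic, slope = slope,
       singular = lme4::isSingular(fit, tol = 1e-6))
}

degenerate_fit <- function(y0, df_between, df_within, nobs, N) {
  nm <- names(GAMMA_MAP)
  beta <- setNames(c(y0, 0, 0, 0, 0, 0), nm)
  V <- matrix(0, 6, 6, dimnames = list(names(beta), names(beta)))
  list(beta = beta, V = V,
       varcomp = c(var_u0 = 0, var_u1 = NA_real_, var_eps = 0),
       aic = c(fixed = NA_real_, random = NA_real_),
       slope = "fixed", singular = TRUE)
}

cell_x <- function(t, g, sex_ref, nm) {
  x <- setNames(numeric(length(nm)), nm)
  x["(Intercept)"] <- 1
  x["time01"] <- t
  x["group01"] <- g
  x["bmi_c"] <- 0
  x["sex01"] <- sex_ref
  x["time01:group01"] <- t * g
  x
}

compute_cells <- function(beta, V, sex_ref, time_labels) {
  nm <- names(beta)
  grid <- expand.grid(time = 0:1, group = 0:1)
  est <- se <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x <- cell_x(grid$time[i], grid$group[i], sex_ref, nm)
    est[i] <- sum(x * beta)
    se[i] <- sqrt(max(0, drop(t(x) %*% V %*% x)))
  }
  data.frame(
    group = c("UIC", "PIC")[grid$group + 1L],
    time = time_labels[grid$time + 1L],
    mean = est, se = se
  )
}

compute_changes <- function(beta, V, df_within, time_labels) {
  nm <- names(beta)
  out <- lapply(c(UIC = 0, PIC = 1), function(g) {
    L <- cell_x(1, g, 0, nm) - cell_x(0, g, 0, nm)
    est <- sum(L * beta)
    se <- sqrt(max(0, drop(t(L) %*% V %*% L)))
    stat <- if (se > 0) est / se else NA_real_
    # Tukey-Kramer over the four group x time cells
    p_adj <- if (is.na(stat)) NA_real_ else
      ptukey(sqrt(2) * abs(stat), nmeans = 4, df = df_within,
             lower.tail = FALSE)
    data.frame(estimate = est, se = se, df = df_within, stat = stat,
               p_unadj = 2 * pt(-abs(stat), df_within), p = p_adj)
  })
  cbind(data.frame(group = names(out),
                   contrast = paste(time_labels[2], "-", time_labels[1])),
        do.call(rbind, out), row.names = NULL)
}

#' @export
print.jitai_mlm <- function(x, ...) {
  cat(sprintf("<jitai_mlm> outcome %s over %s; %d obs / %d participants; %s slope (AIC fixed %.1f / random %.1f)%s\n",
              x$outcome, x$time_var, x$nobs, x$n_participants, x$slope,
              x$aic[["fixed"]], x$aic[["random"]],
              if (isTRUE(x$singular)) " [singular]" else ""))
  print(x$coefficients, digits = 4)
  cat("cell means:\n")
  print(x$cells, digits = 4)
  invisible(x)
}

#' Estimated group x time cell means
#'
#' Cell means are linear combinations of the fixed effects evaluated at the
#' covariate reference (BMI at the sample mean, sex at the sample proportion
#' female unless overridden); SEs come from the fixed-effect covariance.
#'
#' @param fit A `jitai_mlm` object.
#' @param covariate_reference Optional list with `sex` (proportion female) to
#'   override the stored reference. BMI is always centred, so its reference
#'   is the sample mean by construction.
#' @return Data.frame `group`, `time`, `mean`, `se`.
#' @export
cell_means <- function(fit, covariate_reference = NULL) {
  stopifnot(inherits(fit, "jitai_mlm"))
  sex_ref <- fit$covariate_reference[["sex"]]
  if (!is.null(covariate_reference$sex)) sex_ref <- covariate_reference$sex
  compute_cells(fit$coefficients$estimate |>
                  setNames(names(GAMMA_MAP)[match(fit$coefficients$effect, GAMMA_MAP)]),
                fit$vcov, sex_ref, fit$time_labels)
}

#' Within-group change contrasts
#'
#' @param fit A `jitai_mlm` object.
#' @return Data.frame with one row per group: the time change (after-before
#'   or week2-week1), its SE, df, t statistic, unadjusted p and Tukey-Kramer
#'   adjusted p over the four cells.
#' @export
group_changes <- function(fit) {
  stopifnot(inherits(fit, "jitai_mlm"))
  fit$changes
}

#' Difference-in-change (interaction) contrast
#'
#' Returns the group x time interaction gamma11 - how much more the PIC arm
#' changed than the UIC arm - together with a consistency check recomputing
#' it from the estimated cell means.
#'
#' @param fit A `jitai_mlm` object.
#' @return One-row data.frame: `estimate`, `se`, `df`, `stat`, `p`,
#'   `from_cells` (the cell-mean difference-in-change, equal to `estimate` to
#'   numerical tolerance).
#' @export
group_contrast <- function(fit) {
  stopifnot(inherits(fit, "jitai_mlm"))
  cells <- fit$cells
  pick <- function(g, t) cells$mean[cells$group == g & cells$time == t]
  tl <- fit$time_labels
  from_cells <- (pick("PIC", tl[2]) - pick("PIC", tl[1])) -
    (pick("UIC", tl[2]) - pick("UIC", tl[1]))
  out <- fit$contrast
  out$from_cells <- from_cells
  out
}

#' Tukey-Kramer adjustment for pairwise cell contrasts
#'
#' For each pair of cell estimates the Kramer pairwise SE is
#' `sqrt(se_i^2 + se_j^2)`, the studentized-range statistic is
#' `q = sqrt(2) |diff| / se_pair`, and the adjusted p-value is the upper tail
#' of the studentized range distribution with `k` groups and `df` degrees of
#' freedom. With `k = 2` the adjusted p equals the ordinary two-sided t-test
#' p-value.
#'
#' @param estimates Cell estimates.
#' @param ses Their standard errors.
#' @param df Degrees of freedom (> 0).
#' @param labels Optional cell labels.
#' @return Data.frame with one row per pair: `diff`, `se`, `q`, `p_unadj`,
#'   `p_adj`.
#' @export
adjust_tukey_kramer <- function(estimates, ses, df, labels = NULL) {
  k <- length(estimates)
  if (k < 2L) stop("need at least 2 cells", call. = FALSE)
  if (length(ses) != k) stop("estimates and ses must have equal length", call. = FALSE)
  if (df <= 0) stop("df must be > 0", call. = FALSE)
  if (is.null(labels)) labels <- paste0("cell", seq_len(k))
  pairs <- utils::combn(k, 2)
  diff <- estimates[pairs[1, ]] - estimates[pairs[2, ]]
  se <- sqrt(ses[pairs[1, ]]^2 + ses[pairs[2, ]]^2)
  tstat <- abs(diff) / se
  q <- sqrt(2) * tstat
  data.frame(
    a = labels[pairs[1, ]], b = labels[pairs[2, ]],
    diff = diff, se = se, q = q,
    p_unadj = 2 * pt(-tstat, df),
    p_adj = ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  )
}
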