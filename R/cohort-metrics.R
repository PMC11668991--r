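#' Participation rate
#'
#' Participants who completed at least one momentary assessment divided by all
#' invitees.
#'
#' @param n_invited number invited.
#' @param n_participated number with at least one completed assessment.
#' @return Proportion in \[0,1\].
#' @examples
#' participation_rate(1259, 782) # 0.621
#' @export
participation_rate <- function(n_invited, n_participated) {
  if (!is_count(n_invited) || n_invited == 0) stop_emaqc("undefined rate: n_invited must be > 0")
  if (!is_count(n_participated) || n_participated > n_invited) {
    stop_emaqc("n_participated must be a count <= n_invited")
  }
  n_participated / n_invited
}

#' Per-person compliance
#'
#' Completed assessments divided by the design maximum (56 for the default
#' design), regardless of enrollment date: no pro-rating.
#'
#' @param n_completed completed assessments (vectorized).
#' @param design an [ema_design()].
#' @return Proportion(s) in \[0,1\].
#' @examples
#' person_compliance(25) # 0.446 -> displayed 45%
#' @export
person_compliance <- function(n_completed, design = ema_design()) {
  mp <- max_prompts(design)
  if (any(is.na(n_completed)) || any(n_completed < 0) || any(n_completed != floor(n_completed))) {
    stop_emaqc("n_completed must be non-negative counts")
  }
  if (any(n_completed > mp)) stop_emaqc("data error: n_completed exceeds the design maximum (%d)", mp)
  n_completed / mp
}

#' Format a compliance proportion as a percentage
#'
#' @param x proportion(s).
#' @param digits decimals (1 by default; 0 for threshold display).
#' @return Character percentage(s).
#' @export
format_compliance_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round(100 * x, digits))
}

#' Compliance summary of a cohort
#'
#' Mean, SD, median, mode and range of per-person compliance, computed over
#' participants (not assessments). The mode is taken on the discrete
#' n_completed / max_prompts grid.
#'
#' @param cohort participant table with n_completed (and optionally a grouping
#'   column named by `by`).
#' @param design an [ema_design()].
#' @param by optional column name to stratify by (e.g. "subsample").
#' @return Data frame with one row overall (`group = "all"`) and one per
#'   stratum when `by` is given; columns n, mean, sd, median, mode, min, max
#'   (all on the proportion scale).
#' @export
compliance_summary <- function(cohort, design = ema_design(), by = NULL) {
  if (nrow(cohort) == 0) stop_emaqc("empty cohort")
  one <- function(nc) {
    compl <- person_compliance(nc, design)
    tab <- table(nc)
    mode_nc <- as.numeric(names(tab)[which.max(tab)])
    data.frame(
      n = length(compl),
      mean = mean(compl), sd = stats::sd(compl),
      median = stats::median(compl),
      mode = mode_nc / max_prompts(design),
      min = min(compl), max = max(compl)
    )
  }
  out <- cbind(group = "all", one(cohort$n_completed))
  if (!is.null(by)) {
    for (g in sort(unique(cohort[[by]]))) {
      out <- rbind(out, cbind(group = g, one(cohort$n_completed[cohort[[by]] == g])))
    }
  }
  out
}

#' Per-day completion proportions and linear trend
#'
#' Completion proportion per EMA day with a fitted linear slope
#' (proportion/day). Internal days 1..n map to study days 2..(n+1): the first
#' and last study days carry questionnaires, not momentary prompts.
#'
#' @param assessments assessment table with day and completed columns.
#' @param by optional person-level grouping column present in `assessments`.
#' @return List with `by_day` (day, ema_day, n, prop) and `slope` (NA with a
#'   flag when only one day is observed); per-group results under `groups`
#'   when `by` is given.
#' @export
compliance_by_day <- function(assessments, by = NULL) {
  one <- function(a) {
    agg <- stats::aggregate(a$completed, list(day = a$day), mean)
    names(agg)[2] <- "prop"
    n <- stats::aggregate(a$completed, list(day = a$day), length)$x
    by_day <- data.frame(day = agg$day, ema_day = agg$day + 1L, n = n, prop = agg$prop)
    slope <- if (nrow(by_day) < 2) NA_real_ else unname(stats::coef(stats::lm(prop ~ day, by_day))[2])
    list(by_day = by_day, slope = slope,
         single_day = nrow(by_day) < 2)
  }
  out <- one(assessments)
  if (!is.null(by)) {
    out$groups <- lapply(split(assessments, assessments[[by]]), one)
  }
  out
}

covariate_defaults <- c("sex", "nationality", "age_group", "field_of_study")

# declared reference-first category orders for the paper's contrasts
reference_levels <- list(
  sex = c("male", "female"),
  nationality = c("spanish", "other"),
  age_group = c("18-21", "22-25", "26-29", ">=30"),
  field_of_study = c("arts_humanities", "sciences", "health_sciences",
                     "social_legal", "engineering_architecture")
)

prepare_model_frame <- function(data, vars) {
  for (v in vars) {
    if (!v %in% names(data)) stop_emaqc("column '%s' not found", v)
    x <- data[[v]]
    if (!is.numeric(x)) {
      lev <- reference_levels[[v]]
      lev <- if (!is.null(lev) && all(unique(x) %in% lev)) lev[lev %in% unique(x)] else sort(unique(x))
      data[[v]] <- factor(x, levels = lev)
    }
  }
  data
}

# Wald CI on the link scale, exponentiated; rows for the exposure terms only
tidy_exp_terms <- function(fit, exposure, model, n, adjusted_for, vcov_mat = NULL) {
  cf <- stats::coef(fit)
  V <- vcov_mat %||% stats::vcov(fit)
  se <- sqrt(diag(V))
  keep <- grep(paste0("^", exposure), names(cf))
  est <- cf[keep]
  non_est <- !is.finite(est) | se[keep] > 50 | abs(est) > 50
  data.frame(
    term = names(cf)[keep],
    estimate = exp(est),
    ci_low = exp(est - 1.96 * se[keep]),
    ci_high = exp(est + 1.96 * se[keep]),
    model = model,
    n = n,
    adjusted_for = paste(adjusted_for, collapse = "+"),
    note = ifelse(non_est, "non-estimable (separation or empty cell)", ""),
    row.names = NULL
  )
}

#' Logistic model for EMA participation
#'
#' Fits one logistic regression of participation (at least one completed
#' assessment) on a single exposure, adjusting for the four sociodemographic
#' and college-related covariates. One model per exposure — never a joint
#' model over all exposures. Estimates are odds ratios with Wald 95% CIs.
#'
#' @param cohort participant table restricted to invitees; needs
#'   `participated`, the exposure and the adjustment covariates.
#' @param exposure name of the exposure column.
#' @param adjust adjustment covariates (reference category = first of the
#'   declared order: male, spanish, 18-21, arts & humanities).
#' @return Data frame with term, estimate (OR), ci_low, ci_high, model, n,
#'   adjusted_for and a note for non-estimable terms.
#' @export
fit_participation_model <- function(cohort, exposure, adjust = covariate_defaults) {
  cohort <- cohort[cohort$invited, , drop = FALSE]
  adjust <- setdiff(adjust, exposure)
  dat <- prepare_model_frame(cohort, c(exposure, adjust))
  fml <- stats::reformulate(c(exposure, adjust), response = "participated")
  fit <- tryCatch(
    stats::glm(fml, family = stats::binomial(), data = dat),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(data.frame(term = exposure, estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, model = "logistic", n = nrow(dat),
                      adjusted_for = paste(adjust, collapse = "+"),
                      note = "model failed to fit"))
  }
  tidy_exp_terms(fit, exposure, "logistic", nrow(dat), adjust)
}

# HC0 sandwich covariance for a glm fit (score = X'(y - mu))
vcov_hc0 <- function(fit) {
  X <- stats::model.matrix(fit)
  r <- fit$y - fit$fitted.values
  bread <- stats::vcov(fit)
  bread %*% crossprod(X * r) %*% bread
}

#' Poisson model for compliance
#'
#' Fits one Poisson regression of the per-person completed-assessment count on
#' a single exposure plus the four adjustment covariates, with a fixed offset
#' of log(max_prompts) so the estimates are rate ratios, reported as
#' exponentiated coefficients exp(beta) with Wald 95% CIs. A robust
#' (HC0 sandwich) variance option is available for the over/under-dispersion
#' that counts out of 56 typically show; the plain-Poisson Wald CI is the
#' default.
#'
#' @inheritParams fit_participation_model
#' @param design an [ema_design()] fixing the offset denominator.
#' @param robust use the sandwich variance for the CIs.
#' @return Data frame as in [fit_participation_model()] with model "poisson".
#' @export
fit_compliance_model <- function(cohort, exposure, design = ema_design(),
                                 adjust = covariate_defaults, robust = FALSE) {
  adjust <- setdiff(adjust, exposure)
  dat <- prepare_model_frame(cohort, c(exposure, adjust))
  dat$.offset <- log(max_prompts(design))
  fml <- stats::reformulate(c(exposure, adjust, "offset(.offset)"), response = "n_completed")
  fit <- tryCatch(
    stats::glm(fml, family = stats::poisson(), data = dat),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(data.frame(term = exposure, estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, model = "poisson", n = nrow(dat),
                      adjusted_for = paste(adjust, collapse = "+"),
                      note = "model failed to fit"))
  }
  V <- if (robust) vcov_hc0(fit) else NULL
  tidy_exp_terms(fit, exposure, if (robust) "poisson (robust)" else "poisson",
                 nrow(dat), adjust, vcov_mat = V)
}
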