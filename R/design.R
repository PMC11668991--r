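#' EMA study design
#'
#' Describes the sampling scheme of the momentary-assessment protocol: prompts
#' are delivered at a random moment within fixed daily time windows over a
#' number of EMA days, each prompt carrying a common battery of Likert items
#' from which positive-affect (PA) and negative-affect (NA) scores are derived.
#'
#' The default design is 14 EMA days with 4 prompts/day in 2-hour windows
#' starting at 08:00, 12:00, 16:00 and 20:00 (a maximum of 56 assessments per
#' person), a reminder after 30 minutes, and twelve 7-point Likert items of
#' which 5 measure PA and 4 measure NA. Morning and evening prompts carry
#' additional items, so the total item count per assessment varies by window
#' (`n_items_by_window`); the 12-item common set is fixed.
#'
#' @param n_ema_days number of EMA days.
#' @param prompts_per_day prompts delivered per day.
#' @param window_starts clock hours at which each daily window opens.
#' @param window_length_minutes length of each response window; an assessment
#'   not completed within it counts as missed.
#' @param reminder_minutes delay of the reminder notification.
#' @param n_items_common number of Likert items shared by every assessment.
#' @param likert_min,likert_max response scale bounds.
#' @param pa_items,na_items ids (column names) of the PA and NA items within
#'   the common set; disjoint subsets of `item_ids`.
#' @param item_ids ids of the common items, in battery order.
#' @param n_items_by_window total item count per assessment for each window
#'   (common set plus context/add-on items).
#' @return An object of class `ema_design`.
#' @examples
#' d <- ema_design()
#' max_prompts(d) # 56
#' @export
ema_design <- function(n_ema_days = 14L,
                       prompts_per_day = 4L,
                       window_starts = c(8L, 12L, 16L, 20L),
                       window_length_minutes = 120,
                       reminder_minutes = 30,
                       n_items_common = 12L,
                       likert_min = 1L,
                       likert_max = 7L,
                       item_ids = sprintf("item_%02d", 1:12),
                       pa_items = sprintf("item_%02d", 4:8),
                       na_items = sprintf("item_%02d", 9:12),
                       n_items_by_window = NULL) {
  if (!is_count(n_ema_days) || n_ema_days < 1) stop_emaqc("n_ema_days must be a positive count")
  if (!is_count(prompts_per_day) || prompts_per_day < 1) stop_emaqc("prompts_per_day must be a positive count")
  if (length(window_starts) != prompts_per_day) {
    stop_emaqc("window_starts must have one entry per prompt (%d)", prompts_per_day)
  }
  if (likert_min >= likert_max) stop_emaqc("likert_min must be below likert_max")
  if (length(item_ids) != n_items_common) stop_emaqc("item_ids must have n_items_common entries")
  if (!all(pa_items %in% item_ids) || !all(na_items %in% item_ids)) {
    stop_emaqc("pa_items and na_items must be subsets of the common item set")
  }
  if (length(intersect(pa_items, na_items)) > 0) stop_emaqc("pa_items and na_items must be disjoint")
  if (is.null(n_items_by_window)) {
    # morning/evening prompts carry add-on blocks (sleep, alcohol, events)
    n_items_by_window <- rep(n_items_common + 3L, prompts_per_day)
    n_items_by_window[c(1L, prompts_per_day)] <- n_items_common + 8L
  }
  if (length(n_items_by_window) != prompts_per_day) {
    stop_emaqc("n_items_by_window must have one entry per window")
  }
  structure(
    list(
      n_ema_days = as.integer(n_ema_days),
      prompts_per_day = as.integer(prompts_per_day),
      window_starts = as.numeric(window_starts),
      window_length_minutes = as.numeric(window_length_minutes),
      reminder_minutes = as.numeric(reminder_minutes),
      n_items_common = as.integer(n_items_common),
      likert_min = as.integer(likert_min),
      likert_max = as.integer(likert_max),
      item_ids = item_ids,
      pa_items = pa_items,
      na_items = na_items,
      n_items_by_window = as.integer(n_items_by_window)
    ),
    class = "ema_design"
  )
}

#' Maximum number of assessments allowed by a design
#'
#' @param design an [ema_design()].
#' @return `n_ema_days * prompts_per_day` (56 for the default design).
#' @export
max_prompts <- function(design) design$n_ema_days * design$prompts_per_day

#' @export
print.ema_design <- function(x, ...) {
  cat(sprintf(
    "<ema_design> %d days x %d prompts/day (max %d assessments), %d common items (Likert %d-%d), %d PA / %d NA items\n",
    x$n_ema_days, x$prompts_per_day, max_prompts(x), x$n_items_common,
    x$likert_min, x$likert_max, length(x$pa_items), length(x$na_items)
  ))
  invisible(x)
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the synthetic EMA cohort generator. Defaults emulate a
#' university-student EMA study with quota sampling into four mental-health
#' subsamples, mean compliance of 76.9% declining linearly over days, PA/NA
#' between-person variances of 0.94/0.88 and within-person variances of
#' 0.81/0.80, a median prompt-response latency of 15 minutes, and a small
#' amount of careless behaviour (fast responding and straight-lining)
#' concentrated in a cluster of participants.
#'
#' @param n_participants number of participants to simulate.
#' @param subsample_probs probabilities of assignment to the four subsamples
#'   (suicidal ideation, harmful alcohol use, anxiety/depression, control);
#'   must sum to 1.
#' @param sigma2_between named vector `c(pa=, na=)` of between-person latent
#'   variances of the affect scores.
#' @param sigma2_within named vector `c(pa=, na=)` of within-person (momentary)
#'   latent variances.
#' @param affect_correlation latent correlation between PA and NA (applied to
#'   both person intercepts and momentary deviations); negative so that
#'   psychometric antonyms exist.
#' @param ar1_affect lag-1 autocorrelation of the momentary deviations across
#'   a person's consecutive prompts (0 = exchangeable, the default; the
#'   stationary variance stays at `sigma2_within`).
#' @param item_variance_components named vector with `sigma2_item`,
#'   `sigma2_person_item` and `sigma2_error`: item main effect, person-by-item
#'   interaction and residual variances used when generating the individual
#'   item responses around the scale latents. Set `sigma2_error = 0` (and the
#'   others to 0) to make items exact copies of the scale latent.
#' @param mean_compliance mean of the person-specific completion probability.
#' @param compliance_sd between-person SD of the completion probability
#'   (a beta distribution is used).
#' @param compliance_day_slope additive change in completion probability per
#'   EMA day (<= 0; the day effect is centred so the overall mean stays at
#'   `mean_compliance`).
#' @param careless_fraction_fast fraction of completed assessments injected as
#'   "fast" (time per item below 1 s).
#' @param careless_fraction_straightline fraction injected as straight-lined
#'   (all common items identical).
#' @param careless_cluster_size number of participants receiving the careless
#'   injections first, reproducing the clustering of careless behaviour in a
#'   minority of participants.
#' @param latency_median_minutes median delay between prompt and starting the
#'   assessment.
#' @param tpi_median_seconds,tpi_sdlog median and log-scale SD of the
#'   lognormal time-per-item distribution of honest assessments.
#' @param covariate_probs named list of categorical distributions for the
#'   person covariates (sex, nationality, age_group, field_of_study).
#' @param seed integer seed; all generator sub-streams derive from it.
#' @return An object of class `ema_generator_config`.
#' @export
ema_generator_config <- function(n_participants = 780L,
                                 subsample_probs = c(
                                   suicidal_ideation = 0.214,
                                   alcohol = 0.299,
                                   anxiety_depression = 0.263,
                                   control = 0.224
                                 ),
                                 sigma2_between = c(pa = 0.94, na = 0.88),
                                 sigma2_within = c(pa = 0.81, na = 0.80),
                                 affect_correlation = -0.5,
                                 ar1_affect = 0,
                                 item_variance_components = c(
                                   sigma2_item = 0.05,
                                   sigma2_person_item = 0.10,
                                   sigma2_error = 3.0
                                 ),
                                 mean_compliance = 0.769,
                                 compliance_sd = 0.277,
                                 compliance_day_slope = -0.005,
                                 careless_fraction_fast = 0.0013,
                                 careless_fraction_straightline = 0.0078,
                                 careless_cluster_size = 8L,
                                 latency_median_minutes = 15,
                                 tpi_median_seconds = 3.9,
                                 tpi_sdlog = 0.35,
                                 covariate_probs = NULL,
                                 seed = 1L) {
  if (!is_count(n_participants) || n_participants < 1) {
    stop_emaqc("configuration error: n_participants must be a positive count")
  }
  if (length(subsample_probs) != 4L || !is_prob(subsample_probs) ||
      abs(sum(subsample_probs) - 1) > 1e-8) {
    stop_emaqc("configuration error: subsample_probs must be 4 probabilities summing to 1")
  }
  if (any(sigma2_between < 0) || any(sigma2_within < 0)) {
    stop_emaqc("configuration error: variances must be >= 0")
  }
  if (!is_prob(mean_compliance)) stop_emaqc("configuration error: mean_compliance must be in [0,1]")
  if (compliance_day_slope > 0) stop_emaqc("configuration error: compliance_day_slope must be <= 0")
  if (!is_prob(careless_fraction_fast) || !is_prob(careless_fraction_straightline)) {
    stop_emaqc("configuration error: careless fractions must be in [0,1]")
  }
  if (abs(affect_correlation) > 1) stop_emaqc("configuration error: affect_correlation must be in [-1,1]")
  if (abs(ar1_affect) >= 1) stop_emaqc("configuration error: ar1_affect must be in (-1,1)")
  if (is.null(covariate_probs)) {
    covariate_probs <- list(
      sex = c(male = 0.229, female = 0.771),
      nationality = c(spanish = 0.918, other = 0.082),
      age_group = c("18-21" = 0.710, "22-25" = 0.236, "26-29" = 0.029, ">=30" = 0.025),
      field_of_study = c(
        arts_humanities = 0.122, sciences = 0.112, health_sciences = 0.266,
        social_legal = 0.373, engineering_architecture = 0.127
      )
    )
  }
  for (nm in names(covariate_probs)) {
    p <- covariate_probs[[nm]]
    if (!is_prob(p) || abs(sum(p) - 1) > 1e-6 || is.null(names(p))) {
      stop_emaqc("configuration error: covariate_probs$%s must be a named probability vector summing to 1", nm)
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      subsample_probs = subsample_probs,
      sigma2_between = sigma2_between,
      sigma2_within = sigma2_within,
      affect_correlation = affect_correlation,
      ar1_affect = ar1_affect,
      item_variance_components = item_variance_components,
      mean_compliance = mean_compliance,
      compliance_sd = compliance_sd,
      compliance_day_slope = compliance_day_slope,
      careless_fraction_fast = careless_fraction_fast,
      careless_fraction_straightline = careless_fraction_straightline,
      careless_cluster_size = as.integer(careless_cluster_size),
      latency_median_minutes = latency_median_minutes,
      tpi_median_seconds = tpi_median_seconds,
      tpi_sdlog = tpi_sdlog,
      covariate_probs = covariate_probs,
      seed = as.integer(seed)
    ),
    class = "ema_generator_config"
  )
}

#' @export
print.ema_generator_config <- function(x, ...) {
  cat(sprintf(
    "<ema_generator_config> n=%d, mean compliance %.1f%% (slope %+.3f/day), sigma2 B/W: PA %.2f/%.2f NA %.2f/%.2f, careless fast/straight %.2f%%/%.2f%% in cluster of %d, seed %d\n",
    x$n_participants, 100 * x$mean_compliance, x$compliance_day_slope,
    x$sigma2_between[["pa"]], x$sigma2_within[["pa"]],
    x$sigma2_between[["na"]], x$sigma2_within[["na"]],
    100 * x$careless_fraction_fast, 100 * x$careless_fraction_straightline,
    x$careless_cluster_size, x$seed
  ))
  invisible(x)
}
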