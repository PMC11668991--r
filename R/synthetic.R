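#' Generate a synthetic participant cohort
#'
#' Draws `n_participants` invited participants, assigns each to one of the four
#' quota subsamples (suicidal ideation, harmful alcohol use, anxiety or
#' depression, control) and samples the four sociodemographic covariates from
#' the configured categorical distributions. Participation status, completed
#' counts and compliance are filled in once responses exist (see
#' [generate_ema_dataset()]).
#'
#' @param config an [ema_generator_config()].
#' @param design an [ema_design()].
#' @return A data frame (one row per participant) with person_id, invited,
#'   participated, subsample, covariates, n_completed and compliance.
#' @export
generate_cohort <- function(config, design = ema_design()) {
  stopifnot(inherits(config, "ema_generator_config"), inherits(design, "ema_design"))
  n <- config$n_participants
  with_seed(derive_seed(config$seed, 11L), {
    subsample <- sample(names(config$subsample_probs), n, replace = TRUE,
                        prob = config$subsample_probs)
    covs <- lapply(config$covariate_probs, function(p) {
      sample(names(p), n, replace = TRUE, prob = p)
    })
    out <- data.frame(
      person_id = sprintf("p%05d", seq_len(n)),
      invited = TRUE,
      participated = NA,
      subsample = subsample,
      stringsAsFactors = FALSE
    )
    for (nm in names(covs)) out[[nm]] <- covs[[nm]]
    out$n_completed <- NA_integer_
    out$compliance <- NA_real_
    out
  })
}

#' Generate the prompt schedule
#'
#' One row per person x day x window, with the prompt delivered at a uniformly
#' random moment within its window, a reminder after `reminder_minutes`, and
#' expiry at `window_length_minutes` after the prompt. Every person receives
#' exactly `max_prompts(design)` rows.
#'
#' @param cohort a cohort table (needs a `person_id` column).
#' @param design an [ema_design()].
#' @param seed integer seed for the prompt-time stream.
#' @param start_date calendar date of the first EMA day.
#' @return A data frame with person_id, day, window, prompt_time,
#'   reminder_time, expiry_time (POSIXct, UTC) and n_items.
#' @export
generate_prompt_schedule <- function(cohort, design = ema_design(), seed = 1L,
                                     start_date = as.Date("2022-04-04")) {
  stopifnot(inherits(design, "ema_design"))
  ids <- cohort$person_id
  grid <- expand.grid(
    window = seq_len(design$prompts_per_day),
    day = seq_len(design$n_ema_days),
    person_id = ids,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )[, c("person_id", "day", "window")]
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  with_seed(derive_seed(seed, 17L), {
    offset_min <- stats::runif(nrow(grid), 0, design$window_length_minutes)
    prompt <- origin + (grid$day - 1) * 86400 +
      design$window_starts[grid$window] * 3600 + offset_min * 60
    grid$prompt_time <- prompt
    grid$reminder_time <- prompt + design$reminder_minutes * 60
    grid$expiry_time <- prompt + design$window_length_minutes * 60
    grid$n_items <- design$n_items_by_window[grid$window]
    grid
  })
}

# bivariate normal deviates with given variances and correlation
rbinorm <- function(n, v1, v2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  cbind(sqrt(v1) * z1, sqrt(v2) * z2)
}

#' Generate momentary responses for a prompt schedule
#'
#' Each prompt is completed or missed. Completion is Bernoulli with a
#' person-specific probability (beta-distributed across persons with mean
#' `mean_compliance` and SD `compliance_sd`) plus a centred linear day trend
#' of `compliance_day_slope` per day. Completed assessments carry 12 integer
#' item responses built from a latent two-level affect model: person intercept
#' (variance `sigma2_between`) plus momentary deviation (variance
#' `sigma2_within`) around the scale midpoint, PA items loading on the PA
#' latent and NA items (and the stress/energy/concentration items) on the NA
#' latent, plus item, person-by-item and residual noise
#' (`item_variance_components`), rounded and clamped to the Likert range.
#'
#' Timestamps give a lognormal prompt-to-start latency (median
#' `latency_median_minutes`) and a lognormal time-per-item (median
#' `tpi_median_seconds`), truncated so completed assessments end before
#' expiry. Careless behaviour is injected into completed assessments: "fast"
#' ones get a time per item below 1 s, "straight-lined" ones get all 12 common
#' items set to a single value; injections fill the designated cluster
#' participants first, then spread uniformly.
#'
#' @param prompts a prompt schedule from [generate_prompt_schedule()].
#' @param config an [ema_generator_config()].
#' @param design an [ema_design()].
#' @return The prompt table augmented with completed, start/end times, item
#'   responses, pa_score, na_score, and the ground-truth columns
#'   injected_careless, latent_pa, latent_na (split out by
#'   [write_ema_dataset()]).
#' @export
generate_responses <- function(prompts, config, design = ema_design()) {
  stopifnot(inherits(config, "ema_generator_config"), inherits(design, "ema_design"))
  ids <- unique(prompts$person_id)
  np <- length(ids)
  n <- nrow(prompts)
  pidx <- match(prompts$person_id, ids)
  rho <- config$affect_correlation

  with_seed(derive_seed(config$seed, 29L), {
    ## person-level draws -------------------------------------------------
    m <- config$mean_compliance
    s2 <- config$compliance_sd^2
    p_person <- if (s2 == 0) {
      rep(m, np)
    } else {
      if (s2 >= m * (1 - m)) stop_emaqc("configuration error: compliance_sd too large for mean_compliance")
      nu <- m * (1 - m) / s2 - 1
      stats::rbeta(np, m * nu, (1 - m) * nu)
    }
    b <- rbinorm(np, config$sigma2_between[["pa"]], config$sigma2_between[["na"]], rho)

    ## completion ---------------------------------------------------------
    day_centre <- (design$n_ema_days + 1) / 2
    p_complete <- clamp(p_person[pidx] + config$compliance_day_slope * (prompts$day - day_centre), 0, 1)
    completed <- stats::runif(n) < p_complete

    ## latent affect and items --------------------------------------------
    phi <- config$ar1_affect %||% 0
    if (phi == 0) {
      w <- rbinorm(n, config$sigma2_within[["pa"]], config$sigma2_within[["na"]], rho)
    } else {
      # AR(1) momentary deviations across each person's prompt sequence,
      # scaled so the stationary variance stays at sigma2_within
      TT <- design$n_ema_days * design$prompts_per_day
      tidx <- (prompts$day - 1) * design$prompts_per_day + prompts$window
      e_pa <- matrix(stats::rnorm(np * TT), TT, np)
      e_na <- rho * e_pa + sqrt(max(0, 1 - rho^2)) * matrix(stats::rnorm(np * TT), TT, np)
      wpa <- e_pa; wna <- e_na
      for (t in seq_len(TT)[-1]) {
        wpa[t, ] <- phi * wpa[t - 1, ] + sqrt(1 - phi^2) * e_pa[t, ]
        wna[t, ] <- phi * wna[t - 1, ] + sqrt(1 - phi^2) * e_na[t, ]
      }
      w <- cbind(sqrt(config$sigma2_within[["pa"]]) * wpa[cbind(tidx, pidx)],
                 sqrt(config$sigma2_within[["na"]]) * wna[cbind(tidx, pidx)])
    }
    mid <- (design$likert_min + design$likert_max) / 2
    latent_pa <- mid + b[pidx, 1] + w[, 1]
    latent_na <- mid + b[pidx, 2] + w[, 2]

    ivc <- config$item_variance_components
    k <- design$n_items_common
    item_eff <- stats::rnorm(k, 0, sqrt(ivc[["sigma2_item"]]))
    pi_eff <- matrix(stats::rnorm(np * k, 0, sqrt(ivc[["sigma2_person_item"]])), np, k)
    is_pa_item <- design$item_ids %in% design$pa_items
    items <- matrix(NA_integer_, n, k, dimnames = list(NULL, design$item_ids))
    ci <- which(completed)
    for (j in seq_len(k)) {
      lat <- if (is_pa_item[j]) latent_pa else latent_na
      y <- lat[ci] + item_eff[j] + pi_eff[cbind(pidx[ci], j)] +
        stats::rnorm(length(ci), 0, sqrt(ivc[["sigma2_error"]]))
      items[ci, j] <- as.integer(clamp(round(y), design$likert_min, design$likert_max))
    }

    ## timestamps ----------------------------------------------------------
    tpi <- rep(NA_real_, n)
    tpi[ci] <- stats::rlnorm(length(ci), log(config$tpi_median_seconds), config$tpi_sdlog)
    latency_min <- rep(NA_real_, n)
    latency_min[ci] <- stats::rlnorm(length(ci), log(config$latency_median_minutes), 0.9)

    ## careless injection ---------------------------------------------------
    injected <- rep("none", n)
    n_fast <- round(config$careless_fraction_fast * length(ci))
    n_straight <- round(config$careless_fraction_straightline * length(ci))
    if (n_fast + n_straight > 0 && length(ci) > 0) {
      cluster_ids <- sample(ids, min(config$careless_cluster_size, np))
      in_cluster <- ci[prompts$person_id[ci] %in% cluster_ids]
      rest <- setdiff(ci, in_cluster)
      shuffle <- function(x) x[sample.int(length(x))]
      pool <- c(shuffle(in_cluster), shuffle(rest))
      take <- pool[seq_len(min(n_fast + n_straight, length(pool)))]
      straight <- take[seq_len(min(n_straight, length(take)))]
      fast <- setdiff(take, straight)
      if (length(straight) > 0) {
        pick <- items[cbind(straight, sample.int(k, length(straight), replace = TRUE))]
        items[straight, ] <- matrix(pick, length(straight), k)
        injected[straight] <- "straightline"
      }
      if (length(fast) > 0) {
        tpi[fast] <- stats::runif(length(fast), 0.2, 0.95)
        injected[fast] <- "fast"
      }
    }

    ## assemble -------------------------------------------------------------
    duration_s <- tpi * prompts$n_items
    # completed assessments must end before expiry
    max_latency <- design$window_length_minutes - duration_s / 60 - 0.5
    latency_min <- pmin(latency_min, pmax(max_latency, 0.1))
    out <- prompts
    out$completed <- as.integer(completed)
    out$start_time <- out$prompt_time + latency_min * 60
    out$end_time <- out$start_time + duration_s
    out$start_time[!completed] <- as.POSIXct(NA)
    out$end_time[!completed] <- as.POSIXct(NA)
    for (j in seq_len(k)) out[[design$item_ids[j]]] <- items[, j]
    out$pa_score <- rowMeans(items[, design$pa_items, drop = FALSE])
    out$na_score <- rowMeans(items[, design$na_items, drop = FALSE])
    out$injected_careless <- injected
    out$latent_pa <- ifelse(completed, latent_pa, NA_real_)
    out$latent_na <- ifelse(completed, latent_na, NA_real_)
    out
  })
}

#' Generate a complete synthetic EMA dataset
#'
#' Runs [generate_cohort()], [generate_prompt_schedule()] and
#' [generate_responses()] under one seed and fills the cohort's participation
#' and compliance columns from the realized responses (participated = at
#' least one completed assessment).
#'
#' @inheritParams generate_cohort
#' @return A list with elements `participants`, `assessments` (ground-truth
#'   columns removed) and `truth` (person_id, day, window, injected_careless,
#'   latent_pa, latent_na).
#' @export
generate_ema_dataset <- function(config = ema_generator_config(), design = ema_design()) {
  cohort <- generate_cohort(config, design)
  prompts <- generate_prompt_schedule(cohort, design, seed = config$seed)
  resp <- generate_responses(prompts, config, design)
  ncomp <- tapply(resp$completed, resp$person_id, sum)
  cohort$n_completed <- as.integer(ncomp[cohort$person_id])
  cohort$compliance <- cohort$n_completed / max_prompts(design)
  cohort$participated <- cohort$n_completed > 0
  truth_cols <- c("injected_careless", "latent_pa", "latent_na")
  list(
    participants = cohort,
    assessments = resp[, setdiff(names(resp), truth_cols)],
    truth = resp[, c("person_id", "day", "window", truth_cols)]
  )
}

#' Simulate continuous two-level scores
#'
#' Draws a balanced person-by-occasion table of continuous scores from a
#' random-intercept model: score = mean + person intercept (variance
#' `sigma2_between`) + occasion deviation (variance `sigma2_within`). Used for
#' variance-decomposition recovery checks.
#'
#' @param n_persons,n_occasions design size.
#' @param sigma2_between,sigma2_within variance components on the score scale.
#' @param mean grand mean.
#' @param seed integer seed.
#' @return Long data frame with person_id, occasion, score.
#' @export
simulate_two_level_scores <- function(n_persons, n_occasions,
                                      sigma2_between, sigma2_within,
                                      mean = 4, seed = 1L) {
  with_seed(derive_seed(seed, 41L), {
    b <- stats::rnorm(n_persons, 0, sqrt(sigma2_between))
    data.frame(
      person_id = rep(sprintf("p%05d", seq_len(n_persons)), each = n_occasions),
      occasion = rep(seq_len(n_occasions), n_persons),
      score = mean + rep(b, each = n_occasions) +
        stats::rnorm(n_persons * n_occasions, 0, sqrt(sigma2_within))
    )
  })
}

#' Simulate item responses from stated three-level variance components
#'
#' Generates a balanced person x occasion x item table from the additive
#' model: response = mean + person + time-within-person + item +
#' person-by-item + residual, with the stated variances. Optionally
#' discretized to the Likert range.
#'
#' @param n_persons,n_occasions,n_items design size.
#' @param components named vector/list with sigma2_person,
#'   sigma2_time_in_person, sigma2_item, sigma2_person_item, sigma2_error.
#' @param mean grand mean.
#' @param discretize round and clamp to `likert` range.
#' @param likert integer bounds used when `discretize = TRUE`.
#' @param seed integer seed.
#' @return Long data frame with person_id, occasion, item, response.
#' @export
simulate_item_responses <- function(n_persons, n_occasions, n_items, components,
                                    mean = 4, discretize = FALSE,
                                    likert = c(1L, 7L), seed = 1L) {
  cm <- as.list(components)
  with_seed(derive_seed(seed, 53L), {
    P <- stats::rnorm(n_persons, 0, sqrt(cm$sigma2_person))
    TP <- matrix(stats::rnorm(n_persons * n_occasions, 0, sqrt(cm$sigma2_time_in_person)),
                 n_persons, n_occasions)
    I <- stats::rnorm(n_items, 0, sqrt(cm$sigma2_item))
    PI <- matrix(stats::rnorm(n_persons * n_items, 0, sqrt(cm$sigma2_person_item)),
                 n_persons, n_items)
    g <- expand.grid(item = seq_len(n_items), occasion = seq_len(n_occasions),
                     person = seq_len(n_persons), KEEP.OUT.ATTRS = FALSE)
    y <- mean + P[g$person] + TP[cbind(g$person, g$occasion)] + I[g$item] +
      PI[cbind(g$person, g$item)] +
      stats::rnorm(nrow(g), 0, sqrt(cm$sigma2_error))
    if (discretize) y <- clamp(round(y), likert[1], likert[2])
    data.frame(
      person_id = sprintf("p%05d", g$person),
      occasion = g$occasion,
      item = sprintf("item_%02d", g$item),
      response = y
    )
  })
}
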