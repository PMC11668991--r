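test_that("study design arithmetic and invariants hold", {
  d <- ema_design()
  expect_equal(max_prompts(d), 56)
  expect_length(intersect(d$pa_items, d$na_items), 0)
  expect_true(all(c(d$pa_items, d$na_items) %in% d$item_ids))
  d3 <- ema_design(n_ema_days = 3L, prompts_per_day = 1L, window_starts = 8L,
                   n_items_by_window = 12L)
  expect_equal(max_prompts(d3), 3)
  expect_error(ema_design(likert_min = 7L, likert_max = 1L), "likert_min")
  expect_error(ema_design(pa_items = c("item_01", "nope")), "subsets")
})

test_that("cohort generation respects subsample probabilities and is deterministic", {
  cfg1 <- ema_generator_config(n_participants = 100,
                               subsample_probs = c(suicidal_ideation = 1, alcohol = 0,
                                                   anxiety_depression = 0, control = 0),
                               seed = 5)
  co <- generate_cohort(cfg1)
  expect_equal(nrow(co), 100)
  expect_true(all(co$subsample == "suicidal_ideation"))

  cfg <- ema_generator_config(n_participants = 10000, seed = 99)
  co <- generate_cohort(cfg)
  shares <- table(co$subsample) / nrow(co)
  expect_lt(abs(shares[["suicidal_ideation"]] - 0.214), 0.02)
  expect_lt(abs(shares[["alcohol"]] - 0.299), 0.02)
  expect_lt(abs(shares[["anxiety_depression"]] - 0.263), 0.02)
  expect_lt(abs(shares[["control"]] - 0.224), 0.02)

  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(ema_generator_config(subsample_probs = c(0.5, 0.5, 0.5, 0.5)),
               "configuration error")
})

test_that("prompt schedule has one row per person-day-window inside its window", {
  d <- ema_design()
  co <- generate_cohort(ema_generator_config(n_participants = 1, seed = 3))
  sch <- generate_prompt_schedule(co, d, seed = 3)
  expect_equal(nrow(sch), 56)
  hrs <- as.numeric(format(sch$prompt_time, "%H", tz = "UTC")) +
    as.numeric(format(sch$prompt_time, "%M", tz = "UTC")) / 60
  start_hr <- d$window_starts[sch$window]
  expect_true(all(hrs >= start_hr & hrs < start_hr + d$window_length_minutes / 60))
  expect_equal(as.numeric(difftime(sch$expiry_time, sch$prompt_time, units = "mins")),
               rep(120, 56))
  expect_equal(as.numeric(difftime(sch$reminder_time, sch$prompt_time, units = "mins")),
               rep(30, 56))

  d3 <- ema_design(n_ema_days = 3L, prompts_per_day = 1L, window_starts = 8L,
                   n_items_by_window = 12L)
  expect_equal(nrow(generate_prompt_schedule(co, d3, seed = 1)), 3)
})

test_that("generated responses match the stated compliance world", {
  # full completion when mean_compliance = 1 and no day trend
  cfg <- ema_generator_config(n_participants = 20, mean_compliance = 1,
                              compliance_sd = 0, compliance_day_slope = 0, seed = 2)
  ds <- generate_ema_dataset(cfg)
  expect_true(all(ds$participants$compliance == 1))

  # defaults at study scale: realized mean compliance within 3 points of 76.9%
  ds <- generate_ema_dataset(ema_generator_config(n_participants = 780, seed = 11))
  expect_lt(abs(mean(ds$participants$compliance) - 0.769), 0.03)

  # negative day slope: first-week completion above last-week completion,
  # and the fitted per-day trend is negative
  byday <- compliance_by_day(ds$assessments)
  expect_lt(byday$slope, 0)
  expect_gt(mean(byday$by_day$prop[1:7]), mean(byday$by_day$prop[8:14]))
})

test_that("careless injections behave as configured", {
  d <- ema_design()
  # zero injection: nothing satisfies the careless-response rule
  qs <- small_enriched(n = 60, seed = 17, careless_fraction_fast = 0,
                       careless_fraction_straightline = 0)
  fl <- flag_careless_responses(qs$assessments)
  expect_equal(attr(fl, "careless_summary")$n_flagged, 0)

  # default injection: straight-lined assessments have SD exactly 0 and the
  # injected labels agree with the realized item patterns
  qs <- small_enriched(n = 150, seed = 23)
  joined <- merge(qs$assessments, qs$truth, by = c("person_id", "day", "window"))
  st <- joined[joined$injected_careless == "straightline", ]
  expect_gt(nrow(st), 0)
  expect_true(all(st$sd_items == 0))
  fa <- joined[joined$injected_careless == "fast", ]
  expect_gt(nrow(fa), 0)
  expect_true(all(fa$time_per_item < 1))
  # completed assessments end before expiry
  comp <- qs$assessments[qs$assessments$completed == 1, ]
  expect_true(all(comp$end_time <= comp$expiry_time))
  expect_true(all(comp$start_time > comp$prompt_time))
})

test_that("optional AR(1) momentary deviations keep the stationary variance", {
  qs0 <- small_enriched(n = 120, seed = 37, mean_compliance = 1, compliance_sd = 0,
                        compliance_day_slope = 0)
  qs1 <- small_enriched(n = 120, seed = 37, mean_compliance = 1, compliance_sd = 0,
                        compliance_day_slope = 0, ar1_affect = 0.5)
  lag1 <- function(tr) {
    mean(vapply(split(tr$latent_pa, tr$person_id), function(x) {
      stats::cor(x[-1], x[-length(x)])
    }, numeric(1)))
  }
  # exchangeable default: no autocorrelation; AR knob induces it
  expect_lt(abs(lag1(qs0$truth)), 0.05)
  expect_gt(lag1(qs1$truth), 0.3)
  # stationary within-person variance unchanged by the AR term
  est <- decompose_two_level(qs1$truth, score_col = "latent_pa")
  expect_lt(abs(est$sigma2_within - 0.81), 0.08)
})

test_that("latent two-level structure of the generator is recoverable", {
  # the truth table carries the continuous latents: REML recovers the
  # configured between/within variances at simulation tolerance
  qs <- small_enriched(n = 250, seed = 31)
  tr <- qs$truth[!is.na(qs$truth$latent_pa), ]
  est <- decompose_two_level(tr, score_col = "latent_pa")
  expect_lt(abs(est$sigma2_between - 0.94), 0.15)
  expect_lt(abs(est$sigma2_within - 0.81), 0.06)
  est_na <- decompose_two_level(tr, score_col = "latent_na")
  expect_lt(abs(est_na$sigma2_between - 0.88), 0.15)
  expect_lt(abs(est_na$sigma2_within - 0.80), 0.06)
})
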