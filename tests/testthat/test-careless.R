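test_that("antonym selection returns the most negative pair (brute-force check)", {
  qs <- small_enriched(n = 120, seed = 41)
  ant <- select_antonyms(qs$assessments)
  comp <- qs$assessments[qs$assessments$completed == 1, sprintf("item_%02d", 1:12)]
  cm <- cor(comp)
  diag(cm) <- NA
  expect_equal(ant$r, min(cm, na.rm = TRUE))
  idx <- which(cm == min(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_setequal(ant$items, colnames(cm)[idx])
  # PA/NA latents are negatively correlated, so the pair crosses the scales
  d <- ema_design()
  expect_true((ant$items[1] %in% d$pa_items) != (ant$items[2] %in% d$pa_items))
})

test_that("antonym selection handles constructed and degenerate batteries", {
  set.seed(3)
  x <- sample(1:7, 200, TRUE)
  a <- data.frame(completed = 1, item_a = x, item_b = 8 - x,
                  item_c = sample(1:7, 200, TRUE), item_d = 4)
  expect_message(
    ant <- select_antonyms(a, items = c("item_a", "item_b", "item_c", "item_d")),
    "constant items"
  )
  expect_setequal(ant$items, c("item_a", "item_b"))
  expect_equal(ant$r, -1)
  # no negatively correlated pair exists: warns that no antonyms were found
  set.seed(4)
  i1 <- sample(1:7, 500, TRUE)
  b <- data.frame(completed = 1, i1 = i1,
                  i2 = pmin(7, pmax(1, i1 + sample(-1:1, 500, TRUE))))
  expect_warning(select_antonyms(b, items = c("i1", "i2")), "no psychometric antonyms")
  # independent items: most negative correlation is near zero
  set.seed(5)
  ind <- data.frame(completed = 1, i1 = sample(1:7, 3000, TRUE),
                    i2 = sample(1:7, 3000, TRUE), i3 = sample(1:7, 3000, TRUE))
  ant0 <- suppressWarnings(select_antonyms(ind, items = c("i1", "i2", "i3")))
  expect_lt(abs(ant0$r), 0.05)
  expect_error(select_antonyms(a[1:2, ], items = c("item_a", "item_b")), ">= 3 completed")
})

test_that("threshold curves restrict to the suspicious side and hit exact limits", {
  qs <- small_enriched(n = 120, seed = 41)
  a <- qs$assessments
  ant <- select_antonyms(a)
  # no restriction: r_below equals the full-sample antonym correlation
  curve <- antonym_threshold_curve(a, "time_per_item", c(1, Inf), ant)
  expect_equal(curve$r_below[curve$threshold == Inf], ant$r)
  expect_equal(curve$share_below[curve$threshold == Inf], 1)
  expect_true(all(diff(curve$n_below) >= 0))
  # straight-lined subset: antonym values are forced equal within every
  # assessment, so the correlation is exactly 1 when values vary across them
  sd_curve <- antonym_threshold_curve(a, "sd_items", c(0, 0.5, 1), ant)
  sub <- a[a$completed == 1 & a$sd_items == 0, ]
  if (nrow(sub) >= 3 && var(sub[[ant$items[1]]]) > 0) {
    expect_equal(sd_curve$r_below[sd_curve$threshold == 0], 1)
  }
  # pct_mode uses >= threshold
  pm_curve <- antonym_threshold_curve(a, "pct_mode", c(0.6, 0.8, 1), ant)
  expect_true(all(diff(pm_curve$n_below) <= 0))
  n_at_1 <- sum(a$completed == 1 & a$pct_mode == 1)
  expect_equal(pm_curve$n_below[pm_curve$threshold == 1], n_at_1)
  # empty subset yields missing, not an error
  tiny <- antonym_threshold_curve(a, "time_per_item", 0.001, ant)
  expect_true(is.na(tiny$r_below))
})

test_that("careless response flags implement the fast-or-zero-variance rule", {
  base <- data.frame(
    person_id = "p1", completed = 1,
    time_per_item = c(0.9, 3.9, 3.9, 0.5),
    sd_items = c(1.4, 0, 1.2, 0)
  )
  fl <- flag_careless_responses(base)
  expect_equal(fl$careless_flag, c("fast", "straightline", "none", "both"))
  s <- attr(fl, "careless_summary")
  expect_equal(s$n_flagged, 3)
  expect_equal(s$n_both, 1)
  # missed assessments never flagged
  missed <- data.frame(person_id = "p1", completed = 0,
                       time_per_item = NA_real_, sd_items = NA_real_)
  expect_equal(flag_careless_responses(missed)$careless_flag, "none")
})

test_that("flagging is monotone in the time-per-item threshold", {
  qs <- small_enriched(n = 100, seed = 59)
  counts <- vapply(c(0.5, 1, 2, 4), function(th) {
    attr(flag_careless_responses(qs$assessments,
                                 careless_config(tpi_threshold_seconds = th)),
         "careless_summary")$n_flagged
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # flagged with positive dispersion must be fast
  fl <- flag_careless_responses(qs$assessments)
  flagged_varied <- fl$careless_flag != "none" & fl$sd_items > 0
  expect_true(all(fl$time_per_item[flagged_varied] <= 1))
})

test_that("stability curves hit the identity limit and rise with subset size", {
  qs <- small_enriched(n = 80, seed = 67, mean_compliance = 0.9)
  cfg <- careless_config(subset_sizes = c(2, 5, 10, 20, 40))
  sc <- minimum_valid_assessments(qs$assessments, cfg, seed = 5)
  # subset = gold standard: all four agreements exactly 1
  at_max <- sc$curve$icc[sc$curve$subset_size == 40]
  expect_equal(at_max, rep(1, 4), tolerance = 1e-12)
  # agreement for the mean rises with subset size (monotone in expectation)
  mean_pa <- sc$curve$icc[sc$curve$statistic == "mean" & sc$curve$scale == "pa"]
  expect_true(all(diff(mean_pa) > -0.02))
  expect_gt(mean_pa[4], mean_pa[1])
  expect_error(
    minimum_valid_assessments(qs$assessments[qs$assessments$person_id %in% "p00001", ], cfg),
    "fewer than 3 persons"
  )
})

test_that("responder flags combine the minimum-valid and alpha-floor rules", {
  persons <- data.frame(person_id = c("p1", "p2", "p3", "p4"))
  assess <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(id) {
    data.frame(person_id = id, completed = 1,
               time_per_item = 3.9, sd_items = 1.1,
               careless_flag = "none")[rep(1, 56), ]
  }))
  assess$careless_flag[assess$person_id == "p4"][1:40] <- "straightline"
  alpha <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                      alpha_pa = c(0.9, 0.9, 0.9, NA),
                      alpha_na = c(0.9, -0.2, 0.9, NA))
  out <- flag_careless_responders(persons, assess, alpha, minimum = 25)
  expect_equal(out$responder_flag, c("none", "low_alpha", "none", "low_valid"))
  expect_equal(out$n_valid, c(56, 56, 56, 16))
  expect_true(out$alpha_missing[4])
  # invariants: n_careless + n_valid = n_completed
  expect_equal(out$n_careless + out$n_valid, out$n_completed)
  # stricter configurations flag a superset
  strict <- flag_careless_responders(persons, assess, alpha, minimum = 57,
                                     careless_config(alpha_floor = 0.95))
  expect_true(all(which(out$responder_flag != "none") %in%
                    which(strict$responder_flag != "none")))
  expect_gt(sum(strict$responder_flag != "none"), sum(out$responder_flag != "none"))
})

test_that("injected careless cluster is detected with positive sensitivity", {
  qs <- small_enriched(n = 150, seed = 71, careless_fraction_fast = 0.01,
                       careless_fraction_straightline = 0.02)
  fl <- flag_careless_responses(qs$assessments)
  joined <- merge(fl, qs$truth, by = c("person_id", "day", "window"))
  injected <- joined$injected_careless != "none"
  flagged <- joined$careless_flag != "none"
  sens <- sum(flagged & injected) / sum(injected)
  expect_gt(sens, 0.9) # the rule targets exactly the injected patterns
  # persons carrying injections are enriched among flagged persons
  inj_persons <- unique(joined$person_id[injected])
  fl_persons <- unique(joined$person_id[flagged])
  expect_gt(length(intersect(fl_persons, inj_persons)), 0)
})
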