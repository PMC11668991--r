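test_that("ICC from components reproduces the printed worked examples", {
  expect_equal(icc_from_components(0.94, 0.81, digits = 2), 0.54)
  expect_equal(icc_from_components(0.88, 0.80, digits = 2), 0.52)
  expect_equal(icc_from_components(0.42, 0.50, digits = 2), 0.46)
  expect_equal(icc_from_components(1, 1), 0.5)
  expect_warning(out <- icc_from_components(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(icc_from_components(-0.1, 0.5), ">= 0")
  # invariance: ICC unmoved by adding a constant or positive rescaling of scores
  # (variances shift as c^2 on both components)
  expect_equal(icc_from_components(0.94 * 4, 0.81 * 4), icc_from_components(0.94, 0.81))
})

test_that("two-level REML matches the balanced expected-mean-squares oracle", {
  set.seed(100)
  toy <- data.frame(
    person_id = rep(c("a", "b", "c"), each = 4),
    score = c(5.1, 4.8, 5.4, 5.0, 2.2, 2.6, 1.9, 2.4, 3.8, 4.1, 3.6, 4.0)
  )
  est <- decompose_two_level(toy, "score")
  oracle <- ems_two_level(toy, "score")
  expect_equal(est$sigma2_between, oracle$sigma2_between, tolerance = 1e-6)
  expect_equal(est$sigma2_within, oracle$sigma2_within, tolerance = 1e-6)

  # degenerate: persons constant at different levels
  flat <- data.frame(person_id = rep(c("a", "b", "c"), each = 3),
                     score = rep(c(1, 4, 7), each = 3))
  est <- decompose_two_level(flat, "score")
  expect_equal(est$sigma2_within, 0)
  expect_equal(est$icc, 1)
  # all constant
  const <- data.frame(person_id = rep(c("a", "b"), each = 3), score = 2)
  est <- decompose_two_level(const, "score")
  expect_equal(est$sigma2_between + est$sigma2_within, 0)
})

test_that("two-level REML recovers generating components on simulated data", {
  d <- simulate_two_level_scores(400, 30, 0.94, 0.81, seed = 9)
  est <- decompose_two_level(d)
  expect_lt(abs(est$sigma2_between - 0.94), 0.12)
  expect_lt(abs(est$sigma2_within - 0.81), 0.04)
  expect_lt(abs(est$icc - 0.94 / 1.75), 0.03)
})

test_that("three-level REML matches the balanced method-of-moments oracle", {
  comps <- list(sigma2_person = 1.2, sigma2_time_in_person = 0.6, sigma2_item = 0.3,
                sigma2_person_item = 0.4, sigma2_error = 0.5)
  d <- simulate_item_responses(15, 10, 4, comps, seed = 8)
  est <- decompose_three_level(d)
  oracle <- ems_three_level(d)
  # REML equals ANOVA estimators on balanced data when all estimates interior
  for (nm in names(oracle)) {
    expect_gt(oracle[[nm]], 0)
    expect_equal(est[[nm]], oracle[[nm]], tolerance = 1e-4)
  }
  expect_equal(est$n, 10) # harmonic mean reduces to the common n

  # additively constructed fixture without item or person-item effects
  comps0 <- list(sigma2_person = 1, sigma2_time_in_person = 0.5, sigma2_item = 0,
                 sigma2_person_item = 0, sigma2_error = 0.4)
  d0 <- simulate_item_responses(25, 12, 4, comps0, seed = 15)
  est0 <- decompose_three_level(d0)
  expect_lt(est0$sigma2_item, 0.02)
  expect_lt(est0$sigma2_person_item, 0.02)
  expect_lt(abs(est0$sigma2_person - 1), 0.35)
  expect_lt(abs(est0$sigma2_error - 0.4), 0.03)

  # all responses identical -> every component zero
  dc <- d0
  dc$response <- 3
  estc <- decompose_three_level(dc)
  expect_equal(estc$sigma2_person + estc$sigma2_time_in_person + estc$sigma2_item +
                 estc$sigma2_person_item + estc$sigma2_error, 0)
})

test_that("Shrout-Lane reliabilities follow the closed form and its limits", {
  comps <- list(sigma2_person = 1.0, sigma2_time_in_person = 0.5, sigma2_item = 0.1,
                sigma2_person_item = 0.2, sigma2_error = 0.6)
  rep_ <- multilevel_reliability(comps, k = 5, n = 40)
  r_krn_hand <- (1.0 + 0.2 / 5) / (1.0 + 0.2 / 5 + 0.5 / 40 + 0.6 / (5 * 40))
  r_cn_hand <- 0.5 / (0.5 + 0.6 / 5)
  expect_equal(rep_$r_krn, r_krn_hand)
  expect_equal(rep_$r_cn, r_cn_hand)

  # limits: noise-free within-person reliability is 1; no time variance gives 0
  comps$sigma2_error <- 0
  expect_equal(multilevel_reliability(comps, k = 5, n = 40)$r_cn, 1)
  comps$sigma2_error <- 0.6
  comps$sigma2_time_in_person <- 0
  expect_equal(multilevel_reliability(comps, k = 5, n = 40)$r_cn, 0)

  # monotonicity in n and k with components fixed
  comps <- list(sigma2_person = 1, sigma2_time_in_person = 0.5, sigma2_item = 0.1,
                sigma2_person_item = 0.2, sigma2_error = 0.6)
  r1 <- multilevel_reliability(comps, k = 4, n = 10)
  r2 <- multilevel_reliability(comps, k = 4, n = 30)
  r3 <- multilevel_reliability(comps, k = 8, n = 10)
  expect_gt(r2$r_krn, r1$r_krn)
  expect_gt(r3$r_krn, r1$r_krn)
  expect_gt(r3$r_cn, r1$r_cn)
  expect_error(multilevel_reliability(comps, k = 1, n = 10), "k must be")
})

test_that("reliability bands follow the printed convention", {
  expect_equal(reliability_band(c(0.05, 0.2, 0.5, 0.7, 0.95)),
               c("practically none", "slight", "fair", "moderate", "substantial"))
  expect_equal(reliability_band(0.104), "practically none") # rounds to 0.10
  expect_equal(reliability_band(0.405), "fair")
})

test_that("re-estimating from simulated components reproduces the closed-form reliabilities", {
  comps <- list(sigma2_person = 1.0, sigma2_time_in_person = 0.5, sigma2_item = 0.1,
                sigma2_person_item = 0.2, sigma2_error = 0.6)
  truth <- multilevel_reliability(comps, k = 5, n = 40)
  d <- simulate_item_responses(500, 40, 5, comps, seed = 33)
  est <- decompose_three_level(d)
  rep_ <- multilevel_reliability(est)
  expect_lt(abs(rep_$r_krn - truth$r_krn), 0.03)
  expect_lt(abs(rep_$r_cn - truth$r_cn), 0.03)
})

test_that("per-person raw alpha follows the hand formula and degenerates to missing", {
  # parallel items: identical columns give alpha 1
  m <- cbind(c(1, 3, 5, 7), c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_equal(person_alpha(m), 1)
  # constant responses: no variation, no alpha
  expect_true(is.na(person_alpha(matrix(4, 5, 3))))
  # single occasion: missing
  expect_true(is.na(person_alpha(matrix(c(1, 2, 3), 1, 3))))
  # 4-occasion x 3-item toy matrix against the naive covariance-form oracle
  set.seed(2)
  m <- matrix(sample(1:7, 12, TRUE), 4, 3)
  if (var(rowSums(m)) > 0) {
    expect_equal(person_alpha(m), alpha_bruteforce(m))
  }
  # perfectly anticorrelated items sum to a constant: alpha undefined, missing
  expect_true(is.na(person_alpha(cbind(c(1, 7, 1, 7), c(7, 1, 7, 1)))))
  # negative alpha is allowed when inter-item covariance is negative
  m_neg <- cbind(c(1, 7, 1, 7), c(6, 1, 7, 1))
  expect_lt(person_alpha(m_neg), 0)
  expect_equal(person_alpha(m_neg), alpha_bruteforce(m_neg))
})

test_that("stability ICC agrees with the brute-force two-way ANOVA oracle", {
  # perfect agreement
  m <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(stability_icc(m), 1)
  # hand-constructed 5-person pair table
  m <- cbind(c(3.2, 4.1, 2.8, 5.0, 3.9), c(3.0, 4.4, 2.9, 4.7, 4.2))
  expect_equal(stability_icc(m), icc_a1_bruteforce(m), tolerance = 1e-12)
  # independent columns: near zero at large N
  set.seed(10)
  m <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(stability_icc(m)), 0.05)
  expect_error(stability_icc(m[1:2, ]), ">= 3 persons")
})
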