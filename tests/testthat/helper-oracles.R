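# Independent oracles used across tests. These are deliberately naive
# (explicit mean-squares arithmetic), so they never share code with the
# implementation they check.

# one-way ANOVA expected-mean-squares estimator for a balanced two-level table
ems_two_level <- function(scores, score_col = "score", person_col = "person_id") {
  y <- scores[[score_col]]
  g <- factor(scores[[person_col]])
  n <- unique(table(g))
  stopifnot(length(n) == 1) # balanced only
  N <- nlevels(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  msb <- n * sum((means - grand)^2) / (N - 1)
  msw <- sum((y - means[g])^2) / (N * (n - 1))
  list(sigma2_between = (msb - msw) / n, sigma2_within = msw)
}

# method-of-moments estimator for the balanced person x occasion(within) x item
# design, from the five-way mean-squares identities
ems_three_level <- function(d) {
  per <- as.character(d$person_id)
  occ <- as.character(d$occasion)
  itm <- as.character(d$item)
  y <- d$response
  N <- length(unique(per)); n <- length(unique(occ)); k <- length(unique(itm))
  g <- mean(y)
  pm <- c(tapply(y, per, mean))
  im <- c(tapply(y, itm, mean))
  ptm <- as.matrix(tapply(y, list(per, occ), mean)) # N x n
  pim <- as.matrix(tapply(y, list(per, itm), mean)) # N x k
  msp <- n * k * sum((pm - g)^2) / (N - 1)
  msi <- N * n * sum((im - g)^2) / (k - 1)
  mst <- k * sum(sweep(ptm, 1, pm[rownames(ptm)])^2) / (N * (n - 1))
  pi_dev <- sweep(sweep(pim, 1, pm[rownames(pim)]), 2, im[colnames(pim)]) + g
  mspi <- n * sum(pi_dev^2) / ((N - 1) * (k - 1))
  sse <- sum((y - g)^2) - (N - 1) * msp - (k - 1) * msi -
    N * (n - 1) * mst - (N - 1) * (k - 1) * mspi
  mse <- sse / (N * (n - 1) * (k - 1))
  list(
    sigma2_error = mse,
    sigma2_person_item = (mspi - mse) / n,
    sigma2_time_in_person = (mst - mse) / k,
    sigma2_item = (msi - mspi) / (N * n),
    sigma2_person = (msp - mst - mspi + mse) / (n * k)
  )
}

# brute-force two-way absolute-agreement ICC via explicit ANOVA sums
icc_a1_bruteforce <- function(m) {
  m <- as.matrix(m)
  N <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - g)^2)
  ss_cols <- N * sum((colMeans(m) - g)^2)
  ss_tot <- sum((m - g)^2)
  msr <- ss_rows / (N - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((N - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / N * (msc - mse))
}

# hand Cronbach alpha from the covariance definition
alpha_bruteforce <- function(mat) {
  k <- ncol(mat)
  v <- var(rowSums(mat))
  k / (k - 1) * (1 - sum(diag(var(mat))) / v)
}

# small paper-like enriched synthetic dataset shared by careless tests
small_enriched <- function(n = 80, seed = 303, ...) {
  cfg <- ema_generator_config(n_participants = n, seed = seed, ...)
  ds <- generate_ema_dataset(cfg)
  list(
    participants = ds$participants,
    assessments = enrich_assessments(ds$assessments),
    truth = ds$truth
  )
}
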