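#' Intraclass correlation from variance components
#'
#' ICC = sigma2_between / (sigma2_between + sigma2_within): the share of a
#' score's variance due to stable differences between persons. An ICC below
#' 0.5 means the variance is mostly momentary fluctuation, which is what
#' justifies frequent momentary assessment.
#'
#' @param sigma2_between,sigma2_within non-negative variance components.
#' @param digits optional rounding of the returned value (reports use 2).
#' @return Proportion in \[0,1\], or NA (with a warning) when both components
#'   are zero.
#' @examples
#' icc_from_components(0.94, 0.81, digits = 2) # 0.54
#' @export
icc_from_components <- function(sigma2_between, sigma2_within, digits = NULL) {
  if (any(c(sigma2_between, sigma2_within) < 0)) stop_emaqc("variance components must be >= 0")
  tot <- sigma2_between + sigma2_within
  if (tot == 0) {
    warning("both variance components are zero: ICC undefined", call. = FALSE)
    return(NA_real_)
  }
  icc <- sigma2_between / tot
  if (!is.null(digits)) icc <- round(icc, digits)
  icc
}

#' Two-level variance decomposition of momentary scores
#'
#' Splits the variance of a person x occasion score into between-person and
#' within-person components with a random-intercept multilevel model fitted by
#' REML (handles unbalanced data). For perfectly balanced data this matches
#' the one-way expected-mean-squares estimator sigma2_B = (MSB - MSW)/n,
#' sigma2_W = MSW (when that estimate is non-negative).
#'
#' @param scores long data frame of scores.
#' @param score_col,person_col column names.
#' @return Object of class `two_level_components`: sigma2_between,
#'   sigma2_within, icc, n_persons, n_obs.
#' @export
decompose_two_level <- function(scores, score_col = "score", person_col = "person_id") {
  y <- scores[[score_col]]
  g <- factor(scores[[person_col]])
  keep <- !is.na(y)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop_emaqc("need >= 2 persons")
  if (max(table(g)) < 2) stop_emaqc("need >= 2 occasions for at least one person")
  res <- if (stats::var(y) == 0) {
    list(b = 0, w = 0)
  } else if (max(tapply(y, g, stats::var), na.rm = TRUE) < 1e-12) {
    # every person constant: all variance is between persons
    list(b = stats::var(tapply(y, g, mean)), w = 0)
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(b = vc$vcov[vc$grp == "g"], w = vc$vcov[vc$grp == "Residual"])
  }
  structure(
    list(
      sigma2_between = res$b,
      sigma2_within = res$w,
      icc = if (res$b + res$w == 0) NA_real_ else res$b / (res$b + res$w),
      n_persons = nlevels(g),
      n_obs = length(y)
    ),
    class = "two_level_components"
  )
}

#' @export
print.two_level_components <- function(x, ...) {
  cat(sprintf("<two_level_components> sigma2_between %.4f, sigma2_within %.4f, ICC %.2f (%d persons, %d obs)\n",
              x$sigma2_between, x$sigma2_within, x$icc, x$n_persons, x$n_obs))
  invisible(x)
}

#' Three-level variance decomposition of item responses
#'
#' Decomposes person x occasion x item responses into five variance
#' components: person (sigma2_person), time within person
#' (sigma2_time_in_person), item main effect (sigma2_item), person-by-item
#' interaction (sigma2_person_item) and residual (sigma2_error). Items and
#' time are random effects, time nested within persons and items crossed with
#' both — the decomposition underlying the Shrout-Lane multilevel reliability
#' coefficients. Fitted by REML; negative components are truncated at zero by
#' the fit itself, with a `boundary` diagnostic listing components at zero.
#'
#' @param responses long data frame of single-item responses.
#' @param response_col,person_col,occasion_col,item_col column names.
#' @return Object of class `three_level_components` with the five components,
#'   `k` (number of items), `n` (harmonic mean of per-person occasion counts),
#'   n_persons and boundary diagnostics.
#' @export
decompose_three_level <- function(responses, response_col = "response",
                                  person_col = "person_id",
                                  occasion_col = "occasion", item_col = "item") {
  y <- responses[[response_col]]
  person <- factor(responses[[person_col]])
  occ <- factor(paste(responses[[person_col]], responses[[occasion_col]], sep = ":"))
  item <- factor(responses[[item_col]])
  keep <- !is.na(y)
  y <- y[keep]
  person <- droplevels(person[keep]); occ <- droplevels(occ[keep]); item <- droplevels(item[keep])
  if (nlevels(person) < 2 || nlevels(item) < 2) stop_emaqc("need >= 2 persons and >= 2 items")
  k <- nlevels(item)
  occ_per_person <- tapply(as.character(occ), person, function(z) length(unique(z)))
  if (max(occ_per_person) < 2) stop_emaqc("need >= 2 occasions")
  n_harm <- length(occ_per_person) / sum(1 / occ_per_person)

  comp <- c(sigma2_person = 0, sigma2_time_in_person = 0, sigma2_item = 0,
            sigma2_person_item = 0, sigma2_error = 0)
  if (stats::var(y) > 0) {
    pxi <- factor(paste(person, item, sep = ":"))
    fit <- lme4::lmer(
      y ~ 1 + (1 | person) + (1 | occ) + (1 | item) + (1 | pxi),
      REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(grp) vc$vcov[vc$grp == grp]
    comp["sigma2_person"] <- pick("person")
    comp["sigma2_time_in_person"] <- pick("occ")
    comp["sigma2_item"] <- pick("item")
    comp["sigma2_person_item"] <- pick("pxi")
    comp["sigma2_error"] <- pick("Residual")
  }
  boundary <- names(comp)[comp < 1e-10]
  structure(
    c(as.list(comp), list(
      k = k, n = n_harm, n_persons = nlevels(person),
      boundary = boundary
    )),
    class = "three_level_components"
  )
}

#' @export
print.three_level_components <- function(x, ...) {
  cat(sprintf(
    "<three_level_components> P %.4f, T(P) %.4f, I %.4f, PxI %.4f, error %.4f (k=%d, n=%.1f, %d persons)\n",
    x$sigma2_person, x$sigma2_time_in_person, x$sigma2_item,
    x$sigma2_person_item, x$sigma2_error, x$k, x$n, x$n_persons
  ))
  if (length(x$boundary)) cat("  components at zero boundary:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Interpretation band for a reliability coefficient
#'
#' Classic test-theory convention: 0.00-0.10 practically no reliability,
#' 0.11-0.40 slight, 0.41-0.60 fair, 0.61-0.80 moderate, 0.81-1.00
#' substantial. Applied to the value rounded to 2 decimals.
#'
#' @param r reliability value(s) in \[0,1\].
#' @return Character band label(s).
#' @export
reliability_band <- function(r) {
  r2 <- round(r, 2)
  out <- rep(NA_character_, length(r2))
  out[!is.na(r2) & r2 <= 0.10] <- "practically none"
  out[!is.na(r2) & r2 >= 0.11 & r2 <= 0.40] <- "slight"
  out[!is.na(r2) & r2 >= 0.41 & r2 <= 0.60] <- "fair"
  out[!is.na(r2) & r2 >= 0.61 & r2 <= 0.80] <- "moderate"
  out[!is.na(r2) & r2 >= 0.81] <- "substantial"
  out
}

#' Multilevel between- and within-person reliability (Shrout-Lane)
#'
#' From the five three-level variance components, the between-person
#' reliability of scale scores averaged over n time points and k items is
#'
#'   R_kRn = (sP + sPI/k) / (sP + sPI/k + sT(P)/n + sE/(k n))
#'
#' and the within-person (change) reliability of k-item scale scores is
#'
#'   R_cn = sT(P) / (sT(P) + sE/k).
#'
#' Unbalanced designs use the harmonic mean of per-person occasion counts as
#' n (the balanced case reduces to the common n). Values are clamped to
#' \[0,1\] and given an interpretation band.
#'
#' @param components a `three_level_components` object (or list with the five
#'   components).
#' @param k items per scale (defaults to `components$k`).
#' @param n time points per person (defaults to `components$n`).
#' @return Object of class `reliability_report`: r_krn, r_cn, bands, k, n.
#' @export
multilevel_reliability <- function(components, k = NULL, n = NULL) {
  k <- k %||% components$k
  n <- n %||% components$n
  if (is.null(k) || k < 2) stop_emaqc("k must be >= 2")
  if (is.null(n) || n < 2) stop_emaqc("n must be >= 2")
  sP <- components$sigma2_person
  sTP <- components$sigma2_time_in_person
  sPI <- components$sigma2_person_item
  sE <- components$sigma2_error
  den_b <- sP + sPI / k + sTP / n + sE / (k * n)
  den_w <- sTP + sE / k
  r_krn <- if (den_b == 0) NA_real_ else clamp((sP + sPI / k) / den_b, 0, 1)
  r_cn <- if (den_w == 0) NA_real_ else clamp(sTP / den_w, 0, 1)
  if (den_b == 0 || den_w == 0) {
    warning("zero denominator: reliability undefined", call. = FALSE)
  }
  structure(
    list(
      r_krn = r_krn, r_cn = r_cn,
      band_krn = reliability_band(r_krn), band_cn = reliability_band(r_cn),
      k = k, n = n
    ),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> R_kRn %.2f (%s), R_cn %.2f (%s) [k=%d, n=%.1f]\n",
              x$r_krn, x$band_krn, x$r_cn, x$band_cn, x$k, x$n))
  invisible(x)
}

#' Raw Cronbach alpha for one person across occasions
#'
#' alpha = k/(k-1) (1 - sum_i s2_i / s2_total), where s2_i is the variance of
#' item i across the person's occasions and s2_total the variance of the
#' occasion sums. Alpha may be negative. Returned missing when fewer than two
#' occasions exist or the occasion sums never vary (a participant with no
#' variation has no raw alpha).
#'
#' @param mat numeric matrix, occasions in rows, items in columns.
#' @return Alpha, or NA when undefined.
#' @export
person_alpha <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2) return(NA_real_)
  k <- ncol(mat)
  s2_total <- stats::var(rowSums(mat))
  if (s2_total == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) / s2_total)
}

#' Per-person raw Cronbach alpha table for the PA and NA scales
#'
#' @param assessments assessment table with item columns and completed flag.
#' @param design an [ema_design()].
#' @return Data frame: person_id, n_occasions, alpha_pa, alpha_na.
#' @export
person_alpha_table <- function(assessments, design = ema_design()) {
  comp <- assessments[assessments$completed == 1, , drop = FALSE]
  ids <- unique(assessments$person_id)
  out <- data.frame(person_id = ids, n_occasions = 0L,
                    alpha_pa = NA_real_, alpha_na = NA_real_)
  sp <- split(comp, factor(comp$person_id, levels = ids))
  for (i in seq_along(ids)) {
    a <- sp[[i]]
    out$n_occasions[i] <- nrow(a)
    if (nrow(a) >= 2) {
      out$alpha_pa[i] <- person_alpha(a[, design$pa_items])
      out$alpha_na[i] <- person_alpha(a[, design$na_items])
    }
  }
  out
}

#' Two-way absolute-agreement ICC for paired statistics
#'
#' Single-rater, two-way, absolute-agreement intraclass correlation between
#' two measurements per person (e.g. a subset statistic against a
#' gold-standard statistic): with mean squares for rows MSR, columns MSC and
#' error MSE from the two-way ANOVA with k = 2 measurements and N persons,
#'
#'   ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/N)(MSC - MSE)).
#'
#' Not clamped: near-zero between-person variance can yield values at or
#' below zero, which is diagnostic in itself.
#'
#' @param pairs two-column numeric matrix or data frame, persons in rows.
#' @return The agreement coefficient.
#' @export
stability_icc <- function(pairs) {
  m <- as.matrix(pairs)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  N <- nrow(m); k <- ncol(m)
  if (N < 3 || k != 2) stop_emaqc("need >= 3 persons with exactly 2 measurements each")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (N - 1)
  msc <- N * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, N), col_m) + grand)^2)
  mse <- sse / ((N - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / N) * (msc - mse)
  if (den == 0) return(NA_real_) # fully constant table: agreement undefined
  (msr - mse) / den
}
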