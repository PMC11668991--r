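#' Careless-responding rule configuration
#'
#' Thresholds of the careless-response and careless-responder rules: a
#' completed assessment is careless when its time per item is at or below
#' `tpi_threshold_seconds` (1 s) or its 12-item response SD is exactly zero
#' (straight-lining); a person is a potential careless responder when their
#' non-careless assessments fall below the stability-derived minimum or their
#' raw per-person Cronbach alpha is below `alpha_floor` (0.11, "practically no
#' reliability") on either affect scale.
#'
#' @param tpi_threshold_seconds fast-response cutoff (inclusive).
#' @param alpha_floor per-person reliability floor.
#' @param icc_stability_target agreement level the stability curves must reach.
#' @param gold_standard_n assessments forming each person's gold standard.
#' @param subset_sizes subset sizes evaluated for the stability curves.
#' @param n_replicates random subsets drawn per size.
#' @return Object of class `careless_config`.
#' @export
careless_config <- function(tpi_threshold_seconds = 1.0,
                            alpha_floor = 0.11,
                            icc_stability_target = 0.90,
                            gold_standard_n = 40L,
                            subset_sizes = 2:40,
                            n_replicates = 5L) {
  if (tpi_threshold_seconds <= 0 || alpha_floor <= 0) stop_emaqc("thresholds must be positive")
  if (icc_stability_target <= 0 || icc_stability_target >= 1) {
    stop_emaqc("icc_stability_target must be in (0,1)")
  }
  if (any(subset_sizes < 2) || any(subset_sizes > gold_standard_n)) {
    stop_emaqc("subset_sizes must lie in [2, gold_standard_n]")
  }
  structure(
    list(
      tpi_threshold_seconds = tpi_threshold_seconds,
      alpha_floor = alpha_floor,
      icc_stability_target = icc_stability_target,
      gold_standard_n = as.integer(gold_standard_n),
      subset_sizes = as.integer(subset_sizes),
      n_replicates = as.integer(n_replicates)
    ),
    class = "careless_config"
  )
}

#' Select the psychometric-antonym item pair
#'
#' Computes the Pearson correlation over all completed assessments for every
#' pair of candidate items and returns the pair with the strongest negative
#' correlation. In an attentive sample, items with opposite meaning (e.g.
#' feeling nervous vs feeling relaxed) correlate negatively; careless subsets
#' flatten or invert that relationship. Constant items are excluded with a
#' diagnostic; ties are broken by the lowest item-index pair; a warning is
#' emitted when even the most negative correlation is >= 0 (no antonyms
#' exist).
#'
#' @param assessments assessment table with item columns and completed flag.
#' @param items candidate item ids (default: the common set of the design).
#' @param design an [ema_design()].
#' @return List of class `antonym_pair`: `items` (the two ids), `r`, `n`,
#'   `excluded` (constant items).
#' @export
select_antonyms <- function(assessments, items = NULL, design = ema_design()) {
  items <- items %||% design$item_ids
  if (length(items) < 2) stop_emaqc("need >= 2 candidate items")
  comp <- assessments[assessments$completed == 1, items, drop = FALSE]
  if (nrow(comp) < 3) stop_emaqc("need >= 3 completed assessments")
  sds <- vapply(comp, stats::sd, numeric(1))
  excluded <- items[sds == 0 | is.na(sds)]
  if (length(excluded) > 0) {
    message("excluding constant items from antonym search: ", paste(excluded, collapse = ", "))
  }
  use <- setdiff(items, excluded)
  if (length(use) < 2) stop_emaqc("fewer than 2 non-constant candidate items")
  cm <- stats::cor(comp[, use, drop = FALSE])
  best <- c(NA_integer_, NA_integer_); best_r <- Inf
  for (i in seq_len(length(use) - 1)) {
    for (j in (i + 1):length(use)) {
      if (cm[i, j] < best_r) { # strict '<' keeps the lowest-index pair on ties
        best_r <- cm[i, j]
        best <- c(i, j)
      }
    }
  }
  if (best_r >= 0) warning("most negative item correlation is >= 0: no psychometric antonyms found",
                           call. = FALSE)
  structure(
    list(items = use[best], r = best_r, n = nrow(comp), excluded = excluded),
    class = "antonym_pair"
  )
}

#' @export
print.antonym_pair <- function(x, ...) {
  cat(sprintf("<antonym_pair> %s vs %s: r = %.3f over %d completed assessments\n",
              x$items[1], x$items[2], x$r, x$n))
  invisible(x)
}

#' Antonym correlation at careless-parameter thresholds
#'
#' For each threshold of a careless parameter, restricts the completed
#' assessments to the suspicious side (at or below the threshold for time per
#' item and response SD; at or above for percent-at-mode) and reports the
#' antonym-pair correlation there, with counts and shares. These are the
#' threshold curves used to judge where the antonym relationship flattens or
#' inverts. Subsets with fewer than 3 assessments or a constant antonym item
#' yield a missing correlation.
#'
#' @param assessments enriched assessment table (see [enrich_assessments()]).
#' @param parameter one of "time_per_item", "sd_items", "pct_mode".
#' @param thresholds numeric thresholds to evaluate (`Inf` / `-Inf` gives the
#'   unrestricted full-sample correlation).
#' @param antonyms an `antonym_pair` (or character vector of 2 item ids).
#' @return Data frame: threshold, r_below, n_below, share_below.
#' @export
antonym_threshold_curve <- function(assessments,
                                    parameter = c("time_per_item", "sd_items", "pct_mode"),
                                    thresholds, antonyms) {
  parameter <- match.arg(parameter)
  pair <- if (inherits(antonyms, "antonym_pair")) antonyms$items else antonyms
  stopifnot(length(pair) == 2)
  comp <- assessments[assessments$completed == 1, , drop = FALSE]
  if (!parameter %in% names(comp)) stop_emaqc("column '%s' not found (enrich the table first)", parameter)
  p <- comp[[parameter]]
  n_total <- nrow(comp)
  rows <- lapply(thresholds, function(th) {
    sel <- if (parameter == "pct_mode") p >= th else p <= th
    sub <- comp[which(sel), pair, drop = FALSE]
    r <- NA_real_
    if (nrow(sub) >= 3 && all(vapply(sub, stats::sd, numeric(1)) > 0)) {
      r <- stats::cor(sub[[1]], sub[[2]])
    }
    data.frame(threshold = th, r_below = r, n_below = nrow(sub),
               share_below = nrow(sub) / n_total)
  })
  do.call(rbind, rows)
}

#' Flag careless responses
#'
#' A completed assessment is flagged "fast" when its time per item is at or
#' below the threshold (1 s by default), "straightline" when its 12-item
#' response SD is exactly zero (equivalently 100% of items at the mode), or
#' "both". Missed assessments are never flagged.
#'
#' @param assessments enriched assessment table.
#' @param config a [careless_config()].
#' @return The table with a `careless_flag` column
#'   (none/fast/straightline/both); summary counts in the
#'   `careless_summary` attribute (n_completed, n_flagged, share, per-reason
#'   counts and their overlap).
#' @export
flag_careless_responses <- function(assessments, config = careless_config()) {
  comp <- assessments$completed == 1
  fast <- comp & !is.na(assessments$time_per_item) &
    assessments$time_per_item <= config$tpi_threshold_seconds
  straight <- comp & !is.na(assessments$sd_items) & assessments$sd_items == 0
  flag <- rep("none", nrow(assessments))
  flag[fast] <- "fast"
  flag[straight] <- "straightline"
  flag[fast & straight] <- "both"
  assessments$careless_flag <- flag
  n_completed <- sum(comp)
  n_flagged <- sum(fast | straight)
  attr(assessments, "careless_summary") <- list(
    n_completed = n_completed,
    n_flagged = n_flagged,
    share = if (n_completed > 0) n_flagged / n_completed else NA_real_,
    n_fast = sum(fast),
    n_straightline = sum(straight),
    n_both = sum(fast & straight)
  )
  assessments
}

#' Minimum valid assessments via ICC stability curves
#'
#' For every person with at least `gold_standard_n` completed assessments, the
#' gold standard is their first `gold_standard_n` completed assessments in
#' chronological order. For each subset size s, random subsets of s
#' assessments are drawn per person (without replacement, `n_replicates`
#' times), the per-person mean and SD of the PA and NA scores are computed on
#' each subset, and the two-way absolute-agreement ICC against the
#' gold-standard statistic is averaged over replicates. The minimum number of
#' valid assessments is the smallest s from which all four curves
#' (mean/SD x PA/NA) stay at or above `icc_stability_target` for every larger
#' evaluated size.
#'
#' @param assessments enriched assessment table.
#' @param config a [careless_config()].
#' @param seed integer seed for the subset draws.
#' @param design an [ema_design()].
#' @return Object of class `stability_curve`: `curve` (statistic, scale,
#'   subset_size, icc), `minimum` (NA when the target is never reached, with
#'   `reached = FALSE`), target, gold_standard_n, n_persons.
#' @export
minimum_valid_assessments <- function(assessments, config = careless_config(),
                                      seed = 1L, design = ema_design()) {
  comp <- assessments[assessments$completed == 1, , drop = FALSE]
  comp <- comp[order(comp$person_id, comp$day, comp$window), , drop = FALSE]
  counts <- table(comp$person_id)
  eligible <- names(counts)[counts >= config$gold_standard_n]
  if (length(eligible) < 3) stop_emaqc("fewer than 3 persons with >= %d completed assessments",
                                       config$gold_standard_n)
  g <- config$gold_standard_n
  sp <- split(comp[, c("pa_score", "na_score")], comp$person_id)[eligible]
  pa <- t(vapply(sp, function(d) d$pa_score[seq_len(g)], numeric(g)))
  na_ <- t(vapply(sp, function(d) d$na_score[seq_len(g)], numeric(g)))
  gold <- list(
    mean_pa = rowMeans(pa), sd_pa = apply(pa, 1, stats::sd),
    mean_na = rowMeans(na_), sd_na = apply(na_, 1, stats::sd)
  )
  np <- length(eligible)
  sizes <- config$subset_sizes
  curve <- expand.grid(statistic = c("mean", "sd"), scale = c("pa", "na"),
                       subset_size = sizes, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  curve$icc <- NA_real_
  with_seed(derive_seed(seed, 71L), {
    for (s in sizes) {
      acc <- c(mean_pa = 0, sd_pa = 0, mean_na = 0, sd_na = 0)
      for (rep_i in seq_len(config$n_replicates)) {
        idx <- replicate(np, sample.int(g, s))            # s x np
        sub_pa <- matrix(pa[cbind(rep(seq_len(np), each = s), as.vector(idx))], s, np)
        sub_na <- matrix(na_[cbind(rep(seq_len(np), each = s), as.vector(idx))], s, np)
        acc <- acc + c(
          mean_pa = stability_icc(cbind(colMeans(sub_pa), gold$mean_pa)),
          sd_pa = stability_icc(cbind(apply(sub_pa, 2, stats::sd), gold$sd_pa)),
          mean_na = stability_icc(cbind(colMeans(sub_na), gold$mean_na)),
          sd_na = stability_icc(cbind(apply(sub_na, 2, stats::sd), gold$sd_na))
        )
      }
      acc <- acc / config$n_replicates
      curve$icc[curve$subset_size == s & curve$statistic == "mean" & curve$scale == "pa"] <- acc[["mean_pa"]]
      curve$icc[curve$subset_size == s & curve$statistic == "sd" & curve$scale == "pa"] <- acc[["sd_pa"]]
      curve$icc[curve$subset_size == s & curve$statistic == "mean" & curve$scale == "na"] <- acc[["mean_na"]]
      curve$icc[curve$subset_size == s & curve$statistic == "sd" & curve$scale == "na"] <- acc[["sd_na"]]
    }
  })
  ok_at <- vapply(sizes, function(s) {
    all(curve$icc[curve$subset_size == s] >= config$icc_stability_target)
  }, logical(1))
  ok_from <- rev(cumprod(rev(ok_at))) == 1 # >= target at s and every larger size
  minimum <- if (any(ok_from)) sizes[which(ok_from)[1]] else NA_integer_
  structure(
    list(curve = curve, minimum = minimum, reached = !is.na(minimum),
         target = config$icc_stability_target,
         gold_standard_n = g, n_persons = np),
    class = "stability_curve"
  )
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %d persons, gold standard %d assessments, target ICC >= %.2f\n",
              x$n_persons, x$gold_standard_n, x$target))
  if (x$reached) {
    cat(sprintf("  minimum valid assessments: %d\n", x$minimum))
  } else {
    cat("  minimum valid assessments: not reached within evaluated sizes\n")
  }
  invisible(x)
}

#' Flag careless responders
#'
#' A person is a potential careless responder when their number of valid
#' (completed and non-careless) assessments is below the minimum, or when
#' their raw per-person Cronbach alpha is below the floor on either affect
#' scale (negative alpha counts as below). A missing alpha (undefined: one
#' occasion or no variation) does not by itself trigger the alpha rule, but
#' is reported. Flagged persons are marked, never dropped.
#'
#' @param persons participant table (person_id at minimum).
#' @param flagged_assessments output of [flag_careless_responses()].
#' @param alpha_table output of [person_alpha_table()].
#' @param minimum minimum valid assessments (from
#'   [minimum_valid_assessments()]).
#' @param config a [careless_config()].
#' @return Data frame: person_id, n_completed, n_careless, n_valid, alpha_pa,
#'   alpha_na, low_valid, low_alpha, alpha_missing, responder_flag
#'   (none/low_valid/low_alpha/both).
#' @export
flag_careless_responders <- function(persons, flagged_assessments, alpha_table,
                                     minimum, config = careless_config()) {
  ids <- persons$person_id
  comp <- flagged_assessments[flagged_assessments$completed == 1, , drop = FALSE]
  n_completed <- as.integer(table(factor(comp$person_id, levels = ids)))
  n_careless <- as.integer(table(factor(
    comp$person_id[comp$careless_flag != "none"], levels = ids
  )))
  n_valid <- n_completed - n_careless
  am <- alpha_table[match(ids, alpha_table$person_id), ]
  low_valid <- n_valid < minimum
  below <- function(a) !is.na(a) & a < config$alpha_floor
  low_alpha <- below(am$alpha_pa) | below(am$alpha_na)
  alpha_missing <- is.na(am$alpha_pa) | is.na(am$alpha_na)
  flag <- rep("none", length(ids))
  flag[low_valid] <- "low_valid"
  flag[low_alpha] <- "low_alpha"
  flag[low_valid & low_alpha] <- "both"
  data.frame(
    person_id = ids,
    n_completed = n_completed,
    n_careless = n_careless,
    n_valid = n_valid,
    alpha_pa = am$alpha_pa,
    alpha_na = am$alpha_na,
    low_valid = low_valid,
    low_alpha = low_alpha,
    alpha_missing = alpha_missing,
    responder_flag = flag,
    row.names = NULL
  )
}
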