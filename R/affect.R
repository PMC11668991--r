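#' Score positive and negative affect for one assessment
#'
#' PA is the arithmetic mean of the 5 PA item responses and NA the mean of the
#' 4 NA item responses. The two scales are separate and unipolar: no item is
#' reverse-coded.
#'
#' @param items named numeric vector holding at least the common items (names
#'   matching `design$item_ids`), or an unnamed vector of length
#'   `n_items_common` in battery order.
#' @param design an [ema_design()].
#' @return Named numeric vector `c(pa = , na = )`.
#' @examples
#' score_affect(rep(4, 12))
#' @export
score_affect <- function(items, design = ema_design()) {
  if (is.null(names(items))) {
    if (length(items) != design$n_items_common) {
      stop_emaqc("expected %d common items, got %d", design$n_items_common, length(items))
    }
    names(items) <- design$item_ids
  }
  missing_ids <- setdiff(c(design$pa_items, design$na_items), names(items))
  if (length(missing_ids) > 0) stop_emaqc("missing items: %s", paste(missing_ids, collapse = ", "))
  bad <- names(items)[items < design$likert_min | items > design$likert_max | is.na(items)]
  if (length(bad) > 0) {
    stop_emaqc("item response out of range [%d,%d]: %s",
               design$likert_min, design$likert_max, paste(bad, collapse = ", "))
  }
  c(pa = mean(items[design$pa_items]), na = mean(items[design$na_items]))
}

#' Time per item of an assessment
#'
#' Total completion time divided by the number of items of that specific
#' assessment (morning/evening assessments carry more items than midday ones,
#' so the item count travels with the record).
#'
#' @param start,end start and end timestamps (POSIXct or numeric seconds).
#' @param n_items item count of the assessment.
#' @return Seconds per item.
#' @export
time_per_item <- function(start, end, n_items) {
  if (any(n_items < 1)) stop_emaqc("n_items must be >= 1")
  secs <- as.numeric(difftime(end, start, units = "secs"))
  if (any(!is.na(secs) & secs <= 0)) stop_emaqc("non-positive assessment duration")
  secs / n_items
}

#' Within-assessment response dispersion
#'
#' SD of the responses to the 12-item common set (sample SD, n-1 denominator)
#' and the proportion of those responses equal to the assessment's modal
#' response. Ties in the mode are irrelevant: any modal value yields the same
#' proportion.
#'
#' @param items responses to the common items of one assessment.
#' @return List with `sd_items` and `pct_mode`.
#' @examples
#' response_dispersion(rep(5, 12)) # sd 0, pct_mode 1
#' @export
response_dispersion <- function(items) {
  items <- items[!is.na(items)]
  if (length(items) < 1) return(list(sd_items = NA_real_, pct_mode = NA_real_))
  tab <- table(items)
  list(
    sd_items = stats::sd(items),
    pct_mode = as.numeric(max(tab)) / length(items)
  )
}

#' Enrich an assessment table with scores and careless parameters
#'
#' Adds (or recomputes) pa_score, na_score, time_per_item, sd_items and
#' pct_mode for every completed assessment. Missed assessments get NA in all
#' derived columns. Dispersion is computed over the 12-item common set only,
#' never over add-on items; time per item uses the `n_items` column when
#' present, else the size of the common set.
#'
#' @param assessments assessment table (see [read_assessments()] for the
#'   expected columns).
#' @param design an [ema_design()].
#' @return The table with derived columns added.
#' @export
enrich_assessments <- function(assessments, design = ema_design()) {
  it <- as.matrix(assessments[, design$item_ids, drop = FALSE])
  comp <- assessments$completed == 1
  pa <- rowMeans(it[, design$pa_items, drop = FALSE])
  na_ <- rowMeans(it[, design$na_items, drop = FALSE])
  n_items <- assessments$n_items %||% rep(design$n_items_common, nrow(assessments))
  tpi <- rep(NA_real_, nrow(assessments))
  tpi[comp] <- time_per_item(assessments$start_time[comp], assessments$end_time[comp],
                             n_items[comp])
  sds <- apply(it, 1, stats::sd)
  mode_n <- apply(it, 1, function(r) if (all(is.na(r))) NA_real_ else max(table(r)))
  assessments$pa_score <- ifelse(comp, pa, NA_real_)
  assessments$na_score <- ifelse(comp, na_, NA_real_)
  assessments$time_per_item <- tpi
  assessments$sd_items <- ifelse(comp, sds, NA_real_)
  assessments$pct_mode <- ifelse(comp, mode_n / design$n_items_common, NA_real_)
  assessments
}
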