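#' Run the full EMA data-quality pipeline
#'
#' Chains the stages: simulate (or read) -> affect scoring -> participation
#' and compliance -> variance decomposition and multilevel reliability ->
#' careless responses and responders -> consolidated report. Identical
#' configuration and seed yield an identical report.
#'
#' @param generator_config an [ema_generator_config()] (simulated input), or
#'   NULL when `participants`/`assessments` are supplied.
#' @param design an [ema_design()].
#' @param participants,assessments tables (already read/validated) when not
#'   simulating; exactly one input route must be used.
#' @param careless a [careless_config()].
#' @param exposures character vector of participant columns to model as
#'   participation/compliance exposures (each in its own adjusted model).
#' @param seed integer seed controlling the stability-curve subsampling (and
#'   the generator, via `generator_config$seed`, when simulating).
#' @param three_level estimate the three-level components and Shrout-Lane
#'   reliabilities (the slowest stage; disable for quick summaries).
#' @param verbose print stage progress.
#' @return Object of class `quality_report`.
#' @export
run_pipeline <- function(generator_config = NULL, design = ema_design(),
                         participants = NULL, assessments = NULL,
                         careless = careless_config(),
                         exposures = character(0),
                         seed = 1L, three_level = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(generator_config) == (is.null(participants) || is.null(assessments))) {
    stop_emaqc("supply exactly one of: generator_config, or participants + assessments")
  }
  if (!is.null(generator_config)) {
    say("simulate: n=%d persons, seed %d", generator_config$n_participants, generator_config$seed)
    ds <- generate_ema_dataset(generator_config, design)
    participants <- ds$participants
    assessments <- ds$assessments
  }
  say("score: %d assessment rows", nrow(assessments))
  assessments <- enrich_assessments(assessments, design)
  comp <- assessments[assessments$completed == 1, , drop = FALSE]

  ## participation / compliance ------------------------------------------
  n_invited <- sum(participants$invited)
  n_participated <- sum(participants$participated)
  part_block <- list(
    n_invited = n_invited,
    n_participated = n_participated,
    rate = participation_rate(n_invited, n_participated),
    models = lapply(stats::setNames(exposures, exposures), function(e) {
      fit_participation_model(participants, e)
    })
  )
  cohort_part <- participants[participants$participated, , drop = FALSE]
  byday <- compliance_by_day(assessments)
  compl_block <- list(
    summary = compliance_summary(cohort_part, design, by = "subsample"),
    by_day = byday$by_day,
    day_slope = byday$slope,
    models = lapply(stats::setNames(exposures, exposures), function(e) {
      fit_compliance_model(cohort_part, e, design)
    })
  )
  say("compliance: mean %.1f%% over %d participants",
      100 * compl_block$summary$mean[1], nrow(cohort_part))

  ## reliability -----------------------------------------------------------
  rel_block <- list()
  for (scale in c("pa", "na")) {
    col <- paste0(scale, "_score")
    two <- decompose_two_level(comp, score_col = col)
    entry <- list(two_level = two, icc = round(two$icc, 2))
    if (three_level) {
      long <- reshape_items_long(comp, design, scale)
      three <- decompose_three_level(long)
      k <- length(if (scale == "pa") design$pa_items else design$na_items)
      entry$three_level <- three
      entry$reliability <- multilevel_reliability(three, k = k)
    }
    rel_block[[scale]] <- entry
  }
  alpha_tab <- person_alpha_table(assessments, design)
  rel_block$person_alpha <- alpha_tab

  ## careless ---------------------------------------------------------------
  antonyms <- select_antonyms(assessments, design = design)
  flagged <- flag_careless_responses(assessments, careless)
  flag_summary <- attr(flagged, "careless_summary")
  stability <- tryCatch(
    minimum_valid_assessments(flagged, careless, seed = seed, design = design),
    error = function(e) NULL
  )
  minimum <- if (!is.null(stability) && stability$reached) stability$minimum else NA_integer_
  responders <- if (!is.na(minimum)) {
    flag_careless_responders(participants[participants$participated, , drop = FALSE],
                             flagged, alpha_tab, minimum, careless)
  } else {
    NULL
  }
  careless_block <- list(
    antonyms = antonyms,
    responses = flag_summary,
    stability = stability,
    minimum_valid_assessments = minimum,
    responders = responders,
    n_responders = if (is.null(responders)) NA_integer_ else sum(responders$responder_flag != "none")
  )
  say("careless: %d/%d responses flagged (%.2f%%)",
      flag_summary$n_flagged, flag_summary$n_completed, 100 * flag_summary$share)

  structure(
    list(
      schema_version = "1.0",
      seed = seed,
      design = design,
      participation = part_block,
      compliance = compl_block,
      reliability = rel_block,
      careless = careless_block,
      assessments = assessments
    ),
    class = "quality_report"
  )
}

# one-scale long item table (completed assessments only)
reshape_items_long <- function(comp, design, scale = c("pa", "na")) {
  scale <- match.arg(scale)
  items <- if (scale == "pa") design$pa_items else design$na_items
  occ <- paste(comp$day, comp$window, sep = ".")
  do.call(rbind, lapply(items, function(it) {
    data.frame(person_id = comp$person_id, occasion = occ,
               item = it, response = comp[[it]])
  }))
}

#' @export
print.quality_report <- function(x, ...) {
  cs <- x$compliance$summary[x$compliance$summary$group == "all", ]
  cat("== EMA data-quality report ==\n")
  cat(sprintf("participation: %s (%d/%d)\n",
              format_compliance_pct(x$participation$rate),
              x$participation$n_participated, x$participation$n_invited))
  cat(sprintf("compliance: mean %s (SD %s; range %s-%s), median %s, mode %s; day slope %+.4f/day\n",
              format_compliance_pct(cs$mean), format_compliance_pct(cs$sd),
              format_compliance_pct(cs$min), format_compliance_pct(cs$max),
              format_compliance_pct(cs$median), format_compliance_pct(cs$mode),
              x$compliance$day_slope))
  for (scale in c("pa", "na")) {
    e <- x$reliability[[scale]]
    cat(sprintf("%s: sigma2 between %.2f / within %.2f, ICC %.2f",
                toupper(scale), e$two_level$sigma2_between, e$two_level$sigma2_within, e$icc))
    if (!is.null(e$reliability)) {
      cat(sprintf("; R_kRn %.2f (%s), R_cn %.2f (%s)",
                  e$reliability$r_krn, e$reliability$band_krn,
                  e$reliability$r_cn, e$reliability$band_cn))
    }
    cat("\n")
  }
  cr <- x$careless$responses
  cat(sprintf("careless responses: %d/%d (%s)\n", cr$n_flagged, cr$n_completed,
              format_compliance_pct(cr$share, 2)))
  if (!is.na(x$careless$minimum_valid_assessments)) {
    cat(sprintf("minimum valid assessments: %d; careless responders: %d/%d (%s)\n",
                x$careless$minimum_valid_assessments,
                x$careless$n_responders, x$participation$n_participated,
                format_compliance_pct(x$careless$n_responders / x$participation$n_participated)))
  } else {
    cat("minimum valid assessments: not determined\n")
  }
  invisible(x)
}

#' Write a quality report to disk
#'
#' Writes a machine-readable JSON summary plus delimited stage tables
#' (per-day compliance, regression estimates, person alphas, stability curve,
#' responder flags).
#'
#' @param report a `quality_report`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_quality_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- lapply(report$reliability[c("pa", "na")], function(e) {
    out <- list(
      sigma2_between = e$two_level$sigma2_between,
      sigma2_within = e$two_level$sigma2_within,
      icc = e$icc
    )
    if (!is.null(e$reliability)) {
      out$r_krn <- round(e$reliability$r_krn, 2)
      out$r_cn <- round(e$reliability$r_cn, 2)
      out$band_krn <- e$reliability$band_krn
      out$band_cn <- e$reliability$band_cn
    }
    out
  })
  js <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    participation = list(
      n_invited = report$participation$n_invited,
      n_participated = report$participation$n_participated,
      rate_pct = round(100 * report$participation$rate, 1)
    ),
    compliance = list(
      mean_pct = round(100 * report$compliance$summary$mean[1], 1),
      sd_pct = round(100 * report$compliance$summary$sd[1], 1),
      median_pct = round(100 * report$compliance$summary$median[1], 1),
      day_slope = report$compliance$day_slope
    ),
    reliability = rel,
    careless = list(
      responses = report$careless$responses,
      minimum_valid_assessments = report$careless$minimum_valid_assessments,
      n_responders = report$careless$n_responders
    )
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(report$compliance$by_day, file.path(dir, "compliance_by_day.csv"),
                   row.names = FALSE)
  utils::write.csv(report$reliability$person_alpha, file.path(dir, "person_alpha.csv"),
                   row.names = FALSE)
  models <- rbind(
    do.call(rbind, report$participation$models),
    do.call(rbind, report$compliance$models)
  )
  if (!is.null(models) && nrow(models) > 0) {
    utils::write.csv(models, file.path(dir, "regression_models.csv"), row.names = FALSE)
  }
  if (!is.null(report$careless$stability)) {
    utils::write.csv(report$careless$stability$curve,
                     file.path(dir, "stability_curve.csv"), row.names = FALSE)
  }
  if (!is.null(report$careless$responders)) {
    utils::write.csv(report$careless$responders,
                     file.path(dir, "careless_responders.csv"), row.names = FALSE)
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
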