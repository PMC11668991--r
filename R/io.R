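time_fmt <- "%Y-%m-%dT%H:%M:%SZ"

format_iso <- function(x) ifelse(is.na(x), "", format(x, time_fmt, tz = "UTC"))

parse_iso <- function(x) {
  out <- as.POSIXct(x, format = time_fmt, tz = "UTC")
  out[!nzchar(as.character(x)) | is.na(x)] <- NA
  out
}

#' Write a synthetic EMA dataset to delimited text
#'
#' Writes participants.csv, assessments.csv and truth.csv (ground-truth
#' columns: injected careless labels and latent affect, for testing only)
#' with ISO-8601 timestamps.
#'
#' @param dataset list from [generate_ema_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ema_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- dataset$assessments
  for (cn in c("prompt_time", "reminder_time", "expiry_time", "start_time", "end_time")) {
    if (cn %in% names(a)) a[[cn]] <- format_iso(a[[cn]])
  }
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    assessments = file.path(dir, "assessments.csv"),
    truth = file.path(dir, "truth.csv")
  )
  utils::write.csv(dataset$participants, paths["participants"], row.names = FALSE)
  utils::write.csv(a, paths["assessments"], row.names = FALSE)
  utils::write.csv(dataset$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read and validate an assessment table
#'
#' Requires person_id, day, window, completed and the design's item columns.
#' Validates: day within 1..n_ema_days, window within 1..prompts_per_day,
#' items integers within the Likert range (missing only for missed
#' assessments), and no duplicate (person, day, window) key. Timestamp
#' columns are parsed from ISO-8601. Unknown columns are preserved untouched.
#'
#' @param path CSV path.
#' @param design an [ema_design()].
#' @return Validated data frame.
#' @export
read_assessments <- function(path, design = ema_design()) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("person_id", "day", "window", "completed", design$item_ids)
  miss <- setdiff(required, names(a))
  if (length(miss) > 0) stop_emaqc("missing required column(s): %s", paste(miss, collapse = ", "))
  bad_day <- which(a$day < 1 | a$day > design$n_ema_days)
  if (length(bad_day) > 0) stop_emaqc("day out of range 1..%d at row %d", design$n_ema_days, bad_day[1])
  bad_win <- which(a$window < 1 | a$window > design$prompts_per_day)
  if (length(bad_win) > 0) stop_emaqc("window out of range 1..%d at row %d", design$prompts_per_day, bad_win[1])
  key <- paste(a$person_id, a$day, a$window)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_emaqc("duplicate (person, day, window) key at row %d: %s", dup[1], key[dup[1]])
  }
  for (it in design$item_ids) {
    v <- a[[it]]
    bad <- which(!is.na(v) & (v < design$likert_min | v > design$likert_max | v != floor(v)))
    if (length(bad) > 0) {
      stop_emaqc("item %s out of range %d..%d at row %d (value %s)",
                 it, design$likert_min, design$likert_max, bad[1], v[bad[1]])
    }
    miss_completed <- which(a$completed == 1 & is.na(v))
    if (length(miss_completed) > 0) {
      stop_emaqc("item %s missing for completed assessment at row %d", it, miss_completed[1])
    }
  }
  for (cn in c("prompt_time", "reminder_time", "expiry_time", "start_time", "end_time")) {
    if (cn %in% names(a) && is.character(a[[cn]])) a[[cn]] <- parse_iso(a[[cn]])
  }
  a
}

#' Read and validate a participant table
#'
#' Requires person_id, invited, participated, n_completed and compliance;
#' checks the compliance = n_completed / max_prompts identity and that every
#' participant was invited.
#'
#' @param path CSV path.
#' @param design an [ema_design()].
#' @return Validated data frame.
#' @export
read_participants <- function(path, design = ema_design()) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("person_id", "invited", "participated", "n_completed", "compliance")
  miss <- setdiff(required, names(p))
  if (length(miss) > 0) stop_emaqc("missing required column(s): %s", paste(miss, collapse = ", "))
  dup <- which(duplicated(p$person_id))
  if (length(dup) > 0) stop_emaqc("duplicate person_id at row %d", dup[1])
  if (any(p$participated & !p$invited)) stop_emaqc("participated implies invited")
  bad <- which(abs(p$compliance - p$n_completed / max_prompts(design)) > 1e-6)
  if (length(bad) > 0) {
    stop_emaqc("compliance != n_completed/%d at row %d", max_prompts(design), bad[1])
  }
  p
}

#' Read a generator configuration from YAML or JSON
#'
#' The document mirrors the fields of [ema_generator_config()] (top level,
#' with an optional `design` block mirroring [ema_design()]).
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return List with `config` ([ema_generator_config()]) and `design`
#'   ([ema_design()]).
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop_emaqc("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_emaqc("unsupported config extension '%s'", ext)
  }
  design_args <- doc$design %||% list()
  doc$design <- NULL
  for (nm in c("subsample_probs", "sigma2_between", "sigma2_within", "item_variance_components")) {
    if (!is.null(doc[[nm]])) doc[[nm]] <- unlist(doc[[nm]])
  }
  list(
    config = do.call(ema_generator_config, doc),
    design = do.call(ema_design, design_args)
  )
}
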