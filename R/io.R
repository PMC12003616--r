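# Batch input/output. One row (CSV) or object (JSON) per patient-visit:
# feature columns o1..cc4 valued 0/1, optional onset_<code> columns in
# months, and optional raw sub-observation columns from which composite
# features are derived at classification time.

FEATURE_COLS <- tolower(PSP_FEATURE_CODES)
ONSET_COLS <- paste0("onset_", FEATURE_COLS)

RAW_FRONTAL_COLS <- c("frontal_apathy", "frontal_bradyphrenia",
                      "frontal_dysexecutive", "frontal_fluency",
                      "frontal_impulsivity")
RAW_CBS_COLS <- c("cbs_apraxia", "cbs_sensory", "cbs_alien_limb",
                  "cbs_rigidity", "cbs_akinesia", "cbs_myoclonus")
RAW_LDOPA_COLS <- c("ldopa_pre", "ldopa_post", "ldopa_challenge_mg",
                    "ldopa_sustained_mg", "ldopa_sustained_days")
RAW_PULL_COLS <- c("pull_would_fall", "pull_steps",
                   "pull_unaided_recovery", "pull_months")

parse_binary <- function(value, where) {
  if (is.null(value) || is.na(value) || !nzchar(trimws(as.character(value))))
    return(NA)
  v <- trimws(as.character(value))
  if (!v %in% c("0", "1"))
    stop(where, ": value '", v, "' is not 0/1/empty", call. = FALSE)
  v == "1"
}

parse_number <- function(value, where, min = 0) {
  if (is.null(value) || is.na(value) || !nzchar(trimws(as.character(value))))
    return(NA_real_)
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v) || v < min)
    stop(where, ": value '", value, "' is not a number >= ", min,
         call. = FALSE)
  v
}

# Build one psp_record from a named list of raw values (character or
# numeric); `where` prefixes error messages with the row/record position.
build_record <- function(values, where, present_keys) {
  pid <- values[["patient_id"]]
  if (is.null(pid) || is.na(pid) || !nzchar(trimws(as.character(pid))))
    stop(where, ": patient_id is missing or empty", call. = FALSE)
  visit <- parse_number(values[["visit_month"]],
                        paste0(where, ", column 'visit_month'"))

  present <- stats::setNames(rep(FALSE, 16L), PSP_FEATURE_CODES)
  explicit <- character(0)
  for (i in seq_along(FEATURE_COLS)) {
    col <- FEATURE_COLS[i]
    if (!col %in% present_keys) next
    v <- parse_binary(values[[col]], paste0(where, ", column '", col, "'"))
    if (!is.na(v)) {
      present[PSP_FEATURE_CODES[i]] <- v
      explicit <- c(explicit, PSP_FEATURE_CODES[i])
    }
  }
  onset <- stats::setNames(rep(NA_real_, 16L), PSP_FEATURE_CODES)
  for (i in seq_along(ONSET_COLS)) {
    col <- ONSET_COLS[i]
    if (!col %in% present_keys) next
    v <- parse_number(values[[col]], paste0(where, ", column '", col, "'"))
    if (!is.na(v)) {
      code <- PSP_FEATURE_CODES[i]
      if (!present[code])
        stop(where, ": onset given for absent feature ", code, call. = FALSE)
      onset[code] <- v
    }
  }

  raw <- list()
  get_raw <- function(cols, parser) {
    if (!any(cols %in% present_keys)) return(NULL)
    vals <- lapply(cols, function(col)
      if (col %in% present_keys)
        parser(values[[col]], paste0(where, ", column '", col, "'"))
      else NA)
    stats::setNames(vals, cols)
  }
  fr <- get_raw(RAW_FRONTAL_COLS, parse_binary)
  if (!is.null(fr) && !anyNA(unlist(fr)))
    raw$frontal <- lapply(fr, isTRUE)
  cb <- get_raw(RAW_CBS_COLS, parse_binary)
  if (!is.null(cb) && !anyNA(unlist(cb)))
    raw$cbs <- lapply(cb, isTRUE)
  ld <- get_raw(RAW_LDOPA_COLS, parse_number)
  if (!is.null(ld) && !is.na(ld$ldopa_pre) && !is.na(ld$ldopa_post))
    raw$ldopa <- ld
  pl <- list(
    would_fall = if ("pull_would_fall" %in% present_keys)
      parse_binary(values[["pull_would_fall"]],
                   paste0(where, ", column 'pull_would_fall'")) else NA,
    steps = if ("pull_steps" %in% present_keys)
      parse_number(values[["pull_steps"]],
                   paste0(where, ", column 'pull_steps'")) else NA_real_,
    unaided_recovery = if ("pull_unaided_recovery" %in% present_keys)
      parse_binary(values[["pull_unaided_recovery"]],
                   paste0(where, ", column 'pull_unaided_recovery'")) else NA,
    months = if ("pull_months" %in% present_keys)
      parse_number(values[["pull_months"]],
                   paste0(where, ", column 'pull_months'")) else NA_real_)
  if (!is.na(pl$would_fall) && !is.na(pl$steps) && !is.na(pl$unaided_recovery))
    raw$pull <- pl

  profile <- structure(list(present = present, onset = onset),
                       class = "psp_profile")
  structure(list(patient_id = trimws(as.character(pid)),
                 visit_month = visit,
                 explicit = explicit,
                 raw = if (length(raw)) raw else NULL,
                 profile = profile),
            class = "psp_record")
}

#' @export
print.psp_record <- function(x, ...) {
  cat(sprintf("<psp_record> %s%s: %s\n", x$patient_id,
              if (is.na(x$visit_month)) ""
              else sprintf(" (visit month %g)", x$visit_month),
              format(x$profile)))
  invisible(x)
}

#' Read patient-visit records from CSV or JSON
#'
#' Both formats share one flat schema: `patient_id` (required), optional
#' `visit_month`, the 16 feature columns `o1`..`cc4` valued 0/1 (empty =
#' unrecorded), optional onset columns `onset_o1`..`onset_cc4` in months
#' from disease onset, and optional raw sub-observation columns
#' (`frontal_*`, `cbs_*`, `ldopa_*`, `pull_*`) from which composite
#' features are derived during classification. A JSON file holds an array
#' of objects with the same keys. Feature columns missing from the file
#' default to absent with a warning; any feature value other than 0, 1 or
#' empty is an error naming the row and column, as is a duplicated
#' (`patient_id`, `visit_month`) pair.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return List of `psp_record` objects.
#' @export
read_psp_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)

  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = TRUE)
    names(tab) <- tolower(names(tab))
    keys <- names(tab)
    rows <- lapply(seq_len(nrow(tab)), function(i)
      build_record(as.list(tab[i, , drop = FALSE]), sprintf("row %d", i),
                   keys))
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(objs)) stop("JSON input must be an array of records")
    rows <- lapply(seq_along(objs), function(i) {
      o <- objs[[i]]
      names(o) <- tolower(names(o))
      build_record(o, sprintf("record %d", i), names(o))
    })
    keys <- unique(tolower(unlist(lapply(objs, names))))
  }

  missing_cols <- setdiff(FEATURE_COLS, keys)
  if (length(missing_cols) && length(rows))
    warning("feature column(s) absent from input, defaulting to 0: ",
            paste(missing_cols, collapse = ", "), call. = FALSE)

  key <- vapply(rows, function(r)
    paste(r$patient_id, r$visit_month, sep = "\r"), "")
  if (anyDuplicated(key)) {
    d <- rows[[which(duplicated(key))[1]]]
    stop("duplicate (patient_id, visit_month): ", d$patient_id, ", ",
         d$visit_month, call. = FALSE)
  }
  rows
}

# Canonical plain-list form of a report, suitable for loss-free JSON
# serialization (NA -> null, vectors -> arrays).
report_to_list <- function(report) {
  rec_list <- lapply(report$results, function(r) {
    pr <- r$profile
    codes <- names(pr$present)[pr$present]
    ons <- pr$onset[codes]
    ons <- ons[!is.na(ons)]
    list(
      patient_id = r$patient_id,
      visit_month = if (is.na(r$visit_month)) NULL else r$visit_month,
      features = as.list(codes),
      onsets = if (length(ons)) as.list(ons) else NULL,
      allocations = lapply(r$allocations, function(a)
        list(phenotype = a$phenotype, certainty = a$certainty_label,
             satisfied_by = as.list(a$satisfied_by))),
      final = if (is.null(r$diagnosis$final)) NULL else
        list(phenotype = r$diagnosis$phenotype,
             certainty = r$diagnosis$certainty),
      tau_4r = r$diagnosis$tau_4r,
      extinguished = lapply(r$diagnosis$extinguished, function(e)
        list(phenotype = e$allocation$phenotype,
             certainty = e$allocation$certainty_label,
             rule = e$rule)),
      trace = as.list(r$diagnosis$trace)
    )
  })
  list(records = rec_list,
       summary = list(
         n_records = report$summary$n_records,
         by_phenotype = as.list(report$summary$by_phenotype),
         by_certainty = as.list(report$summary$by_certainty),
         n_tau_4r = report$summary$n_tau_4r))
}

write_json_canonical <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write a classification report
#'
#' Three renderings: `json` is loss-free (profiles, all allocations, the
#' full MAX trace, extinguished allocations and summary counts) and round
#' trips through [read_psp_report()]; `csv` is one row per record with the
#' final phenotype (or `"no PSP allocation"`), certainty and a YES/NO
#' 4R-tauopathy cell; `text` is a human-readable per-patient account of
#' features, allocations and the resolution trace.
#'
#' @param report A `psp_report` from [classify_batch()], or a list
#'   previously read with [read_psp_report()] (re-serialized as-is).
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_psp_report <- function(report, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- if (inherits(report, "psp_report")) report_to_list(report)
         else report
    return(write_json_canonical(x, path))
  }
  stopifnot(inherits(report, "psp_report"))
  if (format == "csv") {
    df <- as.data.frame(report)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  lines <- character(0)
  for (r in report$results) {
    dx <- r$diagnosis
    lines <- c(lines,
      sprintf("Patient %s%s", r$patient_id,
              if (is.na(r$visit_month)) ""
              else sprintf(", visit month %g", r$visit_month)),
      sprintf("  Features present: %s", format(r$profile)),
      if (length(r$allocations))
        vapply(r$allocations, function(a)
          sprintf("  Allocation: %s, %s (via %s)", a$phenotype,
                  a$certainty_label,
                  paste(a$satisfied_by, collapse = ", ")), "")
      else "  Allocation: none",
      vapply(dx$trace, function(t) paste0("  ", t), ""),
      sprintf("  Diagnosis: %s",
              if (is.null(dx$final)) "no PSP allocation"
              else sprintf("%s, %s", dx$phenotype, dx$certainty)),
      sprintf("  Probable 4R-tauopathy: %s",
              if (dx$tau_4r) "YES" else "NO"),
      "")
  }
  s <- report$summary
  lines <- c(lines, sprintf("Records: %d", s$n_records),
             "Final phenotype counts:",
             sprintf("  %-18s %d", names(s$by_phenotype), s$by_phenotype))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a JSON classification report
#'
#' Returns the canonical list form written by [write_psp_report()] with
#' `format = "json"`; writing that list again reproduces the file byte for
#' byte.
#'
#' @param path Path to a JSON report.
#' @return Nested list mirroring the JSON structure.
#' @export
read_psp_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
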