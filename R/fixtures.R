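# Synthetic inputs: the 16-feature boolean cube is small enough (2^16 =
# 65,536 profiles) to enumerate exhaustively, which the test suite prefers
# over sampling for oracle comparisons; random cohorts cover the I/O and
# reporting paths.

#' Enumerate all 65,536 feature profiles
#'
#' Yields every present/absent combination of the 16 features exactly once
#' in a deterministic order: row `i` encodes the bits of `i - 1`, with O1
#' as the least-significant bit, so the first row is the all-absent
#' profile. Onsets are undefined throughout.
#'
#' @return A 65,536 x 16 logical matrix with feature codes as column
#'   names. Convert a row to a profile with
#'   `psp_profile(colnames(m)[m[i, ]])`.
#' @examples
#' m <- enumerate_profiles()
#' nrow(m)        # 65536
#' sum(m[1, ])    # 0: first profile is all-absent
#' @export
enumerate_profiles <- function() {
  n <- 65536L
  idx <- 0:(n - 1L)
  P <- matrix(FALSE, n, 16L, dimnames = list(NULL, PSP_FEATURE_CODES))
  for (j in 1:16)
    P[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L
  P
}

# Fast unchecked profile constructor for exhaustive sweeps.
profile_from_flags <- function(flags) {
  structure(list(present = stats::setNames(as.logical(flags),
                                           PSP_FEATURE_CODES),
                 onset = stats::setNames(rep(NA_real_, 16L),
                                         PSP_FEATURE_CODES)),
            class = "psp_profile")
}

#' Minimal satisfying profiles of a rule row
#'
#' One profile per conjunct of the row's formula: exactly that conjunct's
#' literals present, everything else absent. These are the smallest
#' feature sets that trigger the row and serve as fixtures for the
#' row-by-row sweep of the combination table.
#'
#' @param row One rule row from a [psp_rules()] table.
#' @return List of [psp_profile()] objects.
#' @examples
#' rules <- psp_rules()
#' length(minimal_profiles_for_row(rules[[1]]))  # 4 for probable PSP-RS
#' @export
minimal_profiles_for_row <- function(row) {
  stopifnot(is.list(row), !is.null(row$conjuncts))
  lapply(row$conjuncts, psp_profile)
}

#' Default feature prevalences for simulated cohorts
#'
#' Marginal presence probabilities per feature, chosen to resemble a
#' moderately advanced PSP clinic population: falls and vertical gaze
#' involvement common, gait freezing and speech/language presentations
#' rare, clues at background frequency. Features are drawn independently
#' (no progression model), which is all the rule engine's tests require.
#'
#' @return Named numeric vector over the 16 feature codes.
#' @export
psp_default_prevalence <- function() {
  c(O1 = 0.55, O2 = 0.35, O3 = 0.15,
    P1 = 0.60, P2 = 0.35, P3 = 0.15,
    A1 = 0.10, A2 = 0.30, A3 = 0.20,
    C1 = 0.08, C2 = 0.35, C3 = 0.10,
    CC1 = 0.20, CC2 = 0.20, CC3 = 0.20, CC4 = 0.20)
}

#' Sample a synthetic patient cohort
#'
#' Draws `n` independent records: each feature present with its marginal
#' prevalence (independent Bernoulli draws), with optional onset times
#' drawn uniformly per present feature. Reproducible for a fixed seed;
#' the caller's RNG state is restored on exit.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param prevalence Named probability vector over feature codes, see
#'   [psp_default_prevalence()]. Probabilities must lie in `[0, 1]`.
#' @param onset_model `NULL` for no onsets; a numeric `c(min, max)` month
#'   range applied to every present feature; or a named list of such
#'   ranges per feature code (features without an entry get no onset).
#' @return List of `psp_record` objects (patient ids `sim00001`, ...).
#' @examples
#' cohort <- sample_cohort(5, seed = 42)
#' classify_batch(cohort)
#' @export
sample_cohort <- function(n, seed = NULL,
                          prevalence = psp_default_prevalence(),
                          onset_model = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (is.null(names(prevalence)) ||
      !all(names(prevalence) %in% PSP_FEATURE_CODES))
    stop("'prevalence' must be named with valid feature codes")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  prev <- stats::setNames(rep(0, 16L), PSP_FEATURE_CODES)
  prev[names(prevalence)] <- prevalence

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  ranges <- NULL
  if (!is.null(onset_model)) {
    if (is.numeric(onset_model) && length(onset_model) == 2L) {
      ranges <- stats::setNames(
        rep(list(as.numeric(onset_model)), 16L), PSP_FEATURE_CODES)
    } else if (is.list(onset_model)) {
      bad <- setdiff(names(onset_model), PSP_FEATURE_CODES)
      if (length(bad)) stop("unknown feature code(s) in onset_model: ",
                            paste(bad, collapse = ", "))
      ranges <- onset_model
    } else stop("onset_model must be c(min, max) or a named list of ranges")
    for (r in ranges)
      stopifnot(length(r) == 2L, r[1] >= 0, r[2] >= r[1])
  }

  lapply(seq_len(n), function(i) {
    pres <- stats::setNames(stats::runif(16L) < prev, PSP_FEATURE_CODES)
    ons <- stats::setNames(rep(NA_real_, 16L), PSP_FEATURE_CODES)
    if (!is.null(ranges)) {
      for (code in names(ranges))
        if (pres[code])
          ons[code] <- stats::runif(1L, ranges[[code]][1], ranges[[code]][2])
    }
    structure(list(patient_id = sprintf("sim%05d", i),
                   visit_month = NA_real_,
                   explicit = PSP_FEATURE_CODES,
                   raw = NULL,
                   profile = structure(list(present = pres, onset = ons),
                                       class = "psp_profile")),
              class = "psp_record")
  })
}

#' Write a cohort in the standard record schema
#'
#' Serializes records from [sample_cohort()] (or [read_psp_records()]) to
#' the flat CSV/JSON schema accepted by [read_psp_records()].
#'
#' @param records List of `psp_record` objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_psp_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  any_onset <- any(vapply(records, function(r)
    any(!is.na(r$profile$onset)), logical(1)))
  rows <- lapply(records, function(r) {
    vals <- list(patient_id = r$patient_id,
                 visit_month = if (is.na(r$visit_month)) NA else r$visit_month)
    for (i in seq_along(PSP_FEATURE_CODES))
      vals[[FEATURE_COLS[i]]] <-
        as.integer(r$profile$present[PSP_FEATURE_CODES[i]])
    if (any_onset)
      for (i in seq_along(PSP_FEATURE_CODES)) {
        v <- r$profile$onset[PSP_FEATURE_CODES[i]]
        vals[[ONSET_COLS[i]]] <- if (is.na(v)) NA else unname(v)
      }
    vals
  })
  if (format == "csv") {
    df <- do.call(rbind, lapply(rows, function(v)
      as.data.frame(v, stringsAsFactors = FALSE)))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    clean <- lapply(rows, function(v) Filter(function(x)
      !(length(x) == 1L && is.na(x)), v))
    write_json_canonical(clean, path)
  }
  invisible(path)
}

#' Exhaustive diagnosis table over the profile cube
#'
#' Classifies all 65,536 feature profiles (onsets undefined, so the MAX
#' temporal rule never fires) with a vectorized pass of the same
#' data-driven rule table, and resolves each to its final diagnosis.
#'
#' @param rules A [psp_rules()] table.
#' @param tau_map A [psp_tau_map()].
#' @param phenotype_order Residual tie-break order (PSP-RS first
#'   implements PSP-RS precedence).
#' @return Data frame with 65,536 rows: the 16 feature columns (0/1),
#'   `final_phenotype` (`NA` when no rule fires), `certainty` and
#'   `tau_4r`.
#' @export
enumerate_diagnoses <- function(rules = psp_rules(),
                                tau_map = psp_tau_map(),
                                phenotype_order = psp_phenotype_order()) {
  P <- enumerate_profiles()
  cert <- eval_rules_matrix(P, rules)
  maxc <- do.call(pmax, as.data.frame(cert))
  final <- rep(NA_character_, nrow(P))
  for (ph in phenotype_order) {
    hit <- is.na(final) & maxc > 0L & cert[, ph] == maxc
    final[hit] <- ph
  }
  lab <- ifelse(maxc > 0L, CERTAINTY_LEVELS[pmax(maxc, 1L)], NA_character_)
  tau <- rep(FALSE, nrow(P))
  ok <- !is.na(final)
  tau[ok] <- tau_map[cbind(final[ok], lab[ok])]
  out <- as.data.frame(P + 0L)
  names(out) <- FEATURE_COLS
  out$final_phenotype <- final
  out$certainty <- lab
  out$tau_4r <- tau
  out
}
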