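# Feature vocabulary and composite-feature derivation for the MDS-PSP
# criteria: four core functional domains (O, P, A, C), three
# certainty-stratified features each, plus four clinical clues.

#' Core clinical feature vocabulary
#'
#' The 16 binary features the classifier operates on: twelve core clinical
#' features across four functional domains -- ocular motor (O), postural
#' instability (P), akinesia (A) and cognitive dysfunction (C), each
#' stratified by level of diagnostic certainty (1 highest, 2 intermediate,
#' 3 lowest) -- and four clinical clues (CC1--CC4). The features P1, P2, P3
#' and A1 are time-constrained: the criteria require them to occur within
#' the first three years of disease (see [apply_temporal_gate()]).
#'
#' @return A data frame with one row per feature code and columns `code`,
#'   `domain`, `stratum` (1--3 for core features, `NA` for clues),
#'   `time_constrained` (logical) and `label` (short clinical description).
#' @examples
#' psp_features()
#' @export
psp_features <- function() {
  data.frame(
    code = PSP_FEATURE_CODES,
    domain = c(rep("ocular motor", 3), rep("postural instability", 3),
               rep("akinesia", 3), rep("cognitive", 3),
               rep("clinical clue", 4)),
    stratum = c(rep(1:3, 4), rep(NA_integer_, 4)),
    time_constrained = PSP_FEATURE_CODES %in% PSP_TIME_CONSTRAINED,
    label = c(
      "Vertical supranuclear gaze palsy (VSGP)",
      "Slow velocity of vertical saccades",
      "Macro square wave jerks or eyelid opening apraxia",
      "Repeated unprovoked falls within 3 years",
      "Tendency to fall on the pull test within 3 years",
      "More than 2 steps backward on the pull test, unaided recovery, within 3 years",
      "Progressive gait freezing within 3 years",
      "Parkinsonism, akinetic-rigid, axial-predominant, levodopa-resistant",
      "Parkinsonism with tremor and/or asymmetric and/or levodopa-responsive",
      "nfaPPA or progressive apraxia of speech",
      "Frontal cognitive/behavioral presentation",
      "Corticobasal syndrome (CBS)",
      "Clinical clue 1", "Clinical clue 2", "Clinical clue 3", "Clinical clue 4"
    ),
    stringsAsFactors = FALSE
  )
}

PSP_FEATURE_CODES <- c("O1", "O2", "O3", "P1", "P2", "P3",
                       "A1", "A2", "A3", "C1", "C2", "C3",
                       "CC1", "CC2", "CC3", "CC4")

# Features the criteria require within the first 3 years of disease.
PSP_TIME_CONSTRAINED <- c("P1", "P2", "P3", "A1")

#' Construct a clinical feature profile
#'
#' A feature profile is the classifier's sole input: presence/absence of the
#' 16 core clinical features and clues, with an optional symptom-onset time
#' (months from disease onset) per present feature. Onset times are used by
#' the three-year temporal gate ([apply_temporal_gate()]) and by the MAX
#' temporal-precedence rule ([resolve_max()]); bare profiles without onsets
#' are accepted everywhere and treated as already temporally valid.
#'
#' @param present Character vector of feature codes that are present (see
#'   [psp_features()] for the vocabulary), or a named logical vector over
#'   the full vocabulary.
#' @param onset Optional named numeric vector of onset times in months from
#'   disease onset; names must be codes listed in `present`, values must be
#'   non-negative.
#' @return An object of class `psp_profile`: a list with elements `present`
#'   (named logical over all 16 codes) and `onset` (named numeric, `NA`
#'   where no onset is recorded).
#' @examples
#' psp_profile(c("O1", "P1"), onset = c(O1 = 10, P1 = 6))
#' @export
psp_profile <- function(present = character(), onset = NULL) {
  if (is.logical(present)) {
    if (is.null(names(present)) || !all(names(present) %in% PSP_FEATURE_CODES))
      stop("logical 'present' must be named with valid feature codes")
    codes <- names(present)[present]
  } else {
    codes <- toupper(as.character(present))
  }
  bad <- setdiff(codes, PSP_FEATURE_CODES)
  if (length(bad))
    stop("unknown feature code(s): ", paste(bad, collapse = ", "))
  pres <- stats::setNames(PSP_FEATURE_CODES %in% codes, PSP_FEATURE_CODES)
  ons <- stats::setNames(rep(NA_real_, 16L), PSP_FEATURE_CODES)
  if (!is.null(onset) && length(onset)) {
    onames <- toupper(names(onset))
    if (is.null(names(onset)) || !all(onames %in% PSP_FEATURE_CODES))
      stop("'onset' must be named with valid feature codes")
    if (!all(onames %in% codes))
      stop("onset given for absent feature(s): ",
           paste(setdiff(onames, codes), collapse = ", "))
    if (any(!is.na(onset) & onset < 0))
      stop("onset months must be non-negative")
    ons[onames] <- as.numeric(onset)
  }
  structure(list(present = pres, onset = ons), class = "psp_profile")
}

#' @export
print.psp_profile <- function(x, ...) {
  codes <- names(x$present)[x$present]
  cat("<psp_profile> ", length(codes), " feature(s) present\n", sep = "")
  if (length(codes)) {
    ons <- x$onset[codes]
    lab <- ifelse(is.na(ons), codes, sprintf("%s (onset %g mo)", codes, ons))
    cat(" ", paste(lab, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.psp_profile <- function(x, ...) {
  codes <- names(x$present)[x$present]
  if (!length(codes)) return("{}")
  paste0("{", paste(codes, collapse = ","), "}")
}

is_psp_profile <- function(x) inherits(x, "psp_profile")

#' Derive the frontal cognitive/behavioral presentation (feature C2)
#'
#' The intermediate-certainty cognitive feature is present when at least 3
#' of 5 frontal items are observed: apathy, bradyphrenia, dysexecutive
#' syndrome, reduced phonemic verbal fluency, and
#' impulsivity/disinhibition/perseveration.
#'
#' @param apathy,bradyphrenia,dysexecutive,reduced_phonemic_fluency,impulsivity
#'   Logical flags, one per frontal item (`impulsivity` covers impulsivity,
#'   disinhibition and perseveration as a single item).
#' @return `TRUE` if at least three items are present, intended to populate
#'   feature C2.
#' @examples
#' derive_frontal_presentation(TRUE, TRUE, TRUE, FALSE, FALSE)  # TRUE
#' @export
derive_frontal_presentation <- function(apathy, bradyphrenia, dysexecutive,
                                        reduced_phonemic_fluency,
                                        impulsivity) {
  flags <- c(apathy, bradyphrenia, dysexecutive,
             reduced_phonemic_fluency, impulsivity)
  stopifnot(length(flags) == 5L, is.logical(flags), !anyNA(flags))
  sum(flags) >= 3L
}

#' Derive corticobasal syndrome (feature C3)
#'
#' CBS, the lowest-certainty cognitive feature, requires at least one
#' cortical sign (orobuccal or limb apraxia, cortical sensory deficit,
#' alien limb phenomena) together with at least one movement-disorder sign
#' (limb rigidity, akinesia, myoclonus).
#'
#' @param apraxia,cortical_sensory_deficit,alien_limb Cortical-sign flags.
#' @param rigidity,akinesia,myoclonus Movement-disorder-sign flags.
#' @return `TRUE` if at least one sign from each category is present;
#'   intended to populate feature C3.
#' @examples
#' derive_cbs(alien_limb = TRUE, rigidity = TRUE,
#'            apraxia = FALSE, cortical_sensory_deficit = FALSE,
#'            akinesia = FALSE, myoclonus = FALSE)  # TRUE
#' @export
derive_cbs <- function(apraxia, cortical_sensory_deficit, alien_limb,
                       rigidity, akinesia, myoclonus) {
  cortical <- c(apraxia, cortical_sensory_deficit, alien_limb)
  movement <- c(rigidity, akinesia, myoclonus)
  stopifnot(length(cortical) == 3L, length(movement) == 3L,
            is.logical(cortical), is.logical(movement),
            !anyNA(cortical), !anyNA(movement))
  any(cortical) && any(movement)
}

#' Assess levodopa resistance from a challenge or sustained regimen
#'
#' Levodopa resistance -- the property separating akinetic-rigid,
#' axial-predominant parkinsonism (A2) from tremulous/asymmetric/responsive
#' parkinsonism (A3) -- is defined as improvement of the MDS-UPDRS motor
#' score of at most 30% under a qualifying regimen: a challenge dose of at
#' least 200 mg, or at least 1000 mg daily sustained for one month (encoded
#' as >= 30 days). Improvement is `(pre - post) / pre`; worsening (negative
#' improvement) therefore counts as resistant.
#'
#' @param pre_score,post_score MDS-UPDRS part III motor totals before and
#'   after levodopa (points, >= 0).
#' @param challenge_dose_mg Optional single challenge dose in mg.
#' @param sustained_dose_mg Optional sustained daily dose in mg.
#' @param sustained_duration_days Optional duration of the sustained regimen
#'   in days.
#' @return `TRUE` (resistant, supports A2), `FALSE` (responsive, supports
#'   A3), or `NA` when resistance is not assessable: no qualifying regimen,
#'   or `pre_score` is zero.
#' @examples
#' assess_levodopa_resistance(40, 30, challenge_dose_mg = 200)  # TRUE (25%)
#' assess_levodopa_resistance(40, 20, challenge_dose_mg = 250)  # FALSE (50%)
#' assess_levodopa_resistance(40, 30, challenge_dose_mg = 100)  # NA
#' @export
assess_levodopa_resistance <- function(pre_score, post_score,
                                       challenge_dose_mg = NULL,
                                       sustained_dose_mg = NULL,
                                       sustained_duration_days = NULL) {
  stopifnot(is.numeric(pre_score), is.numeric(post_score),
            pre_score >= 0, post_score >= 0)
  ok_challenge <- !is.null(challenge_dose_mg) && !is.na(challenge_dose_mg) &&
    challenge_dose_mg >= 200
  ok_sustained <- !is.null(sustained_dose_mg) && !is.na(sustained_dose_mg) &&
    sustained_dose_mg >= 1000 &&
    !is.null(sustained_duration_days) && !is.na(sustained_duration_days) &&
    sustained_duration_days >= 30
  if (!(ok_challenge || ok_sustained) || pre_score == 0) return(NA)
  improvement <- (pre_score - post_score) / pre_score
  improvement <= 0.30
}

#' Map a pull-test observation to a postural-instability feature
#'
#' The MDS-UPDRS item 3.12 retropulsion test yields P2 when the patient
#' would fall if not caught by the examiner, P3 when the patient takes more
#' than two steps backward but recovers unaided, and no feature otherwise.
#'
#' @param would_fall_if_not_caught Logical; patient would fall without the
#'   examiner's catch.
#' @param steps_backward Non-negative integer count of backward steps
#'   (meaningful when the patient is not caught).
#' @param unaided_recovery Logical; patient recovered without help.
#' @return One of `"P2"`, `"P3"` or `"none"`.
#' @examples
#' derive_pull_test_feature(TRUE, 0, FALSE)   # "P2"
#' derive_pull_test_feature(FALSE, 3, TRUE)   # "P3"
#' derive_pull_test_feature(FALSE, 2, TRUE)   # "none"
#' @export
derive_pull_test_feature <- function(would_fall_if_not_caught, steps_backward,
                                     unaided_recovery) {
  stopifnot(is.logical(would_fall_if_not_caught), is.logical(unaided_recovery),
            is.numeric(steps_backward), steps_backward >= 0)
  if (isTRUE(would_fall_if_not_caught)) return("P2")
  if (steps_backward > 2 && isTRUE(unaided_recovery)) return("P3")
  "none"
}

#' Apply the three-year temporal gate
#'
#' The criteria require the time-constrained features (P1, P2, P3, A1) to
#' occur within the first three years of disease. This gate removes any
#' time-constrained feature whose recorded onset exceeds the window;
#' the boundary is inclusive (onset of exactly `window_months` is
#' retained). Features without a recorded onset are left unchanged -- bare
#' presence flags are trusted as already temporally valid -- and features
#' outside the time-constrained set are never touched.
#'
#' @param profile A [psp_profile()].
#' @param window_months Positive gate width in months; default 36.
#' @return A gated `psp_profile`. The operation is idempotent and can only
#'   remove features, never add them.
#' @examples
#' p <- psp_profile(c("P1", "O1"), onset = c(P1 = 40, O1 = 60))
#' apply_temporal_gate(p)  # P1 dropped, O1 kept
#' @export
apply_temporal_gate <- function(profile, window_months = 36) {
  stopifnot(is_psp_profile(profile), is.numeric(window_months),
            window_months > 0)
  drop <- names(profile$present)[
    profile$present &
      names(profile$present) %in% PSP_TIME_CONSTRAINED &
      !is.na(profile$onset) & profile$onset > window_months
  ]
  if (length(drop)) {
    profile$present[drop] <- FALSE
    profile$onset[drop] <- NA_real_
  }
  profile
}
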