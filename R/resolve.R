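# Multiple Allocations eXtinction (MAX): a patient can satisfy several
# phenotype/certainty rows at one visit; the MAX precedence scheme
# collapses them to a single diagnosis -- (1) diagnostic certainty,
# (2) temporal order of symptom onset, (3) PSP-RS prevails over any
# variant, then a fixed documented order among variants.

#' Default residual tie-break order among phenotypes
#'
#' Applied only after certainty, temporal order and PSP-RS precedence have
#' all failed to single out one allocation. PSP-RS heads the order; the
#' variant order after it is a fixed package convention (the criteria
#' print no order among variants) and can be overridden with a
#' configuration file of one `phenotype` column.
#'
#' @param path Optional path to a tab-separated file with a `phenotype`
#'   column listing all eight phenotypes in priority order; `NULL` loads
#'   the shipped default.
#' @return Character vector of the eight phenotypes in precedence order.
#' @export
psp_phenotype_order <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_tie_break.tsv", package = "psprules")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  ord <- trimws(tab$phenotype)
  if (!setequal(ord, PSP_PHENOTYPES) || length(ord) != 8L)
    stop("tie-break order must list each of the 8 phenotypes exactly once")
  ord
}

#' Probable 4R-tauopathy membership map
#'
#' Which (phenotype, certainty) pairs qualify for the joint PSP/CBD
#' "probable 4R-tauopathy" category used for trial recruitment. The
#' shipped default follows the MDS criteria publication (Hoeglinger et
#' al. 2017): any phenotype at probable certainty, plus possible PSP-CBS.
#' The map is configuration, total over all 8 x 3 pairs, and overridable.
#'
#' @param path Optional path to a tab-separated file with columns
#'   `phenotype`, `certainty`, `tau_4r` (yes/no); `NULL` loads the default.
#' @return An object of class `psp_tau_map`: an 8 x 3 logical matrix,
#'   rows = phenotypes, columns = certainty levels.
#' @examples
#' psp_tau_map()["PSP-CBS", "possible"]  # TRUE
#' @export
psp_tau_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tau_map_4r.tsv", package = "psprules")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("phenotype", "certainty", "tau_4r")
  if (!all(need %in% names(tab)))
    stop("tau map must have columns: ", paste(need, collapse = ", "))
  m <- matrix(NA, length(PSP_PHENOTYPES), length(CERTAINTY_LEVELS),
              dimnames = list(PSP_PHENOTYPES, CERTAINTY_LEVELS))
  for (i in seq_len(nrow(tab))) {
    ph <- trimws(tab$phenotype[i])
    if (!ph %in% PSP_PHENOTYPES)
      stop("unknown phenotype '", ph, "' in tau map row ", i)
    lev <- certainty_label(certainty_rank(tab$certainty[i]))
    val <- tolower(trimws(tab$tau_4r[i]))
    if (!val %in% c("yes", "no", "true", "false"))
      stop("tau map row ", i, ": tau_4r must be yes/no")
    m[ph, lev] <- val %in% c("yes", "true")
  }
  if (anyNA(m))
    stop("tau map must cover all 24 (phenotype, certainty) pairs")
  structure(m, class = c("psp_tau_map", class(m)))
}

#' Onset of a phenotype allocation
#'
#' The MAX temporal rule anchors each allocated phenotype at the earliest
#' symptom onset among the features that satisfied its rule. If any
#' contributing feature lacks a recorded onset the phenotype onset is
#' unknown (`NA`): absence of evidence must not promote a phenotype.
#'
#' @param allocation One allocation from [evaluate_allocations()].
#' @param profile The [psp_profile()] the allocation was produced from.
#' @return Earliest onset in months, or `NA` if unknown.
#' @examples
#' p <- psp_profile(c("O1", "P1"), onset = c(O1 = 10, P1 = 6))
#' a <- evaluate_allocations(p)[[1]]
#' phenotype_onset(a, p)  # 6
#' @export
phenotype_onset <- function(allocation, profile) {
  stopifnot(is_psp_profile(profile))
  ons <- profile$onset[allocation$satisfied_by]
  if (!length(ons) || anyNA(ons)) return(NA_real_)
  min(ons)
}

#' Resolve multiple allocations to a single diagnosis (MAX rules)
#'
#' Filters the allocation set sequentially: (1) keep only allocations at
#' the maximum diagnostic certainty; (2) among ties, keep those with the
#' earliest known phenotype onset (unknown onsets rank after every known
#' onset and tie with each other); (3) PSP-RS prevails over any variant;
#' (4) any residual tie falls through to a fixed documented phenotype
#' order. Exactly one allocation survives whenever the input is non-empty.
#' The returned diagnosis carries the full explanation trace, every
#' extinguished allocation labelled with the rule that removed it, and the
#' probable-4R-tauopathy flag for the final (phenotype, certainty) pair.
#'
#' @param allocations A `psp_allocations` set from [evaluate_allocations()]
#'   on `profile`.
#' @param profile The [psp_profile()] the allocations came from (onset
#'   times feed the temporal rule).
#' @param tau_map A [psp_tau_map()].
#' @param phenotype_order Residual tie-break order, see
#'   [psp_phenotype_order()].
#' @return An object of class `psp_diagnosis`: list with `final` (the
#'   surviving allocation, or `NULL` for an empty input), `phenotype`,
#'   `certainty` (label, `NA` when none), `tau_4r` (logical),
#'   `extinguished` (list of `list(allocation, rule)`) and `trace`
#'   (character vector describing each applied step).
#' @examples
#' p <- psp_profile(c("O1", "P1"))
#' resolve_max(evaluate_allocations(p), p)
#' @export
resolve_max <- function(allocations, profile,
                        tau_map = psp_tau_map(),
                        phenotype_order = psp_phenotype_order()) {
  stopifnot(is_psp_profile(profile))
  extinguished <- list()
  trace <- character(0)
  alive <- unclass(allocations)

  drop_allocs <- function(keep_idx, rule, line) {
    dead <- alive[-keep_idx]
    for (d in dead)
      extinguished[[length(extinguished) + 1L]] <<-
        list(allocation = d, rule = rule)
    trace <<- c(trace, line)
    alive <<- alive[keep_idx]
  }

  if (length(alive)) {
    desc <- function(ix) paste(
      vapply(alive[ix], function(a)
        sprintf("%s (%s)", a$phenotype, a$certainty_label), ""),
      collapse = ", ")

    # MAX 1: diagnostic certainty
    certs <- vapply(alive, `[[`, 0L, "certainty")
    if (length(alive) > 1L && any(certs < max(certs))) {
      keep <- which(certs == max(certs))
      drop_allocs(keep, "MAX rule 1 (diagnostic certainty)",
                  sprintf("MAX rule 1: highest certainty is '%s'; kept %s",
                          certainty_label(max(certs)), desc(keep)))
    }

    # MAX 2: temporal order of symptom onset
    if (length(alive) > 1L) {
      ons <- vapply(alive, phenotype_onset, 0, profile = profile)
      if (any(!is.na(ons))) {
        eff <- ifelse(is.na(ons), Inf, ons)
        if (any(eff > min(eff))) {
          keep <- which(eff == min(eff))
          drop_allocs(keep, "MAX rule 2 (temporal order of symptom onset)",
                      sprintf("MAX rule 2: earliest phenotype onset %g months; kept %s",
                              min(eff), desc(keep)))
        }
      }
    }

    # MAX 3: PSP-RS prevails over any vPSP
    if (length(alive) > 1L) {
      phs <- vapply(alive, `[[`, "", "phenotype")
      if ("PSP-RS" %in% phs) {
        drop_allocs(which(phs == "PSP-RS"),
                    "MAX rule 3 (PSP-RS prevails over variant PSP)",
                    "MAX rule 3: PSP-RS prevails over variant PSP")
      }
    }

    # Residual fixed-order tie-break
    if (length(alive) > 1L) {
      phs <- vapply(alive, `[[`, "", "phenotype")
      keep <- which.min(match(phs, phenotype_order))
      drop_allocs(keep, "fixed phenotype-order tie-break",
                  sprintf("Residual tie broken by fixed phenotype order; kept %s",
                          desc(keep)))
    }
  }

  final <- if (length(alive)) alive[[1L]] else NULL
  tau <- flag_4r_tauopathy(final, tau_map)
  if (!is.null(final))
    trace <- c(trace, sprintf("Final diagnosis: %s, %s; probable 4R-tauopathy: %s",
                              final$phenotype, final$certainty_label,
                              if (tau) "YES" else "NO"))
  structure(list(final = final,
                 phenotype = if (is.null(final)) NA_character_ else final$phenotype,
                 certainty = if (is.null(final)) NA_character_ else final$certainty_label,
                 tau_4r = tau,
                 extinguished = extinguished,
                 trace = trace),
            class = "psp_diagnosis")
}

#' Probable 4R-tauopathy flag for a final allocation
#'
#' @param final The surviving allocation from [resolve_max()], or `NULL`
#'   when there is no PSP allocation.
#' @param tau_map A [psp_tau_map()].
#' @return Logical: does the final (phenotype, certainty) pair qualify as
#'   probable 4R-tauopathy? `FALSE` when `final` is `NULL`.
#' @export
flag_4r_tauopathy <- function(final, tau_map = psp_tau_map()) {
  stopifnot(inherits(tau_map, "psp_tau_map"))
  if (is.null(final)) return(FALSE)
  unname(tau_map[final$phenotype, final$certainty_label])
}

#' Classify one clinical feature profile end to end
#'
#' Convenience wrapper: applies the three-year temporal gate (a no-op when
#' no onsets are recorded), evaluates all phenotype allocations, resolves
#' them with the MAX rules and attaches the probable-4R-tauopathy flag.
#'
#' @param profile A [psp_profile()].
#' @param rules A [psp_rules()] table.
#' @param tau_map A [psp_tau_map()].
#' @param phenotype_order Residual tie-break order.
#' @param gate_window Temporal-gate width in months (default 36); `NULL`
#'   disables gating.
#' @param subsume_strata Passed to [evaluate_allocations()].
#' @return A `psp_diagnosis` (see [resolve_max()]) with the evaluated
#'   allocation set attached as attribute `allocations` and the gated
#'   profile as attribute `profile`.
#' @examples
#' psp_diagnose(psp_profile(c("O1", "P1")))
#' @export
psp_diagnose <- function(profile, rules = psp_rules(),
                         tau_map = psp_tau_map(),
                         phenotype_order = psp_phenotype_order(),
                         gate_window = 36, subsume_strata = FALSE) {
  if (!is.null(gate_window))
    profile <- apply_temporal_gate(profile, gate_window)
  alloc <- evaluate_allocations(profile, rules, subsume_strata)
  dx <- resolve_max(alloc, profile, tau_map, phenotype_order)
  attr(dx, "allocations") <- alloc
  attr(dx, "profile") <- profile
  dx
}

#' @export
print.psp_diagnosis <- function(x, ...) {
  cat("<psp_diagnosis>\n")
  if (is.null(x$final)) {
    cat("  no PSP allocation\n")
  } else {
    cat(sprintf("  final: %s, %s\n", x$phenotype, x$certainty))
  }
  cat("  probable 4R-tauopathy:", if (x$tau_4r) "YES" else "NO", "\n")
  if (length(x$extinguished)) {
    cat("  extinguished:\n")
    for (e in x$extinguished)
      cat(sprintf("    %s (%s) by %s\n", e$allocation$phenotype,
                  e$allocation$certainty_label, e$rule))
  }
  if (length(x$trace)) {
    cat("  trace:\n")
    for (t in x$trace) cat("    -", t, "\n")
  }
  invisible(x)
}
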