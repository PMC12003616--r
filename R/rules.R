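# The allocation engine: a data-driven evaluator of the MDS-PSP
# phenotype/certainty combination table. Rules are shipped as data (a TSV
# of monotone positive formulas in disjunctive normal form), so criterion
# corrections never require a code change.

#' PSP phenotypes
#'
#' The eight clinical phenotypes of the MDS-PSP criteria. PSP-RS
#' (Richardson's syndrome) is the apex of the phenotype hierarchy; the
#' remaining seven are variant PSP (vPSP).
#'
#' @return Character vector of the eight phenotype names.
#' @export
psp_phenotypes <- function() PSP_PHENOTYPES

PSP_PHENOTYPES <- c("PSP-RS", "PSP-P", "PSP-PGF", "PSP-F",
                    "PSP-OM", "PSP-SL", "PSP-CBS", "PSP-PI")

#' Diagnostic certainty levels, lowest to highest
#'
#' The criteria attach one of three certainty levels to every phenotype
#' allocation, totally ordered: `suggestive of` < `possible` < `probable`.
#'
#' @return Character vector of the three levels in increasing order.
#' @export
certainty_levels <- function() CERTAINTY_LEVELS

CERTAINTY_LEVELS <- c("suggestive of", "possible", "probable")

# Canonicalize a certainty string to its integer rank 1..3.
certainty_rank <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("suggestive", "suggestive-of", "suggestive_of")] <- "suggestive of"
  r <- match(x, CERTAINTY_LEVELS)
  if (anyNA(r)) stop("unknown certainty level: ",
                     paste(unique(x[is.na(r)]), collapse = ", "))
  r
}

certainty_label <- function(rank) CERTAINTY_LEVELS[rank]

parse_dnf <- function(formula, where = "") {
  conj <- strsplit(formula, "|", fixed = TRUE)[[1]]
  conj <- trimws(conj)
  conj <- conj[nzchar(conj)]
  if (!length(conj)) stop("empty formula", where)
  lapply(conj, function(cj) {
    lits <- toupper(trimws(strsplit(cj, "+", fixed = TRUE)[[1]]))
    lits <- lits[nzchar(lits)]
    bad <- setdiff(lits, PSP_FEATURE_CODES)
    if (length(bad))
      stop("unknown feature code(s) ", paste(bad, collapse = ", "), where)
    if (anyDuplicated(lits))
      stop("duplicated literal in conjunct '", cj, "'", where)
    lits
  })
}

#' Load a phenotype/certainty rule table
#'
#' Reads a rule table: a tab-separated file with columns `phenotype`,
#' `certainty` and `formula`, one row per (phenotype, certainty) pair. A
#' formula is a positive boolean expression in disjunctive normal form over
#' feature codes: conjuncts separated by `|`, literals within a conjunct
#' joined by `+`, no negation (all rules of the criteria are monotone).
#' The shipped default transcribes the MDS-PSP combination table exactly:
#' 16 rows covering the eight phenotypes.
#'
#' @param path Path to a rule table file; `NULL` (default) loads the
#'   shipped MDS-PSP table.
#' @return An object of class `psp_rules`: a list of rule rows, each with
#'   elements `phenotype`, `certainty` (rank 1--3), `certainty_label` and
#'   `conjuncts` (list of character vectors of feature codes).
#' @examples
#' rules <- psp_rules()
#' length(rules)  # 16
#' as.data.frame(rules)
#' @export
psp_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "mds_psp_rules.tsv", package = "psprules")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, sep = "\t",
                           strip.white = TRUE)
  need <- c("phenotype", "certainty", "formula")
  if (!all(need %in% names(tab)))
    stop("rule table must have columns: ", paste(need, collapse = ", "))
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    where <- sprintf(" (rule row %d: %s / %s)", i, tab$phenotype[i],
                     tab$certainty[i])
    ph <- trimws(tab$phenotype[i])
    if (!ph %in% PSP_PHENOTYPES)
      stop("unknown phenotype '", ph, "'", where)
    rank <- tryCatch(certainty_rank(tab$certainty[i]),
                     error = function(e) stop(conditionMessage(e), where,
                                              call. = FALSE))
    rows[[i]] <- list(phenotype = ph, certainty = rank,
                      certainty_label = certainty_label(rank),
                      conjuncts = parse_dnf(tab$formula[i], where))
  }
  key <- vapply(rows, function(r) paste(r$phenotype, r$certainty), "")
  if (anyDuplicated(key))
    stop("duplicate (phenotype, certainty) rule row: ",
         key[duplicated(key)][1])
  structure(rows, class = "psp_rules", source = path)
}

#' @export
print.psp_rules <- function(x, ...) {
  cat("<psp_rules> ", length(x), " rule row(s)\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.psp_rules <- function(x, ...) {
  data.frame(
    phenotype = vapply(x, `[[`, "", "phenotype"),
    certainty = vapply(x, `[[`, "", "certainty_label"),
    formula = vapply(x, function(r)
      paste(vapply(r$conjuncts, paste, "", collapse = "+"), collapse = " | "),
      ""),
    stringsAsFactors = FALSE
  )
}

# Expand presence flags for stratum-subsumption mode: a literal Xk is
# treated as satisfied when any feature of the same domain with stratum
# <= k is present. Clinical clues carry no stratum and match literally.
subsume_present <- function(present) {
  eff <- present
  for (dom in c("O", "P", "A", "C")) {
    codes <- paste0(dom, 1:3)
    eff[codes[2]] <- eff[codes[2]] || present[codes[1]]
    eff[codes[3]] <- eff[codes[3]] || present[codes[1]] || present[codes[2]]
  }
  eff
}

#' Evaluate all phenotype allocations for a profile
#'
#' Applies every rule row to the profile's present-feature set and returns,
#' for each phenotype, at most one allocation at the highest satisfied
#' certainty. Matching is literal: a higher-stratum feature does not stand
#' in for a lower one unless the formula names it (e.g. O1 does not satisfy
#' a slot that names O2). An optional stratum-subsumption mode relaxes this
#' within each core domain; it is off by default and off in all shipped
#' checks.
#'
#' @param profile A [psp_profile()].
#' @param rules A [psp_rules()] table.
#' @param subsume_strata Logical; if `TRUE`, a literal is also satisfied by
#'   any higher-certainty feature of the same domain. Default `FALSE`.
#' @return An object of class `psp_allocations`: a list of allocations,
#'   each a list with `phenotype`, `certainty` (rank), `certainty_label`
#'   and `satisfied_by` (the present features occurring in satisfied
#'   conjuncts of the winning rule row). Empty when no rule fires.
#' @examples
#' evaluate_allocations(psp_profile(c("O1", "P1")))
#' @export
evaluate_allocations <- function(profile, rules = psp_rules(),
                                 subsume_strata = FALSE) {
  stopifnot(is_psp_profile(profile), inherits(rules, "psp_rules"))
  present <- profile$present
  eff <- if (subsume_strata) subsume_present(present) else present
  best <- list()
  for (row in rules) {
    ph <- row$phenotype
    if (!is.null(best[[ph]]) && best[[ph]]$certainty >= row$certainty) next
    sat <- vapply(row$conjuncts, function(cj) all(eff[cj]), logical(1))
    if (any(sat)) {
      lits <- unique(unlist(row$conjuncts[sat]))
      best[[ph]] <- list(phenotype = ph, certainty = row$certainty,
                         certainty_label = certainty_label(row$certainty),
                         satisfied_by = lits[present[lits]])
    }
  }
  out <- best[intersect(PSP_PHENOTYPES, names(best))]
  names(out) <- NULL
  structure(out, class = "psp_allocations")
}

#' @export
print.psp_allocations <- function(x, ...) {
  if (!length(x)) {
    cat("<psp_allocations> no PSP allocation\n")
    return(invisible(x))
  }
  cat("<psp_allocations> ", length(x), " allocation(s)\n", sep = "")
  for (a in x)
    cat(sprintf("  %-8s %-13s via %s\n", a$phenotype, a$certainty_label,
                paste(a$satisfied_by, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.psp_allocations <- function(x, ...) {
  data.frame(
    phenotype = vapply(x, `[[`, "", "phenotype"),
    certainty = vapply(x, `[[`, "", "certainty_label"),
    satisfied_by = vapply(x, function(a)
      paste(a$satisfied_by, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' Highest certainty among a set of allocations
#'
#' @param allocations A `psp_allocations` object (or plain list of
#'   allocations).
#' @return The maximum certainty label under the
#'   suggestive-of < possible < probable order, or `NA` for an empty set.
#' @examples
#' highest_certainty(evaluate_allocations(psp_profile(c("O1", "P1"))))
#' @export
highest_certainty <- function(allocations) {
  if (!length(allocations)) return(NA_character_)
  certainty_label(max(vapply(allocations, `[[`, 0L, "certainty")))
}

# Vectorized form of the same data-driven evaluation: profiles as a logical
# matrix (one row per profile, columns named by feature code), certainty
# out as an n x 8 integer matrix (0 = no allocation). Used for exhaustive
# sweeps over the 2^16 profile cube.
eval_rules_matrix <- function(P, rules, subsume_strata = FALSE) {
  stopifnot(is.matrix(P), all(PSP_FEATURE_CODES %in% colnames(P)))
  mode(P) <- "logical"
  if (subsume_strata) {
    for (dom in c("O", "P", "A", "C")) {
      codes <- paste0(dom, 1:3)
      P[, codes[3]] <- P[, codes[3]] | P[, codes[1]] | P[, codes[2]]
      P[, codes[2]] <- P[, codes[2]] | P[, codes[1]]
    }
  }
  cert <- matrix(0L, nrow(P), length(PSP_PHENOTYPES),
                 dimnames = list(NULL, PSP_PHENOTYPES))
  for (row in rules) {
    sat <- rep(FALSE, nrow(P))
    for (cj in row$conjuncts) {
      s <- rep(TRUE, nrow(P))
      for (f in cj) s <- s & P[, f]
      sat <- sat | s
    }
    ph <- row$phenotype
    cert[sat, ph] <- pmax(cert[sat, ph], row$certainty)
  }
  cert
}
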