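test_that("the shipped rule table transcribes the combination table: 16 rows, 8 phenotypes", {
  df <- as.data.frame(RULES)
  expect_identical(nrow(df), 16L)
  expect_setequal(unique(df$phenotype), psp_phenotypes())
  counts <- table(df$phenotype)
  expect_identical(as.integer(counts[psp_phenotypes()]),
                   c(3L, 2L, 2L, 2L, 2L, 2L, 2L, 1L))
  # probable PSP-RS expands (O1 or O2) + (P1 or P2) into 4 conjuncts
  rs_prob <- Filter(function(r)
    r$phenotype == "PSP-RS" && r$certainty_label == "probable", RULES)[[1]]
  expect_length(rs_prob$conjuncts, 4L)
  # suggestive-of PSP-P: 2 A-literals x 9 qualifying partners
  pp_sug <- Filter(function(r)
    r$phenotype == "PSP-P" && r$certainty_label == "suggestive of",
    RULES)[[1]]
  expect_length(pp_sug$conjuncts, 18L)
})

test_that("the rule loader validates and localizes schema violations", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("phenotype\tcertainty\tformula",
               "PSP-RS\tprobable\tO4+P1"), bad)
  expect_error(psp_rules(bad), "O4")

  writeLines(c("phenotype\tcertainty\tformula",
               "PSP-XX\tprobable\tO1"), bad)
  expect_error(psp_rules(bad), "PSP-XX")

  writeLines(c("phenotype\tcertainty\tformula",
               "PSP-RS\tdefinite\tO1"), bad)
  expect_error(psp_rules(bad), "certainty")

  writeLines(c("phenotype\tcertainty\tformula",
               "PSP-RS\tprobable\tO1",
               "PSP-RS\tProbable\tO2"), bad)
  expect_error(psp_rules(bad), "duplicate")

  # an empty rule document yields an empty rule set, which allocates nothing
  writeLines("phenotype\tcertainty\tformula", bad)
  empty <- psp_rules(bad)
  expect_length(empty, 0L)
  expect_length(evaluate_allocations(prof("O1", "P1"), empty), 0L)
})

test_that("allocation examples: co-fulfilled phenotypes, empty profile, single clue", {
  df <- alloc_df(prof("O1", "P1"), RULES)
  expect_identical(df[df$phenotype == "PSP-RS", "certainty"], "probable")
  expect_identical(df[df$phenotype == "PSP-OM", "certainty"], "possible")
  expect_identical(df[df$phenotype == "PSP-PI", "certainty"], "suggestive of")
  expect_identical(nrow(df), 3L)

  expect_length(evaluate_allocations(psp_profile(), RULES), 0L)

  df_c1 <- alloc_df(prof("C1"), RULES)
  expect_identical(df_c1$phenotype, "PSP-SL")
  expect_identical(df_c1$certainty, "suggestive of")
})

test_that("matching is literal: a higher-stratum feature does not fill a lower slot", {
  # possible PSP-RS names O2 + P3; O1 must not satisfy the O2 slot
  df <- alloc_df(prof("O1", "P3"), RULES)
  expect_false("PSP-RS" %in% df$phenotype)
  # with the optional subsumption mode on, O1 stands in for O2
  df_sub <- alloc_df(prof("O1", "P3"), RULES, subsume_strata = TRUE)
  expect_identical(df_sub[df_sub$phenotype == "PSP-RS", "certainty"],
                   "possible")
})

test_that("satisfied_by lists only present features that drive the winning row", {
  a <- evaluate_allocations(prof("O1", "O2", "P1"), RULES)
  rs <- Filter(function(x) x$phenotype == "PSP-RS", a)[[1]]
  expect_setequal(rs$satisfied_by, c("O1", "O2", "P1"))
  p <- prof("O1", "P1")
  for (al in evaluate_allocations(p, RULES))
    expect_true(all(p$present[al$satisfied_by]))
})

test_that("highest_certainty is the maximum under the certainty order", {
  a <- evaluate_allocations(prof("O1", "P1"), RULES)
  expect_identical(highest_certainty(a), "probable")
  expect_identical(highest_certainty(list()), NA_character_)
  a1 <- evaluate_allocations(prof("C1"), RULES)
  expect_identical(highest_certainty(a1), "suggestive of")
})

test_that("allocation sets are deterministic and unique per phenotype on random profiles", {
  for (p in random_profiles(60)) {
    a1 <- evaluate_allocations(p, RULES)
    a2 <- evaluate_allocations(p, RULES)
    expect_identical(a1, a2)
    phs <- vapply(a1, `[[`, "", "phenotype")
    expect_false(anyDuplicated(phs) > 0)
  }
})
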