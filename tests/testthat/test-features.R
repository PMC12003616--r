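test_that("frontal presentation equals the >=3-of-5 rule on all 32 item combinations", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (i in seq_len(nrow(grid))) {
    flags <- as.logical(grid[i, ])
    expect_identical(
      derive_frontal_presentation(flags[1], flags[2], flags[3],
                                  flags[4], flags[5]),
      sum(flags) >= 3L)
  }
})

test_that("CBS requires one cortical and one movement sign on all 64 combinations", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  for (i in seq_len(nrow(grid))) {
    g <- as.logical(grid[i, ])
    expect_identical(
      derive_cbs(g[1], g[2], g[3], g[4], g[5], g[6]),
      any(g[1:3]) && any(g[4:6]))
  }
})

test_that("levodopa resistance follows the <=30% improvement rule under qualifying regimens", {
  # 25% improvement under a 200 mg challenge: resistant
  expect_true(assess_levodopa_resistance(40, 30, challenge_dose_mg = 200))
  # 50% improvement: responsive
  expect_false(assess_levodopa_resistance(40, 20, challenge_dose_mg = 250))
  # sub-threshold challenge dose, no sustained regimen: not assessable
  expect_true(is.na(assess_levodopa_resistance(40, 30,
                                               challenge_dose_mg = 100)))
  # sustained regimen qualifies at >= 1000 mg for >= 30 days
  expect_true(assess_levodopa_resistance(40, 30, sustained_dose_mg = 1000,
                                         sustained_duration_days = 30))
  expect_true(is.na(assess_levodopa_resistance(40, 30,
                                               sustained_dose_mg = 1000,
                                               sustained_duration_days = 20)))
  # exactly 30% improvement is still resistant (boundary inclusive)
  expect_true(assess_levodopa_resistance(40, 28, challenge_dose_mg = 200))
  # worsening counts as resistant
  expect_true(assess_levodopa_resistance(40, 45, challenge_dose_mg = 200))
  # zero pre-score: ratio undefined
  expect_true(is.na(assess_levodopa_resistance(0, 0,
                                               challenge_dose_mg = 200)))
})

test_that("levodopa resistance is monotone: more improvement never flips responsive to resistant", {
  pre <- 48
  verdicts <- vapply(seq(pre, 0, by = -2), function(post)
    assess_levodopa_resistance(pre, post, challenge_dose_mg = 200),
    logical(1))
  # as post decreases (improvement grows), TRUE may only switch to FALSE once
  expect_false(any(diff(!verdicts) < 0))
})

test_that("pull-test outcomes map to P2, P3 or no feature", {
  expect_identical(derive_pull_test_feature(TRUE, 0, FALSE), "P2")
  # a caught fall dominates any step count
  expect_identical(derive_pull_test_feature(TRUE, 5, TRUE), "P2")
  expect_identical(derive_pull_test_feature(FALSE, 3, TRUE), "P3")
  # exactly two steps is not "more than two"
  expect_identical(derive_pull_test_feature(FALSE, 2, TRUE), "none")
  # many steps without unaided recovery does not qualify for P3
  expect_identical(derive_pull_test_feature(FALSE, 4, FALSE), "none")
})

test_that("temporal gate removes late time-constrained features only, inclusively at the boundary", {
  p <- prof("P1", "O1", onset = c(P1 = 40, O1 = 60))
  g <- apply_temporal_gate(p)
  expect_false(g$present[["P1"]])
  expect_true(g$present[["O1"]]) # O features are not time-constrained
  expect_true(is.na(g$onset[["P1"]]))

  # onset exactly at the window is retained
  g36 <- apply_temporal_gate(prof("P1", onset = c(P1 = 36)))
  expect_true(g36$present[["P1"]])

  # features without a recorded onset are trusted as-is
  g_bare <- apply_temporal_gate(prof("P1", "A1"))
  expect_true(all(g_bare$present[c("P1", "A1")]))
})

test_that("temporal gate is idempotent and can only remove P1/P2/P3/A1", {
  set.seed(7)
  starred <- c("P1", "P2", "P3", "A1")
  for (i in 1:50) {
    codes <- sample(psp_features()$code, sample(1:16, 1))
    onset <- stats::setNames(round(runif(length(codes), 0, 80)), codes)
    keep <- runif(length(codes)) < 0.7
    p <- psp_profile(codes, onset = onset[keep])
    g1 <- apply_temporal_gate(p)
    g2 <- apply_temporal_gate(g1)
    expect_identical(g1, g2)
    expect_false(any(g1$present & !p$present)) # never adds
    changed <- names(p$present)[p$present & !g1$present]
    expect_true(all(changed %in% starred))
  }
})

test_that("profile construction validates codes and onsets", {
  expect_error(psp_profile("O4"), "unknown feature code")
  expect_error(psp_profile("O1", onset = c(P1 = 3)), "absent feature")
  expect_error(psp_profile("O1", onset = c(O1 = -2)), "non-negative")
  p <- psp_profile(c("o1", "p1")) # case-insensitive codes
  expect_true(all(p$present[c("O1", "P1")]))
  expect_identical(format(p), "{O1,P1}")
})
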