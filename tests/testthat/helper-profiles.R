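# Shared fixtures built in code.

prof <- function(..., onset = NULL) psp_profile(c(...), onset = onset)

alloc_df <- function(profile, ...) {
  as.data.frame(evaluate_allocations(profile, ...))
}

# One shared copy of the expensive inputs.
RULES <- psp_rules()
TAU <- psp_tau_map()
ORDER <- psp_phenotype_order()

# Random present-feature sets under a fixed seed, for property loops.
random_profiles <- function(n, seed = 20260101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(0:16, 1)
    psp_profile(sample(psp_features()$code, k))
  })
}
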