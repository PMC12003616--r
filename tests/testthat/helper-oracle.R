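# Independent evaluator of the phenotype/certainty combination table,
# transcribed cell by cell as explicit conditionals. Deliberately naive
# and kept free of any code shared with the package's data-driven engine:
# it is the oracle the engine is checked against over the whole cube.

oracle_certainty_matrix <- function(P) {
  O1 <- P[, "O1"]; O2 <- P[, "O2"]; O3 <- P[, "O3"]
  P1 <- P[, "P1"]; P2 <- P[, "P2"]; P3 <- P[, "P3"]
  A1 <- P[, "A1"]; A2 <- P[, "A2"]; A3 <- P[, "A3"]
  C1 <- P[, "C1"]; C2 <- P[, "C2"]; C3 <- P[, "C3"]
  CC1 <- P[, "CC1"]; CC2 <- P[, "CC2"]
  CC3 <- P[, "CC3"]; CC4 <- P[, "CC4"]
  SUG <- 1L; POS <- 2L; PRO <- 3L; NONE <- 0L
  cbind(
    "PSP-RS" = ifelse((O1 | O2) & (P1 | P2), PRO,
               ifelse(O2 & P3, POS,
               ifelse(O3 & (P2 | P3), SUG, NONE))),
    "PSP-P" = ifelse((O1 | O2) & (A2 | A3), PRO,
              ifelse((A2 | A3) &
                     (O3 | P1 | P2 | C1 | C2 | CC1 | CC2 | CC3 | CC4),
                     SUG, NONE)),
    "PSP-PGF" = ifelse((O1 | O2) & A1, PRO, ifelse(A1, POS, NONE)),
    "PSP-F" = ifelse(C2 & (O1 | O2), PRO,
              ifelse(C2 & (O3 | P3), SUG, NONE)),
    "PSP-OM" = ifelse(O1, POS, ifelse(O2 | O3, SUG, NONE)),
    "PSP-SL" = ifelse((O1 | O2) & C1, POS, ifelse(C1, SUG, NONE)),
    "PSP-CBS" = ifelse((O1 | O2) & C3, POS, ifelse(C3, SUG, NONE)),
    "PSP-PI" = ifelse(P1 | P2, SUG, NONE))
}
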