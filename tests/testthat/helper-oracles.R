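# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Single-expression transcription of the full heat-balance model.
oracle_H <- function(Tr, tw, ts, He) {
  0.96 * 5.67e-8 * Tr^4 + 2.38 * (tw - ts)^1.25 +
    3.054 * (0.256 * tw - 3.37) * (1 - He)
}

# Second, independently written transcription of the Clarke grid geometry
# (vectorized; evaluated as non-overlapping region tests rather than the
# implementation's priority chain). Inputs in mg/dL.
oracle_clarke <- function(x, y) {
  in_A <- (x < 70 & y < 70) | (y >= 0.8 * x & y <= 1.2 * x)
  in_E <- !in_A & ((x >= 180 & y <= 70) | (x <= 70 & y >= 180))
  in_C <- !in_A & !in_E &
    ((x >= 70 & x <= 290 & y >= x + 110) |
     (x >= 130 & x <= 180 & y <= 1.4 * x - 182))
  in_D <- !in_A & !in_E & !in_C &
    ((x >= 240 & y >= 70 & y <= 180) |
     (x <= 175 / 3 & y >= 70 & y <= 180) |
     (x > 175 / 3 & x <= 70 & y >= 1.2 * x & y <= 180))
  out <- rep("B", length(x))
  out[in_A] <- "A"; out[in_E] <- "E"; out[in_C] <- "C"; out[in_D] <- "D"
  out
}

# Brute-force enumeration of all products of distinct predictors
# (subset sizes 1-4) for one feature row.
oracle_interaction_products <- function(x) {
  out <- numeric(0)
  for (size in 1:4) {
    cmb <- utils::combn(4, size)
    out <- c(out, apply(cmb, 2, function(ix) prod(x[ix])))
  }
  out
}

# Random admissible sensor frames.
random_frames <- function(n) {
  data.frame(Tr = runif(n, 295, 315),
             tw = runif(n, 25, 40),
             ts = runif(n, 18, 25),
             He = runif(n, 0, 1))
}

# Features + reference glucose straight off a cohort's ground-truth ledger.
cohort_features <- function(cohort) {
  data.frame(H = cohort$H_true_Wm2, SpO2 = cohort$SpO2_true_pct,
             HR = cohort$HR_true_bpm, BF = cohort$BF_pu,
             bg_ref = cohort$BG_ref_mmolL)
}
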