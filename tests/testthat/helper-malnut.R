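# A small complete cohort of near-identical senior women on which every
# score is applicable: BMI 19 (< the senior GLIM cutoff of 22), albumin
# 30 g/L, inflamed (CRP 10, ASA 3), mild anemia.  Used as the baseline for
# missingness-contract checks.
complete_senior_cohort <- function(n = 5) {
  data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age = 75, sex = "female",
    abw = 19 * 1.6^2 + seq_len(n) * 0.01, # tiny spread so quartiles exist
    height = 160,
    alb = 30, palb = 200, crp = 10,
    lymc = 1600, neutc = 8000,
    ahb = 120, mcv = 90, mch = 30, mchc = 34,
    asaps = 3,
    stringsAsFactors = FALSE
  )
}

# Bisection boundary search: given a step-function classifier `f` over a
# real input with different codes at `lo` and `hi`, localize the switch
# point to within `tol`.  Independent of how any score computes its bands.
bisect_code <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  stopifnot(!identical(flo, f(hi)))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(f(mid), flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Extract one score's rows from a coded cohort, in record order.
score_rows <- function(cohort, score) {
  d <- cohort$results[cohort$results$score == score, , drop = FALSE]
  d[match(cohort$records$patient_id, d$patient_id), , drop = FALSE]
}
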