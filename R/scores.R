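#' Neutrophil-to-lymphocyte ratio
#'
#' @param neutc Neutrophil count, cells/uL (>= 0).
#' @param lymc Lymphocyte count, cells/uL (> 0).
#' @return Numeric ratio; `NA` where either count is `NA` or `lymc` is 0.
#' @export
compute_nlr <- function(neutc, lymc) {
  if (any(!is.na(neutc) & neutc < 0) || any(!is.na(lymc) & lymc < 0)) {
    stop("compute_nlr: counts must be >= 0")
  }
  ifelse(!is.na(lymc) & lymc == 0, NA_real_, neutc / lymc)
}

#' Grade the neutrophil-to-lymphocyte ratio
#'
#' Chronic inflammatory status: normal below 2, low 2 to under 4, mild 4 to
#' under 6, moderate 6 to under 8, severe 8 and above.
#'
#' @param nlr Ratio (>= 0).
#' @return Factor with levels `normal`, `low`, `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' grade_nlr(c(1.99, 5.5, 8))
grade_nlr <- function(nlr) {
  if (any(!is.na(nlr) & nlr < 0)) stop("grade_nlr: nlr must be >= 0")
  lv <- c("normal", "low", "mild", "moderate", "severe")
  idx <- findInterval(nlr, c(2, 4, 6, 8)) + 1L
  factor(lv[idx], levels = lv)
}

#' Geriatric nutritional risk index
#'
#' GNRI = 1.489 x albumin (g/L) + 41.7 x ABW/IBW, with the weight ratio
#' clamped at 1 by default (the index was designed so weight above ideal
#' adds no protection).  Risk bands: major below 82 (code 3), moderate 82 to
#' under 92 (code 2), low 92 to 98 (code 1), no risk above 98 (code 0).
#' Restriction to seniors is a pipeline concern, not enforced here.
#'
#' @param alb Serum albumin, g/L (>= 0).
#' @param abw Actual body weight, kg (> 0).
#' @param ibw Ideal body weight, kg (> 0).
#' @param cap_ratio Clamp ABW/IBW at 1; default TRUE.
#' @return A [score_result()] for score `GNRI`.
#' @export
#' @examples
#' compute_gnri(40, 70, 70) # value 101.26, code 0
compute_gnri <- function(alb, abw, ibw, cap_ratio = TRUE) {
  if (any(!is.na(alb) & alb < 0)) stop("compute_gnri: alb must be >= 0")
  if (any(!is.na(abw) & abw <= 0) || any(!is.na(ibw) & ibw <= 0)) {
    stop("compute_gnri: abw and ibw must be > 0")
  }
  n <- max(length(alb), length(abw), length(ibw))
  alb <- rep_len(alb, n)
  abw <- rep_len(abw, n)
  ibw <- rep_len(ibw, n)
  mr <- missing_reason(list(
    ALB = is.na(alb), ABW = is.na(abw), IBW = is.na(ibw)
  ))
  r <- abw / ibw
  if (isTRUE(cap_ratio)) r <- pmin(r, 1)
  value <- 1.489 * alb + 41.7 * r
  code <- ifelse(value < 82, 3L,
    ifelse(value < 92, 2L, ifelse(value <= 98, 1L, 0L))
  )
  score_result("GNRI",
    value = ifelse(mr$any, NA_real_, value),
    code = ifelse(mr$any, NA_integer_, code),
    applicable = !mr$any, reason = mr$reason
  )
}

#' Instant nutritional assessment
#'
#' Joint albumin/lymphocyte classification.  Albumin at or above 3.5 g/dL
#' and lymphocytes at or above 1500 cells/uL is no risk (code 0); low
#' albumin alone is protein risk (code 1); low lymphocytes alone is energy
#' risk (code 2); both low is protein-energy risk (code 3).
#'
#' @param alb Serum albumin, g/dL (>= 0).  Note the unit: the published
#'   cutoff is 3.5 g/dL; divide a canonical g/L value by 10.
#' @param lymc Lymphocyte count, cells/uL (>= 0).
#' @return A [score_result()] for score `INA` (nominal: no continuous value).
#' @export
#' @examples
#' classify_ina(c(3.5, 3.4, 3.6), c(1500, 1400, 1200)) # codes 0, 3, 2
classify_ina <- function(alb, lymc) {
  if (any(!is.na(alb) & alb < 0) || any(!is.na(lymc) & lymc < 0)) {
    stop("classify_ina: alb and lymc must be >= 0")
  }
  n <- max(length(alb), length(lymc))
  alb <- rep_len(alb, n)
  lymc <- rep_len(lymc, n)
  mr <- missing_reason(list(ALB = is.na(alb), LYMC = is.na(lymc)))
  low_alb <- alb < 3.5
  low_lym <- lymc < 1500
  code <- ifelse(low_alb & low_lym, 3L,
    ifelse(!low_alb & low_lym, 2L, ifelse(low_alb, 1L, 0L))
  )
  score_result("INA",
    value = NA_real_,
    code = ifelse(mr$any, NA_integer_, code),
    applicable = !mr$any, reason = mr$reason
  )
}

#' Lymphocyte-albumin product score
#'
#' Value = lymphocyte count (cells/uL) x albumin (g/dL).  Poor nutrition at
#' or below 4515 (code 2), middle above 4515 to 7920 (code 1), good above
#' 7920 (code 0).
#'
#' @param lymc Lymphocyte count, cells/uL (>= 0).
#' @param alb Serum albumin, g/dL (>= 0).
#' @return A [score_result()] for score `LxA`.
#' @export
#' @examples
#' compute_lxa(c(903, 1500, 2000), c(5, 3.5, 4.5)) # codes 2, 1, 0
compute_lxa <- function(lymc, alb) {
  if (any(!is.na(alb) & alb < 0) || any(!is.na(lymc) & lymc < 0)) {
    stop("compute_lxa: lymc and alb must be >= 0")
  }
  n <- max(length(alb), length(lymc))
  alb <- rep_len(alb, n)
  lymc <- rep_len(lymc, n)
  mr <- missing_reason(list(LYMC = is.na(lymc), ALB = is.na(alb)))
  value <- lymc * alb
  code <- ifelse(value <= 4515, 2L, ifelse(value <= 7920, 1L, 0L))
  score_result("LxA",
    value = ifelse(mr$any, NA_real_, value),
    code = ifelse(mr$any, NA_integer_, code),
    applicable = !mr$any, reason = mr$reason
  )
}

#' CRP/albumin ratio (protein malnutrition with acute inflammation)
#'
#' Value = CRP (mg/L) / albumin (g/dL).  No risk below 0.4 (code 0), low 0.4
#' to under 1.2 (code 1), moderate 1.2 to under 2 (code 2), high 2 and above
#' (code 3).
#'
#' @param crp C-reactive protein, mg/L (>= 0).
#' @param alb Serum albumin, g/dL (> 0; a zero denominator is not
#'   applicable).
#' @return A [score_result()] for score `PMA`.
#' @export
#' @examples
#' compute_pma(c(0, 10, 4.8), 4) # codes 0, 3, 2
compute_pma <- function(crp, alb) {
  if (any(!is.na(crp) & crp < 0) || any(!is.na(alb) & alb < 0)) {
    stop("compute_pma: crp and alb must be >= 0")
  }
  n <- max(length(crp), length(alb))
  crp <- rep_len(crp, n)
  alb <- rep_len(alb, n)
  mr <- missing_reason(list(CRP = is.na(crp), ALB = is.na(alb)))
  value <- crp / alb
  code <- ifelse(value < 0.4, 0L,
    ifelse(value < 1.2, 1L, ifelse(value < 2, 2L, 3L))
  )
  res <- score_result("PMA",
    value = ifelse(mr$any, NA_real_, value),
    code = ifelse(mr$any, NA_integer_, code),
    applicable = !mr$any, reason = mr$reason
  )
  apply_guard(res, !is.na(alb) & alb == 0, "ALB is zero")
}

#' Combined acute/chronic inflammation-protein index
#'
#' Value = (NLR + CRP mg/L) / (albumin g/dL + prealbumin mg/L).  No
#' published cutoffs exist; the categorical code is assigned later against
#' the cohort's own quartiles (see [quartile_codes()]), so this operation
#' returns the continuous value with a pending (`NA`) code that
#' [score_cohort()] fills in.
#'
#' @param nlr Neutrophil-to-lymphocyte ratio (>= 0).
#' @param crp C-reactive protein, mg/L (>= 0).
#' @param alb Serum albumin, g/dL (>= 0).
#' @param palb Prealbumin, mg/L (>= 0; `alb + palb` must be > 0).
#' @return A [score_result()] for score `PMAC`.
#' @export
#' @examples
#' compute_pmac(2, 5, 4, 200) # value 7/204
compute_pmac <- function(nlr, crp, alb, palb) {
  for (v in list(nlr, crp, alb, palb)) {
    if (any(!is.na(v) & v < 0)) stop("compute_pmac: inputs must be >= 0")
  }
  n <- max(length(nlr), length(crp), length(alb), length(palb))
  nlr <- rep_len(nlr, n)
  crp <- rep_len(crp, n)
  alb <- rep_len(alb, n)
  palb <- rep_len(palb, n)
  mr <- missing_reason(list(
    CRP = is.na(crp), NLR = is.na(nlr), ALB = is.na(alb), PALB = is.na(palb)
  ))
  value <- (nlr + crp) / (alb + palb)
  res <- score_result("PMAC",
    value = ifelse(mr$any, NA_real_, value),
    code = NA_integer_,
    applicable = !mr$any, reason = mr$reason, pending_code = TRUE
  )
  apply_guard(res, !is.na(alb + palb) & alb + palb == 0, "ALB + PALB is zero")
}

#' Iron deficit (Ganzoni equation)
#'
#' Total-body iron deficit in mg: ABW (kg) x hemoglobin deficit x 2.4 + 500,
#' where the deficit between ideal and actual hemoglobin is taken in g/dL
#' (the 2.4 factor is defined for that unit; inputs here are canonical g/L
#' and converted internally).  Patients whose actual hemoglobin exceeds the
#' ideal are not applicable.  The categorical code is cohort-relative
#' (quartiles); this operation returns the continuous value with a pending
#' (`NA`) code that [score_cohort()] fills in.
#'
#' @param abw Actual body weight, kg (> 0).
#' @param ihb Ideal hemoglobin, g/L.
#' @param ahb Actual hemoglobin, g/L.
#' @return A [score_result()] for score `IDM`, value in mg.
#' @export
#' @examples
#' compute_idm(70, 150, 150) # 500 mg
#' compute_idm(70, 150, 100) # 1340 mg
compute_idm <- function(abw, ihb, ahb) {
  if (any(!is.na(abw) & abw <= 0)) stop("compute_idm: abw must be > 0")
  if (any(!is.na(ihb) & ihb < 0) || any(!is.na(ahb) & ahb < 0)) {
    stop("compute_idm: hemoglobin values must be >= 0")
  }
  n <- max(length(abw), length(ihb), length(ahb))
  abw <- rep_len(abw, n)
  ihb <- rep_len(ihb, n)
  ahb <- rep_len(ahb, n)
  mr <- missing_reason(list(
    ABW = is.na(abw), IHB = is.na(ihb), AHB = is.na(ahb)
  ))
  value <- abw * ((ihb - ahb) / 10) * 2.4 + 500
  res <- score_result("IDM",
    value = ifelse(mr$any, NA_real_, value),
    code = NA_integer_,
    applicable = !mr$any, reason = mr$reason, pending_code = TRUE
  )
  apply_guard(res, !is.na(ihb) & !is.na(ahb) & ihb < ahb, "IHB lower than AHB")
}

#' Vitamin B deficit flag from red-cell indices
#'
#' Flags the red-cell signature of macrocytic hyperchromic anemia.  Default
#' rule (`"mcv_and"`): raised MCV and (raised MCH or lowered MCHC) codes 1
#' (functional vitamin B deficiency); macrocytosis is treated as necessary.
#' The alternative reading `"or_mchc"` codes 1 when (raised MCV and raised
#' MCH) or lowered MCHC.
#'
#' @param mcv Mean corpuscular volume, fL (>= 0).
#' @param mch Mean corpuscular hemoglobin, pg (>= 0).
#' @param mchc Mean corpuscular hemoglobin concentration, g/dL (>= 0).
#' @param refs A [vbd_ref_ranges()] object.
#' @param rule `"mcv_and"` (default) or `"or_mchc"`; see Details.
#' @return A [score_result()] for score `VBD` (dichotomous, no value).
#' @export
#' @examples
#' classify_vbd(c(105, 90, 105), c(36, 30, 30), 33) # codes 1, 0, 0
classify_vbd <- function(mcv, mch, mchc, refs = vbd_ref_ranges(),
                         rule = c("mcv_and", "or_mchc")) {
  rule <- match.arg(rule)
  for (v in list(mcv, mch, mchc)) {
    if (any(!is.na(v) & v < 0)) stop("classify_vbd: indices must be >= 0")
  }
  n <- max(length(mcv), length(mch), length(mchc))
  mcv <- rep_len(mcv, n)
  mch <- rep_len(mch, n)
  mchc <- rep_len(mchc, n)
  mr <- missing_reason(list(
    MCV = is.na(mcv), MCH = is.na(mch), MCHC = is.na(mchc)
  ))
  hi_mcv <- mcv > refs$mcv_high
  hi_mch <- mch > refs$mch_high
  lo_mchc <- mchc < refs$mchc_low
  flag <- if (rule == "mcv_and") {
    hi_mcv & (hi_mch | lo_mchc)
  } else {
    (hi_mcv & hi_mch) | lo_mchc
  }
  score_result("VBD",
    value = NA_real_,
    code = ifelse(mr$any, NA_integer_, as.integer(flag)),
    applicable = !mr$any, reason = mr$reason
  )
}

#' Published thresholds, in one place
#'
#' Read-only registry of every numeric cutoff the classifiers use, so
#' documentation and tests share a single source of truth.
#'
#' @return Named list of numeric vectors.
#' @export
score_thresholds <- function() {
  list(
    GNRI = c(major = 82, moderate = 92, low = 98),
    LxA = c(poor = 4515, middle = 7920),
    PMA = c(low = 0.4, moderate = 1.2, high = 2.0),
    INA = c(alb_gdl = 3.5, lymc = 1500),
    NLR = c(low = 2, mild = 4, moderate = 6, severe = 8),
    GLIM = c(bmi_adult = 20, bmi_senior = 22, asaps = 2, crp = 5, nlr = 6),
    BWd = c(mcid_fraction = 0.1),
    age = c(adult = 40, senior = 70)
  )
}
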