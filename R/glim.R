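#' GLIM diagnosis from routinely-collected data
#'
#' Operationalizes the GLIM two-pillar scheme (at least one phenotypic plus
#' one etiologic criterion) with the variables a retrospective orthopedic
#' database actually holds.  The phenotypic criterion is low BMI, with an
#' age-adjusted cutoff (below 20 kg/m2 before age 70, below 22 kg/m2 from
#' 70).  The etiologic criteria are disease burden (ASA physical status at
#' or above 2) and inflammation (CRP above 5 mg/L, or NLR at or above 6).
#'
#' Codes: 1 = clean undernutrition (low BMI, no disease burden, no
#' inflammation), 2 = disease-related undernutrition without inflammation
#' (low BMI, disease burden, at least one inflammation marker low), 3 =
#' disease-related undernutrition with inflammation (low BMI, disease
#' burden, at least one inflammation marker raised).  When both 2 and 3
#' would match (discordant inflammation markers), 3 takes precedence: an
#' elevated marker is the clinically dominant etiology.  Patients without
#' low BMI are not applicable.  Low BMI with no disease burden but raised
#' inflammation matches no defined class and is returned as not applicable
#' ("unclassifiable combination") rather than forced into a diagnosis.
#'
#' @param bmi kg/m2 (> 0).
#' @param age_class Age-class vector as from [classify_age()].
#' @param asaps ASA physical status, integer 1 (healthy) to 6 (brain-dead).
#' @param crp C-reactive protein, mg/L.
#' @param nlr Neutrophil-to-lymphocyte ratio.
#' @param th A [glim_thresholds()] object.
#' @return A `data.frame` of class `glim_result` with columns `code`,
#'   `applicable`, `reason`, and the fired criteria `low_bmi`, `asaps_high`,
#'   `crp_high`, `nlr_high`.
#' @export
#' @examples
#' classify_glim(19, "adult", 3, 10, 2) # code 3
#' classify_glim(21, "senior", 2, 2, 1) # code 2
#' classify_glim(19, "adult", 1, 2, 1) # code 1
#' classify_glim(25, "adult", 1, 2, 1) # not applicable
classify_glim <- function(bmi, age_class, asaps, crp, nlr,
                          th = glim_thresholds()) {
  if (any(!is.na(asaps) & (asaps < 1 | asaps > 6 | asaps != round(asaps)))) {
    stop("classify_glim: asaps must be an integer in 1..6")
  }
  if (any(!is.na(bmi) & bmi <= 0)) stop("classify_glim: bmi must be > 0")
  age_class <- as.character(age_class)
  n <- max(length(bmi), length(age_class), length(asaps), length(crp),
           length(nlr))
  bmi <- rep_len(bmi, n)
  age_class <- rep_len(age_class, n)
  asaps <- rep_len(asaps, n)
  crp <- rep_len(crp, n)
  nlr <- rep_len(nlr, n)
  mr <- missing_reason(list(
    BMI = is.na(bmi), `age class` = is.na(age_class),
    ASAPS = is.na(asaps), CRP = is.na(crp), NLR = is.na(nlr)
  ))
  cutoff <- ifelse(age_class == "senior", th$bmi_senior, th$bmi_adult)
  low_bmi <- bmi < cutoff
  asaps_high <- asaps >= th$asaps_min
  crp_high <- crp > th$crp_max
  nlr_high <- nlr >= th$nlr_min
  code <- ifelse(asaps_high & (crp_high | nlr_high), 3L,
    ifelse(asaps_high, 2L,
      ifelse(!crp_high & !nlr_high, 1L, NA_integer_)
    )
  )
  applicable <- !mr$any & low_bmi & !is.na(code)
  reason <- mr$reason
  reason[!mr$any & !low_bmi] <- "BMI >= cutoff"
  reason[!mr$any & low_bmi & is.na(code)] <- "unclassifiable combination"
  out <- data.frame(
    code = ifelse(applicable, code, NA_integer_),
    applicable = applicable,
    reason = ifelse(applicable, "", reason),
    low_bmi = ifelse(mr$any, NA, low_bmi),
    asaps_high = ifelse(mr$any, NA, asaps_high),
    crp_high = ifelse(mr$any, NA, crp_high),
    nlr_high = ifelse(mr$any, NA, nlr_high),
    stringsAsFactors = FALSE
  )
  class(out) <- c("glim_result", "data.frame")
  out
}

# Render a glim_result as a score_result row set for cohort assembly.
glim_as_score_result <- function(g) {
  score_result("GLIM",
    value = NA_real_, code = g$code,
    applicable = g$applicable,
    reason = ifelse(g$applicable, "", g$reason)
  )
}
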