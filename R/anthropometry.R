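#' Body mass index
#'
#' Quetelet index, weight over squared height.
#'
#' @param abw Actual body weight, kg (> 0).
#' @param height Height, cm (> 0).
#' @return BMI in kg/m2; `NA` where either input is `NA`.
#' @export
#' @examples
#' compute_bmi(80, 200) # 20
compute_bmi <- function(abw, height) {
  if (any(!is.na(abw) & abw <= 0) || any(!is.na(height) & height <= 0)) {
    stop("compute_bmi: abw and height must be > 0")
  }
  abw / (height / 100)^2
}

#' Ideal body weight
#'
#' Lorenz (default): males H - 100 - (H - 150)/4, females
#' H - 100 - (H - 150)/2.5, H in cm.  Devine: 50 kg (males) or 45.5 kg
#' (females) plus 2.3 kg per inch over 5 feet.  Lorenz is the default
#' because the geriatric nutritional risk index was developed with it.
#'
#' @param height Height, cm (> 0).
#' @param sex `"male"` or `"female"` (vector).
#' @param formula `"lorenz"` (default) or `"devine"`.
#' @return Ideal body weight in kg; `NA` where height or sex is `NA`.
#' @export
#' @examples
#' compute_ibw(170, "male") # 65
#' compute_ibw(170, "female") # 62
compute_ibw <- function(height, sex, formula = c("lorenz", "devine")) {
  formula <- match.arg(formula)
  if (any(!is.na(height) & height <= 0)) {
    stop("compute_ibw: height must be > 0")
  }
  known <- !is.na(sex)
  if (any(!sex[known] %in% c("male", "female"))) {
    stop("compute_ibw: sex must be 'male' or 'female'")
  }
  male <- sex == "male"
  ibw <- if (formula == "lorenz") {
    ifelse(male,
      height - 100 - (height - 150) / 4,
      height - 100 - (height - 150) / 2.5
    )
  } else {
    inches_over_5ft <- height / 2.54 - 60
    ifelse(male, 50 + 2.3 * inches_over_5ft, 45.5 + 2.3 * inches_over_5ft)
  }
  if (any(!is.na(ibw) & ibw <= 0)) {
    stop("compute_ibw: height too small, formula yields non-positive weight")
  }
  ibw
}

#' Age class
#'
#' Younger adults are under 40, adults 40 to under 70, seniors 70 and over.
#' Pediatric ages are rejected: the scoring system is defined for adults.
#'
#' @param age Age in years (>= 18).
#' @return Factor with levels `younger_adult`, `adult`, `senior`; `NA` where
#'   age is `NA`.
#' @export
#' @examples
#' classify_age(c(39, 40, 70))
classify_age <- function(age) {
  if (any(!is.na(age) & age < 18)) {
    stop("classify_age: age must be >= 18 (pediatric patients not supported)")
  }
  cls <- ifelse(age < 40, "younger_adult", ifelse(age < 70, "adult", "senior"))
  factor(cls, levels = c("younger_adult", "adult", "senior"))
}

# Band edges per age class.  Adults use the traditional half-open bands;
# seniors use right-shifted bands reflecting the protective role of fat in
# old age, closed on the right (25-35 normal, 35.1-40 overweight, ... are
# rendered as (35,40] etc. so every BMI classifies).
bmi_levels <- c(
  "underweight", "normal", "overweight",
  "obesity_I", "obesity_II", "obesity_III"
)

#' Age-adjusted BMI category
#'
#' Adults and younger adults: under 18.5 underweight, 18.5-24.9 normal,
#' 25-29.9 overweight, 30-34.9 obesity I, 35-39.9 obesity II, 40+
#' obesity III (left-closed bands).  Seniors: under 25 underweight, 25-35
#' normal, over 35 to 40 overweight, over 40 to 45 obesity I, over 45 to 50
#' obesity II, over 50 obesity III (right-closed bands).
#'
#' @param bmi BMI, kg/m2 (> 0).
#' @param age_class An age-class factor or character vector as returned by
#'   [classify_age()].
#' @return Factor with the six category levels; `NA` where either input is
#'   `NA`.
#' @export
#' @examples
#' classify_bmi(24, classify_age(c(75, 45))) # underweight, normal
classify_bmi <- function(bmi, age_class) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("classify_bmi: bmi must be > 0")
  age_class <- as.character(age_class)
  n <- max(length(bmi), length(age_class))
  bmi <- rep_len(bmi, n)
  age_class <- rep_len(age_class, n)
  senior <- age_class == "senior"
  adult_idx <- findInterval(bmi, c(18.5, 25, 30, 35, 40)) + 1L
  # seniors: right-closed bands, so strict inequality at the upper edges
  senior_idx <- 1L +
    (bmi >= 25) + (bmi > 35) + (bmi > 40) + (bmi > 45) + (bmi > 50)
  idx <- ifelse(senior, senior_idx, adult_idx)
  idx[is.na(bmi) | is.na(age_class)] <- NA_integer_
  factor(bmi_levels[idx], levels = bmi_levels)
}

#' Body weight difference score
#'
#' Deviation of actual from ideal body weight.  A deviation greater than the
#' minimal clinically important difference, 10% of ideal weight, flags risk:
#' a loss codes 1 (risk of undernutrition), a gain codes 2 (risk of
#' overnutrition), anything within the 10% envelope codes 0.  The boundary
#' itself (exactly 10%) is not "greater than" and codes 0.
#'
#' @param abw Actual body weight, kg (> 0; `NA` allowed).
#' @param ibw Ideal body weight, kg (> 0; `NA` allowed).
#' @return A [score_result()] for score `BWd`, with `value = abw - ibw` (kg).
#' @export
#' @examples
#' compute_bwd(c(70, 77.8, 63), 70) # codes 0, 2, 0
compute_bwd <- function(abw, ibw) {
  if (any(!is.na(abw) & abw <= 0) || any(!is.na(ibw) & ibw <= 0)) {
    stop("compute_bwd: abw and ibw must be > 0")
  }
  n <- max(length(abw), length(ibw))
  abw <- rep_len(abw, n)
  ibw <- rep_len(ibw, n)
  mr <- missing_reason(list(ABW = is.na(abw), IBW = is.na(ibw)))
  value <- abw - ibw
  code <- ifelse(value < -0.1 * ibw, 1L, ifelse(value > 0.1 * ibw, 2L, 0L))
  score_result("BWd",
    value = ifelse(mr$any, NA_real_, value),
    code = ifelse(mr$any, NA_integer_, code),
    applicable = !mr$any, reason = mr$reason
  )
}
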