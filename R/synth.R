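#' Phenotypes the synthetic generator can plant
#'
#' @return Character vector of phenotype names.
#' @export
phenotype_names <- function() {
  c("healthy", "undernourished_inflamed", "undernourished_clean",
    "overnourished", "b_deficient", "iron_deficient")
}

#' Generate a synthetic patient cohort with planted phenotypes
#'
#' Draws a seeded cohort of plausible adult orthopedic-surgery patients and
#' plants nutritional phenotypes whose expected score codes are known by
#' construction, so every classifier branch can be exercised without real
#' data.  Baseline ("healthy") draws: albumin N(42, 3) g/L truncated at 30,
#' CRP log-normal(log 2, 0.5) mg/L, lymphocytes N(2200, 400) cells/uL
#' truncated at 800, neutrophils N(4500, 900), hemoglobin N(145, 10) g/L,
#' MCV N(90, 4) fL, MCH N(30, 1.5) pg, MCHC N(34, 1) g/dL, prealbumin
#' N(250, 40) mg/L, height by sex, BMI N(26, 3) kg/m2 truncated above the
#' GLIM cutoff, ASA class 1-2.  Phenotype overrides are applied after the
#' base draws and are deliberately placed clear of every threshold:
#' \describe{
#'   \item{undernourished_inflamed}{BMI at least 1 kg/m2 below the GLIM
#'     cutoff, ASA class 3-4, CRP above 10 mg/L; forces GLIM code 3.}
#'   \item{undernourished_clean}{BMI below cutoff minus 1, ASA class 1, CRP
#'     under 2 mg/L, NLR under 2 via the counts; forces GLIM code 1.}
#'   \item{overnourished}{actual weight above 1.15 x ideal weight; forces
#'     body-weight-difference code 2.}
#'   \item{b_deficient}{MCV above 102 fL and MCH above 35 pg; forces the
#'     vitamin B deficit flag (code 1).}
#'   \item{iron_deficient}{actual hemoglobin at least 20 g/L below the
#'     ideal; guarantees an applicable, positive iron deficit (its code is
#'     cohort-relative, so none is forced).}
#' }
#' The distribution parameters are plausible clinical magnitudes chosen so
#' the planted classes sit well clear of the decision thresholds; they are
#' test fixtures, not estimates of any real population.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param mix Named numeric vector of phenotype proportions over
#'   [phenotype_names()] (must sum to 1); default all healthy.
#' @param ihb_policy Ideal hemoglobin by sex, g/L.
#' @param ibw_formula Ideal-body-weight formula for the overnutrition
#'   override.
#' @return A list with `records` (patient-record `data.frame`) and `truth`
#'   (`data.frame`: `patient_id`, `phenotype`, and `expected_glim`,
#'   `expected_bwd`, `expected_vbd` codes, `NA` where the phenotype forces
#'   none).
#' @export
generate_cohort <- function(n, seed, mix = c(healthy = 1),
                            ihb_policy = c(male = 150, female = 140),
                            ibw_formula = c("lorenz", "devine")) {
  stopifnot(n >= 1, is.numeric(seed))
  ibw_formula <- match.arg(ibw_formula)
  unknown <- setdiff(names(mix), phenotype_names())
  if (length(unknown)) {
    stop("unknown phenotype(s) in mix: ", paste(unknown, collapse = ", "))
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("mix proportions must be non-negative and sum to 1")
  }
  set.seed(seed)

  phen <- sample(names(mix), n, replace = TRUE, prob = mix)
  age <- sample(18:95, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age_class <- classify_age(age)
  senior <- age_class == "senior"
  cutoff <- ifelse(senior, 22, 20)

  height <- ifelse(sex == "male",
    stats::rnorm(n, 175, 7), stats::rnorm(n, 162, 6)
  )
  height <- pmin(pmax(height, 145), 205)
  ibw <- compute_ibw(height, sex, ibw_formula)
  ihb <- unname(ihb_policy[match(sex, c("male", "female"))])

  alb <- pmax(stats::rnorm(n, 42, 3), 30)
  crp <- stats::rlnorm(n, log(2), 0.5)
  lymc <- pmax(stats::rnorm(n, 2200, 400), 800)
  neutc <- pmax(stats::rnorm(n, 4500, 900), 500)
  ahb <- pmax(stats::rnorm(n, 145, 10), 90)
  mcv <- pmax(stats::rnorm(n, 90, 4), 70)
  mch <- pmax(stats::rnorm(n, 30, 1.5), 22)
  mchc <- pmax(stats::rnorm(n, 34, 1), 32.5)
  palb <- pmax(stats::rnorm(n, 250, 40), 80)
  asaps <- sample(1:2, n, replace = TRUE)
  # healthy BMI stays above the GLIM cutoff so no baseline patient
  # accidentally satisfies the phenotypic criterion
  bmi <- pmax(stats::rnorm(n, 26, 3), cutoff + 1)
  abw <- bmi * (height / 100)^2

  exp_glim <- rep(NA_integer_, n)
  exp_bwd <- rep(NA_integer_, n)
  exp_vbd <- rep(NA_integer_, n)

  idx <- which(phen == "undernourished_inflamed")
  if (length(idx)) {
    low_bmi <- stats::runif(length(idx), 16.5, cutoff[idx] - 1)
    abw[idx] <- low_bmi * (height[idx] / 100)^2
    asaps[idx] <- sample(3:4, length(idx), replace = TRUE)
    crp[idx] <- stats::runif(length(idx), 10.5, 60)
    exp_glim[idx] <- 3L
  }
  idx <- which(phen == "undernourished_clean")
  if (length(idx)) {
    low_bmi <- stats::runif(length(idx), 16.5, cutoff[idx] - 1)
    abw[idx] <- low_bmi * (height[idx] / 100)^2
    asaps[idx] <- 1L
    crp[idx] <- stats::runif(length(idx), 0.2, 1.9)
    lymc[idx] <- pmax(stats::rnorm(length(idx), 2500, 300), 1800)
    neutc[idx] <- lymc[idx] * stats::runif(length(idx), 0.6, 1.8)
    exp_glim[idx] <- 1L
  }
  idx <- which(phen == "overnourished")
  if (length(idx)) {
    abw[idx] <- ibw[idx] * stats::runif(length(idx), 1.16, 1.45)
    exp_bwd[idx] <- 2L
  }
  idx <- which(phen == "b_deficient")
  if (length(idx)) {
    mcv[idx] <- stats::runif(length(idx), 102.5, 115)
    mch[idx] <- stats::runif(length(idx), 35.5, 40)
    exp_vbd[idx] <- 1L
  }
  idx <- which(phen == "iron_deficient")
  if (length(idx)) {
    ahb[idx] <- ihb[idx] - stats::runif(length(idx), 21, 60)
  }

  records <- validate_records(data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, abw = abw, height = height, alb = alb,
    palb = palb, crp = crp, lymc = lymc, neutc = neutc, ahb = ahb,
    mcv = mcv, mch = mch, mchc = mchc, asaps = asaps,
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(
    patient_id = records$patient_id, phenotype = phen,
    expected_glim = exp_glim, expected_bwd = exp_bwd,
    expected_vbd = exp_vbd, stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Blank fields at random to emulate ragged retrospective data
#'
#' Each named field is independently set to missing with probability `rate`,
#' reproducibly for a fixed seed.
#'
#' @param records A patient-record `data.frame`.
#' @param rate Missingness probability in `[0, 1]`.
#' @param fields Character vector of fields to blank (any patient field
#'   except `patient_id`).
#' @param seed Integer seed.
#' @return The records with the chosen entries set to `NA`.
#' @export
inject_missingness <- function(records, rate, fields, seed) {
  stopifnot(is.data.frame(records), rate >= 0, rate <= 1)
  unknown <- setdiff(fields, setdiff(patient_fields, "patient_id"))
  if (length(unknown)) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  for (f in fields) {
    blank <- stats::runif(nrow(records)) < rate
    records[[f]][blank] <- if (f == "sex") NA_character_ else NA_real_
  }
  records
}

#' Write a synthetic cohort to disk
#'
#' Writes the records in the same CSV dialect [read_cohort()] ingests
#' (canonical units, identity column mapping) and the truth labels next to
#' it as `<stem>_truth.csv`.
#'
#' @param cohort A list from [generate_cohort()].
#' @param path Destination CSV path for the records.
#' @return Named character vector with the two paths written, invisibly.
#' @export
write_synthetic <- function(cohort, path) {
  stopifnot(is.list(cohort), all(c("records", "truth") %in% names(cohort)))
  con <- file(path, open = "wb")
  utils::write.csv(cohort$records, con, row.names = FALSE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  close(con)
  truth_path <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
  con <- file(truth_path, open = "wb")
  utils::write.csv(cohort$truth, con, row.names = FALSE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  close(con)
  invisible(c(records = path, truth = truth_path))
}
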