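# Patient fields carrying a unit, and the analyte dialect each one uses.
field_analytes <- c(
  abw = "weight", height = "height", alb = "albumin", palb = "prealbumin",
  crp = "crp", lymc = "lymphocytes", neutc = "neutrophils",
  ahb = "hemoglobin", mcv = "mcv", mch = "mch", mchc = "mchc"
)

# All patient-record fields, in canonical column order.
patient_fields <- c(
  "patient_id", "age", "sex", "abw", "height", "alb", "palb", "crp",
  "lymc", "neutc", "ahb", "mcv", "mch", "mchc", "asaps"
)

#' GLIM routine-data thresholds
#'
#' Cutoffs for the etiologic and phenotypic criteria of the routine-data
#' GLIM classifier: ASA physical status >= `asaps_min` flags disease burden,
#' CRP > `crp_max` mg/L or NLR >= `nlr_min` flags inflammation, and the
#' phenotypic low-BMI criterion uses `bmi_adult` kg/m2 before age 70 and
#' `bmi_senior` kg/m2 from age 70.
#'
#' @param asaps_min Integer, default 2.
#' @param crp_max mg/L, default 5 (strict inequality: CRP > 5 is elevated).
#' @param nlr_min Ratio, default 6 (NLR >= 6 is elevated).
#' @param bmi_adult kg/m2, default 20.
#' @param bmi_senior kg/m2, default 22.
#' @return A named list of class `glim_thresholds`.
#' @export
glim_thresholds <- function(asaps_min = 2, crp_max = 5, nlr_min = 6,
                            bmi_adult = 20, bmi_senior = 22) {
  stopifnot(
    asaps_min >= 1, crp_max > 0, nlr_min > 0,
    bmi_adult > 0, bmi_senior >= bmi_adult
  )
  structure(
    list(
      asaps_min = asaps_min, crp_max = crp_max, nlr_min = nlr_min,
      bmi_adult = bmi_adult, bmi_senior = bmi_senior
    ),
    class = "glim_thresholds"
  )
}

#' Red-cell index reference ranges for the vitamin B deficit flag
#'
#' Upper reference limits for MCV and MCH and the lower limit for MCHC used
#' to translate the score's qualitative arrows (raised MCV, raised MCH,
#' lowered MCHC) into numbers.
#'
#' @param mcv_high fL, default 100.
#' @param mch_high pg, default 34.
#' @param mchc_low g/dL, default 32.
#' @return A named list of class `vbd_ref_ranges`.
#' @export
vbd_ref_ranges <- function(mcv_high = 100, mch_high = 34, mchc_low = 32) {
  stopifnot(mcv_high > 0, mch_high > 0, mchc_low > 0)
  structure(
    list(mcv_high = mcv_high, mch_high = mch_high, mchc_low = mchc_low),
    class = "vbd_ref_ranges"
  )
}

#' Ingestion and scoring configuration
#'
#' One configuration object covers column mapping and source units for CSV
#' ingestion, the ideal-body-weight formula, the ideal hemoglobin policy,
#' GLIM thresholds, red-cell reference ranges, and scoring flags.
#'
#' @param columns Named character vector mapping patient fields (see
#'   `patient_id`, `age`, `sex`, `abw`, `height`, `alb`, `palb`, `crp`,
#'   `lymc`, `neutc`, `ahb`, `mcv`, `mch`, `mchc`, `asaps`) to source column
#'   names.  Defaults to identity.  Fields absent from the mapping are read
#'   as missing.
#' @param units Named character vector of source units per unit-bearing
#'   field, e.g. `c(alb = "g/dL")`.  Defaults to canonical units.
#' @param ibw_formula `"lorenz"` (default) or `"devine"`.
#' @param ihb_policy Named numeric vector `c(male = , female = )`, ideal
#'   hemoglobin in g/L; default 150 / 140 (the usual Ganzoni target of
#'   15 / 14 g/dL).
#' @param glim A [glim_thresholds()] object.
#' @param vbd_refs A [vbd_ref_ranges()] object.
#' @param cap_gnri_ratio Clamp the ABW/IBW ratio at 1 inside the geriatric
#'   nutritional risk index (the original formulation caps it); default TRUE.
#' @param gnri_senior_only Restrict the GNRI to patients aged 70 or over
#'   (its published validity domain); default TRUE.
#' @param vbd_rule `"mcv_and"` (default): deficiency requires raised MCV and
#'   (raised MCH or lowered MCHC).  `"or_mchc"`: (raised MCV and raised MCH)
#'   or lowered MCHC.
#' @param scores Character vector of scores to compute, default all nine.
#' @return A list of class `malnut_config`.
#' @export
malnut_config <- function(columns = NULL, units = NULL,
                          ibw_formula = c("lorenz", "devine"),
                          ihb_policy = c(male = 150, female = 140),
                          glim = glim_thresholds(),
                          vbd_refs = vbd_ref_ranges(),
                          cap_gnri_ratio = TRUE,
                          gnri_senior_only = TRUE,
                          vbd_rule = c("mcv_and", "or_mchc"),
                          scores = score_names()) {
  ibw_formula <- match.arg(ibw_formula)
  vbd_rule <- match.arg(vbd_rule)
  full_cols <- stats::setNames(patient_fields, patient_fields)
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), patient_fields)
    if (length(unknown)) {
      stop("unknown patient fields in column mapping: ",
           paste(unknown, collapse = ", "))
    }
    full_cols[names(columns)] <- columns
  }
  if (anyDuplicated(full_cols)) {
    stop("column mapping must be unique; duplicated: ",
         paste(full_cols[duplicated(full_cols)], collapse = ", "))
  }
  full_units <- vapply(unit_dialects[field_analytes], function(d) names(d)[1], "")
  names(full_units) <- names(field_analytes)
  if (!is.null(units)) {
    unknown <- setdiff(names(units), names(field_analytes))
    if (length(unknown)) {
      stop("unit declared for non-analyte field: ",
           paste(unknown, collapse = ", "))
    }
    for (f in names(units)) {
      dial <- unit_dialects[[field_analytes[[f]]]]
      if (!units[[f]] %in% names(dial)) {
        stop(sprintf(
          "unknown unit '%s' for field '%s' (supported: %s)",
          units[[f]], f, paste(names(dial), collapse = ", ")
        ))
      }
    }
    full_units[names(units)] <- units
  }
  stopifnot(
    is.numeric(ihb_policy), all(c("male", "female") %in% names(ihb_policy)),
    all(ihb_policy > 0)
  )
  bad <- setdiff(scores, score_names())
  if (length(bad)) {
    stop("unknown scores requested: ", paste(bad, collapse = ", "))
  }
  if (!inherits(glim, "glim_thresholds")) glim <- do.call(glim_thresholds, glim)
  if (!inherits(vbd_refs, "vbd_ref_ranges")) {
    vbd_refs <- do.call(vbd_ref_ranges, vbd_refs)
  }
  structure(
    list(
      columns = full_cols, units = full_units, ibw_formula = ibw_formula,
      ihb_policy = ihb_policy[c("male", "female")], glim = glim,
      vbd_refs = vbd_refs, cap_gnri_ratio = isTRUE(cap_gnri_ratio),
      gnri_senior_only = isTRUE(gnri_senior_only), vbd_rule = vbd_rule,
      scores = scores
    ),
    class = "malnut_config"
  )
}

#' Read a configuration file
#'
#' Accepts YAML or JSON holding any subset of the [malnut_config()]
#' arguments; unspecified entries keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `malnut_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path)
  }
  args <- list()
  for (nm in c("columns", "units", "ihb_policy")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("ibw_formula", "vbd_rule", "scores")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("cap_gnri_ratio", "gnri_senior_only")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- isTRUE(raw[[nm]])
  }
  if (!is.null(raw$glim)) args$glim <- do.call(glim_thresholds, raw$glim)
  if (!is.null(raw$vbd_refs)) args$vbd_refs <- do.call(vbd_ref_ranges, raw$vbd_refs)
  do.call(malnut_config, args)
}

#' Write a configuration file
#'
#' @param cfg A `malnut_config` object.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "malnut_config"))
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  plain$columns <- as.list(cfg$columns)
  plain$units <- as.list(cfg$units)
  plain$ihb_policy <- as.list(cfg$ihb_policy)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json: ", path)
  }
  invisible(path)
}
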