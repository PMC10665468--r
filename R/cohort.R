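#' Cohort-relative quartile codes
#'
#' Codes each value against the cohort's own quartiles: below the 25th
#' percentile codes 0, 25th to under 50th codes 1, 50th to under 75th codes
#' 2, at or above the 75th codes 3.  Percentiles are computed by linear
#' interpolation (the inclusive method, `stats::quantile` type 7) over the
#' non-missing values.  Ties share a code, so an all-equal cohort codes 3
#' throughout (every value sits at its own 75th percentile).
#'
#' @param values Numeric vector; `NA` entries are ignored for the quartiles
#'   and receive `NA` codes.
#' @return Integer vector of codes 0-3.  With fewer than 4 non-missing
#'   values quartiles are undefined and every entry is `NA`.
#' @export
#' @examples
#' quartile_codes(1:8) # 0 0 1 1 2 2 3 3
#' quartile_codes(rep(5, 4)) # 3 3 3 3
quartile_codes <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    return(rep(NA_integer_, length(values)))
  }
  q <- stats::quantile(values[ok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  codes <- rep(NA_integer_, length(values))
  codes[ok] <- findInterval(values[ok], q)
  codes
}

# Replace derived-quantity tokens in reason strings with the underlying
# missing patient fields, so every reason names columns the user can act on.
# `frags` maps token -> per-patient replacement (character, "" if unused).
rewrite_reasons <- function(reason, frags) {
  for (token in names(frags)) {
    hit <- which(grepl(token, reason, fixed = TRUE) & nzchar(frags[[token]]))
    for (i in hit) {
      reason[i] <- gsub(token, frags[[token]][i], reason[i], fixed = TRUE)
    }
  }
  reason
}

# Underlying-field fragment for a derived quantity: which of `parts`
# (named logical missing-vectors) are missing, comma-joined.
field_frag <- function(parts) {
  n <- max(vapply(parts, length, 1L))
  labs <- names(parts)
  miss <- vapply(parts, function(m) rep_len(m, n), logical(n))
  if (n == 1L) miss <- matrix(miss, nrow = 1L, dimnames = list(NULL, labs))
  apply(miss, 1L, function(row) paste(labs[row], collapse = ", "))
}

#' Score a cohort
#'
#' Runs the full scoring pipeline on a cohort of patient records: derives
#' BMI, ideal body weight, age class, NLR and ideal hemoglobin; computes
#' every selected score honoring each score's applicability rules; assigns
#' cohort-relative quartile codes to the two percentile-coded scores (PMAC,
#' IDM); and attaches a per-score summary.  Per-patient problems become
#' non-applicable results with a reason, never batch failures.  The run is
#' deterministic: identical records and configuration give identical output.
#'
#' @param records A patient-record `data.frame` as returned by
#'   [read_cohort()] or [generate_cohort()]: columns `patient_id`, `age`,
#'   `sex`, `abw`, `height`, `alb`, `palb`, `crp`, `lymc`, `neutc`, `ahb`,
#'   `mcv`, `mch`, `mchc`, `asaps`, all analytes in canonical units.
#' @param cfg A [malnut_config()] object.
#' @return An object of class `coded_cohort`: a list with elements
#'   `records`, `results` (long `data.frame`: `patient_id`, `score`,
#'   `value`, `code`, `applicable`, `reason`) and `summary` (see
#'   [summarize_cohort()]).
#' @export
score_cohort <- function(records, cfg = malnut_config()) {
  stopifnot(inherits(cfg, "malnut_config"))
  records <- validate_records(records)
  if (nrow(records) == 0L) stop("score_cohort: empty cohort")
  n <- nrow(records)
  r <- records

  age_class <- classify_age(r$age)
  ibw <- ifelse(is.na(r$height) | is.na(r$sex), NA_real_,
    compute_ibw(
      ifelse(is.na(r$height), 170, r$height),
      ifelse(is.na(r$sex), "male", r$sex), cfg$ibw_formula
    )
  )
  bmi <- compute_bmi(r$abw, r$height)
  nlr <- compute_nlr(r$neutc, r$lymc)
  ihb <- unname(cfg$ihb_policy[match(r$sex, c("male", "female"))])
  alb_gdl <- from_canonical(r$alb, "albumin", "g/dL")
  lymc_zero <- !is.na(r$lymc) & r$lymc == 0

  frags <- list(
    IBW = field_frag(list(height = is.na(r$height), sex = is.na(r$sex))),
    IHB = field_frag(list(sex = is.na(r$sex))),
    BMI = field_frag(list(ABW = is.na(r$abw), height = is.na(r$height))),
    NLR = field_frag(list(NEUTC = is.na(r$neutc), LYMC = is.na(r$lymc)))
  )

  results <- list()
  for (sc in cfg$scores) {
    res <- switch(sc,
      BWd = compute_bwd(r$abw, ibw),
      GNRI = {
        x <- compute_gnri(r$alb, r$abw, ibw, cfg$cap_gnri_ratio)
        if (cfg$gnri_senior_only) {
          x <- apply_guard(x, is.na(r$age), "missing age")
          x <- apply_guard(
            x, !is.na(age_class) & age_class != "senior",
            "younger adult or adult patient"
          )
        }
        x
      },
      INA = classify_ina(alb_gdl, r$lymc),
      LxA = compute_lxa(r$lymc, alb_gdl),
      PMA = compute_pma(r$crp, alb_gdl),
      PMAC = compute_pmac(nlr, r$crp, alb_gdl, r$palb),
      IDM = compute_idm(r$abw, ihb, r$ahb),
      VBD = classify_vbd(r$mcv, r$mch, r$mchc, cfg$vbd_refs, cfg$vbd_rule),
      GLIM = {
        g <- classify_glim(bmi, age_class, r$asaps, r$crp, nlr, cfg$glim)
        x <- glim_as_score_result(g)
        x$reason <- rewrite_reasons(x$reason, list(
          `age class` = rep("age", n)
        ))
        x
      }
    )
    # a zero lymphocyte count makes the NLR undefined without any field
    # being missing; name the real cause before the generic rewrite
    zero_hit <- lymc_zero & !res$applicable &
      grepl("NLR", res$reason, fixed = TRUE)
    res$reason[zero_hit] <- "LYMC is zero"
    res$reason <- rewrite_reasons(res$reason, frags)
    res$patient_id <- r$patient_id
    results[[sc]] <- res
  }

  # cohort-relative quartile coding for PMAC and IDM
  for (sc in intersect(c("PMAC", "IDM"), names(results))) {
    res <- results[[sc]]
    vals <- ifelse(res$applicable, res$value, NA_real_)
    if (sum(!is.na(vals)) < 4L) {
      # values are still emitted for pooling, but no within-cohort code exists
      pending <- res$applicable
      res$applicable[pending] <- FALSE
      res$reason[pending] <- "insufficient cohort size for percentile coding"
    } else {
      res$code <- quartile_codes(vals)
    }
    results[[sc]] <- res
  }

  long <- do.call(rbind, lapply(results, function(x) {
    data.frame(
      patient_id = x$patient_id, score = x$score, value = x$value,
      code = x$code, applicable = x$applicable, reason = x$reason,
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long$score <- factor(long$score, levels = intersect(score_names(), cfg$scores))
  long <- long[order(match(long$patient_id, r$patient_id), long$score), ]
  rownames(long) <- NULL

  out <- structure(
    list(records = records, results = long, config = cfg),
    class = "coded_cohort"
  )
  out$summary <- summarize_cohort(out)
  out
}

#' Summarize a scored cohort
#'
#' Per-score prevalence bookkeeping: how many patients each score applied
#' to, the count and proportion per categorical code among applicable
#' patients, and the count per non-applicability reason.  Counts per score
#' always sum to the cohort size.
#'
#' @param cohort A `coded_cohort` from [score_cohort()].
#' @return A list of class `cohort_summary` with `n` (cohort size),
#'   `codes` (`data.frame`: `score`, `code`, `n`, `prop`) and
#'   `not_applicable` (`data.frame`: `score`, `reason`, `n`).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "coded_cohort"))
  res <- cohort$results
  if (nrow(res) == 0L) stop("summarize_cohort: empty cohort")
  codes <- do.call(rbind, lapply(split(res, res$score), function(d) {
    app <- d[d$applicable, , drop = FALSE]
    if (nrow(app) == 0L) {
      return(NULL)
    }
    tab <- table(app$code)
    data.frame(
      score = d$score[1], code = as.integer(names(tab)),
      n = as.integer(tab), prop = as.numeric(tab) / nrow(app),
      stringsAsFactors = FALSE
    )
  }))
  nas <- do.call(rbind, lapply(split(res, res$score), function(d) {
    na <- d[!d$applicable, , drop = FALSE]
    if (nrow(na) == 0L) {
      return(NULL)
    }
    tab <- table(na$reason)
    data.frame(
      score = d$score[1], reason = names(tab), n = as.integer(tab),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(codes)) {
    codes <- data.frame(
      score = character(), code = integer(), n = integer(),
      prop = numeric(), stringsAsFactors = FALSE
    )
  }
  if (is.null(nas)) {
    nas <- data.frame(
      score = character(), reason = character(), n = integer(),
      stringsAsFactors = FALSE
    )
  }
  rownames(codes) <- rownames(nas) <- NULL
  structure(
    list(n = length(unique(res$patient_id)), codes = codes,
         not_applicable = nas),
    class = "cohort_summary"
  )
}

#' @export
summary.coded_cohort <- function(object, ...) object$summary

#' @export
print.coded_cohort <- function(x, ...) {
  scores <- levels(x$results$score)
  cat(sprintf(
    "<coded_cohort> %d patients, %d scores (%s)\n",
    nrow(x$records), length(scores), paste(scores, collapse = ", ")
  ))
  print(x$summary)
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n\nCode counts (applicable patients):\n", x$n))
  print(x$codes, row.names = FALSE)
  if (nrow(x$not_applicable)) {
    cat("\nNot applicable:\n")
    print(x$not_applicable, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.coded_cohort <- function(x, ...) {
  cohort_wide(x)
}

# Wide per-patient layout: one row per patient, four columns per score.
cohort_wide <- function(cohort) {
  res <- cohort$results
  ids <- cohort$records$patient_id
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (sc in levels(res$score)) {
    d <- res[res$score == sc, , drop = FALSE]
    d <- d[match(ids, d$patient_id), , drop = FALSE]
    out[[paste0(sc, "_value")]] <- d$value
    out[[paste0(sc, "_code")]] <- d$code
    out[[paste0(sc, "_applicable")]] <- d$applicable
    out[[paste0(sc, "_reason")]] <- d$reason
  }
  out
}

#' Export a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param path Destination `.csv` or `.json` path.  CSV concatenates the
#'   code-count and not-applicable tables with a `section` column; JSON
#'   keeps them nested.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else if (ext == "csv") {
    a <- cbind(section = "codes", x$codes,
               reason = rep("", nrow(x$codes)))
    b <- cbind(section = "not_applicable",
               x$not_applicable[, "score", drop = FALSE],
               code = rep(NA_integer_, nrow(x$not_applicable)),
               n = x$not_applicable$n,
               prop = rep(NA_real_, nrow(x$not_applicable)),
               reason = x$not_applicable$reason)
    utils::write.csv(rbind(a, b[names(a)]), path, row.names = FALSE)
  } else {
    stop("summary export must be .csv or .json: ", path)
  }
  invisible(path)
}
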