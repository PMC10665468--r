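#' Score names handled by the package
#'
#' The nine scores computable from routinely-collected orthopedic-surgery
#' data: the GLIM routine-data diagnosis plus eight screening scores.
#'
#' @return Character vector of the nine score names.
#' @export
score_names <- function() {
  c("GLIM", "BWd", "GNRI", "INA", "LxA", "PMA", "PMAC", "IDM", "VBD")
}

#' Construct a vector of score results
#'
#' A score result holds, per patient, the continuous value of a score (when
#' the score has one), its integer categorical code, an applicability flag,
#' and the reason the score could not be applied.  The contract is:
#' `applicable == FALSE` implies `value` and `code` are `NA` and `reason` is
#' non-empty; `applicable == TRUE` implies `code` is present.
#'
#' @param score Single score name, one of [score_names()].
#' @param value Numeric vector of continuous values (`NA` where absent).
#' @param code Integer vector of categorical codes (`NA` where absent).
#' @param applicable Logical vector.
#' @param reason Character vector of non-applicability reasons ("" when
#'   applicable).
#' @param pending_code Allow `code = NA` on applicable entries.  Used by the
#'   two cohort-relative scores (PMAC, IDM) whose code only exists once the
#'   whole cohort's quartiles are known; [score_cohort()] fills it in.
#' @return A `data.frame` of class `score_result` with columns `score`,
#'   `value`, `code`, `applicable`, `reason`.
#' @export
score_result <- function(score, value = NA_real_, code = NA_integer_,
                         applicable = TRUE, reason = "",
                         pending_code = FALSE) {
  score <- match.arg(score, score_names())
  n <- max(length(value), length(code), length(applicable), length(reason))
  out <- data.frame(
    score = rep_len(score, n),
    value = as.numeric(rep_len(value, n)),
    code = as.integer(rep_len(code, n)),
    applicable = rep_len(as.logical(applicable), n),
    reason = rep_len(as.character(reason), n),
    stringsAsFactors = FALSE
  )
  # enforce the contract rather than trusting callers
  out$value[!out$applicable] <- NA_real_
  out$code[!out$applicable] <- NA_integer_
  out$reason[out$applicable] <- ""
  bad <- !out$applicable & !nzchar(out$reason)
  if (any(bad)) {
    stop("score_result: non-applicable entries must carry a non-empty reason")
  }
  bad <- out$applicable & is.na(out$code)
  if (any(bad) && !isTRUE(pending_code)) {
    stop("score_result: applicable entries must carry a code")
  }
  class(out) <- c("score_result", "data.frame")
  out
}

#' Mark a score as not applicable
#'
#' Builds a score result whose every entry is non-applicable, carrying the
#' limitation that fired (for example a missing analyte, or the iron-deficit
#' guard "IHB lower than AHB").
#'
#' @param score Single score name, one of [score_names()].
#' @param reason Character vector of non-empty reasons (recycled).
#' @param n Number of entries.
#' @return A `score_result` with `applicable = FALSE` throughout.
#' @export
#' @examples
#' not_applicable("GNRI", "missing ALB")
not_applicable <- function(score, reason, n = length(reason)) {
  if (any(!nzchar(reason))) {
    stop("not_applicable: reason must be non-empty")
  }
  score_result(score,
    value = rep(NA_real_, n), code = rep(NA_integer_, n),
    applicable = FALSE, reason = rep_len(reason, n)
  )
}

# Combine per-field missingness into applicability and a reason string.
# `required` is a named list of logical "is missing" vectors; names are the
# field labels used in reason strings ("missing ALB", "missing ALB, LYMC").
missing_reason <- function(required) {
  n <- max(vapply(required, length, 1L))
  labs <- names(required)
  miss <- vapply(required, function(m) rep_len(m, n), logical(n))
  if (n == 1L) miss <- matrix(miss, nrow = 1L, dimnames = list(NULL, labs))
  reason <- apply(miss, 1L, function(row) {
    if (any(row)) paste("missing", paste(labs[row], collapse = ", ")) else ""
  })
  list(any = as.vector(rowSums(miss) > 0), reason = as.character(reason))
}

# Merge a base result with a guard: entries where `fire` is TRUE become
# not-applicable with `reason`.  Used for post-formula guards such as
# "IHB lower than AHB".
apply_guard <- function(res, fire, reason) {
  fire <- fire & res$applicable
  res$applicable[fire] <- FALSE
  res$value[fire] <- NA_real_
  res$code[fire] <- NA_integer_
  res$reason[fire] <- reason
  res
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "<score_result> %s: %d patient(s), %d applicable\n",
    x$score[1], nrow(x), sum(x$applicable)
  ))
  print.data.frame(x, ...)
  invisible(x)
}
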