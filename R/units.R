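# Unit dialects per analyte.  Canonical units are the first entry of each
# vector; factors convert FROM the named unit TO canonical by multiplication.
# Canonical choices: ALB g/L, PALB mg/L, CRP mg/L, cell counts cells/uL,
# hemoglobin g/L, MCV fL, MCH pg, MCHC g/dL, weight kg, height cm.
unit_dialects <- list(
  albumin      = c("g/L" = 1, "g/dL" = 10),
  prealbumin   = c("mg/L" = 1, "mg/dL" = 10, "g/L" = 1000),
  crp          = c("mg/L" = 1, "mg/dL" = 10),
  lymphocytes  = c("cells/uL" = 1, "10^9/L" = 1000, "10^3/uL" = 1000),
  neutrophils  = c("cells/uL" = 1, "10^9/L" = 1000, "10^3/uL" = 1000),
  hemoglobin   = c("g/L" = 1, "g/dL" = 10),
  mcv          = c("fL" = 1),
  mch          = c("pg" = 1),
  mchc         = c("g/dL" = 1, "g/L" = 0.1),
  weight       = c("kg" = 1),
  height       = c("cm" = 1, "m" = 100, "mm" = 0.1)
)

#' Supported unit dialects
#'
#' Lists, per analyte, the source units the ingestion layer accepts and the
#' exact multiplicative factor to the canonical storage unit.  The canonical
#' unit is the first entry of each analyte (factor 1).
#'
#' @return Named list of named numeric vectors (unit -> factor).
#' @export
supported_units <- function() unit_dialects

#' Convert an analyte value to its canonical unit
#'
#' Canonical storage units are albumin g/L, prealbumin mg/L, CRP mg/L, cell
#' counts cells/uL, hemoglobin g/L, MCV fL, MCH pg, MCHC g/dL, weight kg,
#' height cm.  Conversion is exact multiplication by a fixed factor, so a
#' round trip through [from_canonical()] is exact to floating-point.
#'
#' @param raw_value Numeric vector in the source unit.
#' @param analyte One of `names(supported_units())`.
#' @param source_unit A unit listed for that analyte.
#' @return Numeric vector in the canonical unit.
#' @export
#' @examples
#' to_canonical(3.5, "albumin", "g/dL") # 35 g/L
#' to_canonical(1.5, "lymphocytes", "10^9/L") # 1500 cells/uL
to_canonical <- function(raw_value, analyte, source_unit) {
  analyte <- match.arg(analyte, names(unit_dialects))
  dial <- unit_dialects[[analyte]]
  if (!source_unit %in% names(dial)) {
    stop(sprintf(
      "unknown unit '%s' for analyte '%s' (supported: %s)",
      source_unit, analyte, paste(names(dial), collapse = ", ")
    ))
  }
  raw_value * dial[[source_unit]]
}

#' Convert a canonical value back to a source unit
#'
#' Inverse of [to_canonical()].
#'
#' @inheritParams to_canonical
#' @param canonical_value Numeric vector in the canonical unit.
#' @return Numeric vector in `source_unit`.
#' @export
from_canonical <- function(canonical_value, analyte, source_unit) {
  analyte <- match.arg(analyte, names(unit_dialects))
  dial <- unit_dialects[[analyte]]
  if (!source_unit %in% names(dial)) {
    stop(sprintf(
      "unknown unit '%s' for analyte '%s' (supported: %s)",
      source_unit, analyte, paste(names(dial), collapse = ", ")
    ))
  }
  canonical_value / dial[[source_unit]]
}
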