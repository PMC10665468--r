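---
title: "Methods: routine-data malnutrition scoring and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: routine-data malnutrition scoring and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malnut)
```

## The model

`malnut` operationalizes a two-step view of nutritional assessment in
orthopedic-surgery research: *screening* for risk with substitute scores
computable from routinely-collected variables, then a *probable diagnosis*
with a routine-data rendering of the GLIM framework. None of the scores is
diagnostic on its own; each couples at least two surrogate variables of
nutritional interest (visceral proteins, immune counts, inflammation
markers, weight relative to ideal, red-cell indices). The package's job is
to compute them reproducibly, with an explicit per-score applicability
contract, over ragged retrospective data.

The GLIM classifier requires the phenotypic criterion (low BMI, with an
age-adjusted cutoff: below 20 kg/m² before age 70, below 22 kg/m² from 70)
plus an etiologic criterion built from the ASA physical status class
(disease burden, elevated at class ≥ 2) and two inflammation markers (CRP
> 5 mg/L, NLR ≥ 6). Three classes result: clean undernutrition (code 1:
nothing elevated), disease-related undernutrition without inflammation
(code 2), and with inflammation (code 3).

## Units

Laboratory sources disagree about units (albumin in g/L or g/dL, counts in
cells/µL or 10⁹/L), and the score formulas themselves mix dialects: the
GNRI takes albumin in g/L while INA, LxA, PMA and PMAC take it in g/dL. To
prevent silent factor-of-10 errors the package stores one canonical unit
per analyte (albumin g/L, prealbumin mg/L, CRP mg/L, counts cells/µL,
hemoglobin g/L, MCHC g/dL) and each score converts internally to the unit
its formula was published in. Ingestion converts declared source units by
exact multiplicative factors (`to_canonical()`), so round trips are exact
to floating point.

The Ganzoni iron-deficit formula deserves a note: its widely used factor
2.4 presumes the hemoglobin difference in g/dL (0.24 per g/L). The deficit
is therefore computed as ABW·(IHB−AHB)/10·2.4 + 500 with hemoglobin stored
in g/L, which keeps the additive 500 mg store term and the order-10³ mg
repletion magnitudes of clinical practice: a 70 kg patient 5 g/dL below
target carries a 1340 mg deficit.

## Parameters and defaults

* **Ideal body weight** — Lorenz by default (males H−100−(H−150)/4, females
  H−100−(H−150)/2.5), because the GNRI's source cohort used Lorenz, so the
  default keeps the index faithful; Devine is selectable
  (`ibw_formula = "devine"`).
* **Ideal hemoglobin** — 150 g/L (males) / 140 g/L (females), the usual
  Ganzoni target of 15/14 g/dL; configurable (`ihb_policy`), since no
  single target is universal.
* **GLIM thresholds** — ASAPS ≥ 2, CRP > 5 mg/L, NLR ≥ 6, BMI cutoffs
  20/22 kg/m². The inequality directions are kept exactly as published
  (≥ for ASAPS and NLR, strict > for CRP) rather than symmetrized.
* **VBD reference ranges** — MCV > 100 fL, MCH > 34 pg, MCHC < 32 g/dL.
  The score is defined only by qualitative arrows, so the numeric limits
  are ordinary upper/lower reference bounds and are config-exposed
  (`vbd_ref_ranges()`).
* **GNRI ratio cap** — ABW/IBW is clamped at 1 by default, matching the
  original formulation in which weight above ideal adds no protection;
  `cap_gnri_ratio = FALSE` removes the clamp.
* **GNRI senior gate** — the index was validated in patients ≥ 70, so the
  pipeline marks younger patients not-applicable; the formula itself does
  not enforce this, and `gnri_senior_only = FALSE` computes it anyway for
  study designs that want it.

## Decisions where the published material is ambiguous

* **BWd coding direction.** The published coding table transposes its
  parentheticals (attaching "gain" to undernutrition). Implemented
  semantically: loss beyond 10% of IBW codes 1 (undernutrition risk), gain
  beyond 10% codes 2 (overnutrition risk), consistent with the score's own
  definition of risk directions. The boundary case — a deviation of exactly
  10% — is not "greater than" and codes 0. The companion limitation note,
  read literally, would make the within-10% range non-applicable; since the
  coding table itself assigns it code 0 ("no risk"), code 0 wins.
* **GLIM overlap and gap.** Read literally, the published with- and
  without-inflammation rows overlap whenever the two inflammation markers
  are discordant (one raised, one not). Precedence goes to *with*
  inflammation (code 3): an elevated inflammatory marker is the clinically
  dominant etiology. Conversely, low BMI with no disease burden but raised
  inflammation matches no published row; such patients return
  not-applicable with reason `"unclassifiable combination"` rather than a
  diagnosis invented by the software. Enumerating the 8 boolean
  combinations under low BMI yields codes {1, 2, 3} and exactly this one
  gap (three of eight cells).
* **VBD precedence.** "Raised MCV and raised MCH or lowered MCHC" is
  parsed as MCV↑ AND (MCH↑ OR MCHC↓): the score targets macrocytic
  hyperchromic anemia, so macrocytosis is treated as necessary. The other
  reading, (MCV↑ AND MCH↑) OR MCHC↓, is available as
  `vbd_rule = "or_mchc"`.
* **Interval edges.** All banded scores use the closure stated in their
  band definitions, with gaps between printed bands (e.g. GNRI "82–91.9"
  then "92–98") closed half-open: [82, 92), [92, 98], value > 98 no risk.
  Senior BMI bands, printed with 0.1-wide gaps ("25.0–35.0" then
  "35.1–40.0"), are closed as right-closed intervals so that every positive
  BMI classifies deterministically — partition of (0, ∞) is
  property-tested. Age 70 belongs to the seniors ("≥ 70" being the
  explicit inequality).
* **Quartile coding.** The percentile-based coding for PMAC and IDM
  specifies the coding rule (below 25th → 0, …, at or above 75th → 3) but
  not the percentile estimator. Fixed to linear interpolation, the
  inclusive method (`stats::quantile` type 7). Ties are coded by value, so
  equal values share a code; in the degenerate all-equal cohort every value
  sits at its own 75th percentile and codes 3. Quartiles of fewer than 4
  values are not meaningful: such cohorts get no codes, with an explicit
  reason. The continuous values are still emitted in that case — the one
  deliberate exception to "not applicable implies no value" — so that
  small cohorts can be pooled and re-coded downstream.

## Missingness and applicability

Missing fields are explicit `NA`s, never sentinels. Each score checks its
own requirement list and reports the missing fields by name
(`"missing ALB"`, `"missing ABW, height"`); derived quantities are traced
back to their inputs, so a missing height surfaces as `"missing height"` in
the BWd, GNRI and GLIM rows, and a missing sex (which blocks ideal body
weight and ideal hemoglobin) as `"missing sex"`. A zero lymphocyte count
makes the NLR undefined without anything being missing and is reported as
`"LYMC is zero"`. Per-patient problems never abort a batch: an entirely
empty cohort scores to all-not-applicable output.

Age is restricted to ≥ 18 at ingestion; every classification in the system
starts at "younger adults", so pediatric records are rejected rather than
silently misclassified.

## The synthetic generator

`generate_cohort()` draws plausible adult orthopedic patients (albumin
N(42, 3) g/L, CRP log-normal around 2 mg/L, lymphocytes N(2200, 400)
cells/µL, hemoglobin N(145, 10) g/L, BMI N(26, 3) kg/m² truncated above
the GLIM cutoff, ASA 1–2, heights by sex) and then applies phenotype
overrides placed deliberately clear of every threshold: the
undernourished-inflamed class forces BMI at least 1 kg/m² below the cutoff,
ASA 3–4 and CRP above 10 mg/L, so its GLIM code 3 follows by construction;
the clean-undernourished class forces ASA 1, CRP below 2 and NLR below 2;
the overnourished class forces weight above 1.15×IBW; the B-deficient class
forces MCV above 102 fL and MCH above 35 pg; the iron-deficient class
forces hemoglobin at least 20 g/L below the ideal.

These distributions are test fixtures, not population claims. The
generator emulates the *structure* of routine data — the analytes, their
magnitudes, sex-dependent anthropometry, seeded missingness via
`inject_missingness()` — but not correlations between analytes, assay
noise, between-center calibration drift, or realistic phenotype frequency.
Passing the planted-phenotype recovery suite therefore demonstrates that
the classifiers implement their definitions exactly, not that they would
achieve any particular accuracy on real patients.

Validation problem sizes: property suites run on 10⁵ random inputs per
banded score; phenotype-recovery runs use 500 patients per phenotype;
threshold recovery uses bisection to a 10⁻¹² bracket. The whole suite runs
in a few seconds.

## Known limitations

* The scores are screening surrogates; the package deliberately offers no
  outcome validation, severity grading, iron-dosing or any clinical
  recommendation.
* Cohort-relative codes (PMAC, IDM) are not comparable across cohorts, and
  percentiles are computed over the whole cohort, not within subgroups.
* Canonical GLIM criteria that need non-routine data (weight-loss
  trajectory, muscle mass, food intake) are out of scope by design.
* Inputs are assumed assay-harmonized; the unit layer converts dialects,
  it does not calibrate methods.
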