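test_that("quartile codes follow the inclusive linear-interpolation rule", {
  expect_equal(quartile_codes(1:8), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # all equal: every value sits at its own 75th percentile
  expect_equal(quartile_codes(rep(5, 4)), rep(3L, 4))
  expect_equal(quartile_codes(c(1, 2, 3)), rep(NA_integer_, 3))
  expect_equal(quartile_codes(c(10, NA, 20, 30, 40, NA)),
               c(0L, NA, 1L, 2L, 3L, NA))
})

test_that("quartile codes travel with their values under permutation", {
  set.seed(51)
  for (i in 1:20) {
    v <- stats::rnorm(37)
    codes <- quartile_codes(v)
    p <- sample(length(v))
    expect_identical(quartile_codes(v[p]), codes[p])
  }
})

test_that("quartile codes are monotone in value", {
  set.seed(52)
  for (i in 1:20) {
    v <- stats::rnorm(50)
    codes <- quartile_codes(v)
    o <- order(v)
    expect_true(all(diff(codes[o]) >= 0))
  }
})

test_that("tie-free quartile buckets are near-balanced", {
  set.seed(53)
  for (n in c(8, 23, 40, 101)) {
    v <- sample(stats::rnorm(n * 3), n) # continuous, ties have prob 0
    tab <- tabulate(quartile_codes(v) + 1L, nbins = 4)
    expect_true(all(tab >= floor(n / 4) - 1 & tab <= ceiling(n / 4) + 1))
  }
})

test_that("scoring a complete senior cohort applies every score", {
  co <- score_cohort(complete_senior_cohort(8))
  res <- co$results
  expect_equal(nrow(res), 8 * 9)
  expect_true(all(res$applicable))
  expect_true(all(res$reason == ""))
  # spot checks against hand-computed values for the fixture
  gnri <- score_rows(co, "GNRI")
  expect_equal(gnri$value[1], 1.489 * 30 + 41.7 * (19 * 1.6^2 + 0.01) / 56)
  expect_equal(score_rows(co, "GLIM")$code, rep(3L, 8))
  expect_equal(score_rows(co, "BWd")$code, rep(1L, 8)) # ~48.7 vs IBW 56
  expect_equal(score_rows(co, "VBD")$code, rep(0L, 8))
  # percentile-coded scores received cohort-relative codes
  expect_false(anyNA(score_rows(co, "PMAC")$code))
  expect_false(anyNA(score_rows(co, "IDM")$code))
})

test_that("the GNRI senior gate is enforced at pipeline level and overridable", {
  rec <- complete_senior_cohort(4)
  rec$age <- 45
  co <- score_cohort(rec)
  g <- score_rows(co, "GNRI")
  expect_true(all(!g$applicable))
  expect_true(all(g$reason == "younger adult or adult patient"))
  cfg <- malnut_config(gnri_senior_only = FALSE)
  g2 <- score_rows(score_cohort(rec, cfg), "GNRI")
  expect_true(all(g2$applicable))
})

test_that("cohorts too small for quartiles keep values but code nothing", {
  co <- score_cohort(complete_senior_cohort(3))
  pmac <- score_rows(co, "PMAC")
  expect_true(all(!pmac$applicable))
  expect_true(all(pmac$reason == "insufficient cohort size for percentile coding"))
  expect_false(anyNA(pmac$value)) # continuous values still emitted
})

test_that("an all-missing cohort scores without error, everything not applicable", {
  rec <- data.frame(patient_id = c("a", "b", "c", "d"),
                    stringsAsFactors = FALSE)
  co <- score_cohort(validate_records(rec))
  expect_true(all(!co$results$applicable))
  expect_true(all(nzchar(co$results$reason)))
})

test_that("a zero lymphocyte count is named, not reported as missing", {
  rec <- complete_senior_cohort(4)
  rec$lymc <- 0
  co <- score_cohort(rec)
  for (sc in c("PMAC", "GLIM")) {
    d <- score_rows(co, sc)
    expect_true(all(!d$applicable))
    expect_true(all(d$reason == "LYMC is zero"))
  }
  # INA and LxA are defined at zero lymphocytes
  expect_true(all(score_rows(co, "INA")$applicable))
})

test_that("summaries conserve the cohort and proportions sum to one", {
  g <- generate_cohort(40, 9, c(healthy = 0.5, overnourished = 0.25,
                                b_deficient = 0.25))
  co <- score_cohort(g$records)
  s <- summary(co)
  expect_equal(s$n, 40)
  for (sc in score_names()) {
    n_app <- sum(s$codes$n[s$codes$score == sc])
    n_na <- sum(s$not_applicable$n[s$not_applicable$score == sc])
    expect_equal(n_app + n_na, 40)
    if (n_app > 0) {
      expect_equal(sum(s$codes$prop[s$codes$score == sc]), 1)
    }
  }
  expect_error(
    score_cohort(data.frame(patient_id = character(), stringsAsFactors = FALSE)),
    "empty"
  )
})

test_that("score selection restricts the computed set", {
  cfg <- malnut_config(scores = c("GNRI", "PMA"))
  co <- score_cohort(complete_senior_cohort(4), cfg)
  expect_setequal(unique(as.character(co$results$score)), c("GNRI", "PMA"))
  expect_error(malnut_config(scores = "XYZ"), "unknown")
})
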