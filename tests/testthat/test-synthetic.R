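test_that("generation is reproducible for a fixed seed", {
  mix <- c(healthy = 0.5, overnourished = 0.5)
  a <- generate_cohort(30, 3, mix)
  b <- generate_cohort(30, 3, mix)
  expect_identical(a, b)
  c <- generate_cohort(30, 4, mix)
  expect_false(identical(a$records, c$records))
})

test_that("generated records always satisfy the record invariants", {
  mix <- stats::setNames(rep(1 / 6, 6), phenotype_names())
  g <- generate_cohort(200, 13, mix)
  expect_silent(validate_records(g$records)) # would stop on violation
  expect_true(all(g$records$age >= 18))
  expect_true(all(g$records$abw > 0 & g$records$height > 0))
  expect_true(all(g$records$asaps %in% 1:6))
})

test_that("invalid mixes are rejected", {
  expect_error(generate_cohort(10, 1, c(healthy = 0.4)), "sum to 1")
  expect_error(generate_cohort(10, 1, c(martian = 1)), "unknown phenotype")
  expect_error(generate_cohort(10, 1, c(healthy = 1.4, overnourished = -0.4)))
})

test_that("empirical phenotype proportions match the requested mix", {
  mix <- c(healthy = 0.4, undernourished_inflamed = 0.3, b_deficient = 0.3)
  g <- generate_cohort(400, 17, mix)
  tab <- table(g$truth$phenotype)
  for (ph in names(mix)) {
    ci <- stats::binom.test(tab[[ph]], 400, mix[[ph]],
                            conf.level = 0.99)$p.value
    expect_gt(ci, 0.01)
  }
})

test_that("planted phenotypes force their expected codes", {
  checks <- list(
    list(mix = c(undernourished_inflamed = 1), score = "GLIM", code = 3L),
    list(mix = c(undernourished_clean = 1), score = "GLIM", code = 1L),
    list(mix = c(overnourished = 1), score = "BWd", code = 2L),
    list(mix = c(b_deficient = 1), score = "VBD", code = 1L)
  )
  for (ck in checks) {
    g <- generate_cohort(60, 23, ck$mix)
    d <- score_rows(score_cohort(g$records), ck$score)
    expect_true(all(d$applicable), info = names(ck$mix))
    expect_true(all(d$code == ck$code), info = names(ck$mix))
  }
  # healthy patients never satisfy the low-BMI phenotypic criterion
  g <- generate_cohort(100, 7, c(healthy = 1))
  glim <- score_rows(score_cohort(g$records), "GLIM")
  expect_true(all(is.na(glim$code)))
  # iron-deficient patients always have a computable, positive deficit
  g <- generate_cohort(60, 29, c(iron_deficient = 1))
  idm <- score_rows(score_cohort(g$records), "IDM")
  expect_true(all(idm$applicable))
  expect_true(all(idm$value > 500))
})

test_that("missingness injection is seeded, field-scoped and bounded", {
  g <- generate_cohort(50, 19, c(healthy = 1))
  expect_identical(inject_missingness(g$records, 0, "alb", 1), g$records)
  all_gone <- inject_missingness(g$records, 1, c("alb", "sex"), 1)
  expect_true(all(is.na(all_gone$alb)) && all(is.na(all_gone$sex)))
  a <- inject_missingness(g$records, 0.5, "crp", 99)
  b <- inject_missingness(g$records, 0.5, "crp", 99)
  expect_identical(a, b)
  expect_error(inject_missingness(g$records, 0.5, "patient_id", 1), "unknown")
  expect_error(inject_missingness(g$records, 0.5, "xyz", 1), "unknown")
})

test_that("blanking albumin disables exactly the albumin-dependent scores", {
  g <- generate_cohort(20, 31, c(healthy = 1))
  rec <- inject_missingness(g$records, 1, "alb", 2)
  co <- score_cohort(rec)
  for (sc in c("GNRI", "INA", "LxA", "PMA", "PMAC")) {
    d <- score_rows(co, sc)
    expect_true(all(!d$applicable), info = sc)
    expect_true(all(grepl("ALB", d$reason)), info = sc)
  }
  for (sc in c("BWd", "VBD", "INA")[1:2]) {
    expect_true(all(score_rows(co, sc)$applicable), info = sc)
  }
})
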