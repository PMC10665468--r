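test_that("NLR is the neutrophil/lymphocyte quotient with a division guard", {
  expect_equal(compute_nlr(4000, 2000), 2)
  expect_equal(compute_nlr(6000, 1000), 6)
  expect_true(is.na(compute_nlr(1000, 0)))
  expect_error(compute_nlr(-1, 100), ">= 0")
})

test_that("NLR grades split at 2, 4, 6, 8", {
  expect_equal(
    as.character(grade_nlr(c(0, 1.99, 2, 3.99, 4, 5.5, 6, 7.99, 8, 30))),
    c("normal", "normal", "low", "low", "mild", "mild", "moderate",
      "moderate", "severe", "severe")
  )
})

test_that("GNRI combines albumin and the capped weight ratio", {
  expect_equal(compute_gnri(0, 70, 70)$value, 41.7)
  r <- compute_gnri(c(40, 27), 70, 70)
  expect_equal(r$value, c(101.26, 81.903))
  expect_equal(r$code, c(0L, 3L))
  expect_equal(compute_gnri(35, 70, 70)$code, 1L) # 93.815 in the low band
  expect_equal(compute_gnri(30, 70, 70)$code, 2L) # 86.37 moderate
  # ratio cap: weight above ideal adds nothing unless uncapped
  capped <- compute_gnri(40, 84, 70)$value
  expect_equal(capped, compute_gnri(40, 70, 70)$value)
  expect_gt(compute_gnri(40, 84, 70, cap_ratio = FALSE)$value, capped)
  na <- compute_gnri(NA, 70, 70)
  expect_false(na$applicable)
  expect_equal(na$reason, "missing ALB")
})

test_that("instant nutritional assessment crosses albumin and lymphocytes", {
  res <- classify_ina(c(3.5, 3.4, 3.6, 3.4), c(1500, 1400, 1200, 1600))
  expect_equal(res$code, c(0L, 3L, 2L, 1L))
  expect_true(all(is.na(res$value))) # nominal score, no continuous value
  expect_equal(classify_ina(NA, 1500)$reason, "missing ALB")
  expect_equal(classify_ina(3.5, NA)$reason, "missing LYMC")
})

test_that("lymphocyte-albumin product bands at 4515 and 7920", {
  res <- compute_lxa(c(903, 1500, 2000), c(5, 3.5, 4.5))
  expect_equal(res$value, c(4515, 5250, 9000))
  expect_equal(res$code, c(2L, 1L, 0L))
  expect_equal(compute_lxa(NA, 4)$reason, "missing LYMC")
})

test_that("CRP/albumin ratio bands at 0.4, 1.2, 2.0, left-closed", {
  res <- compute_pma(c(0, 10, 4.8, 1.6, 8), 4)
  expect_equal(res$value, c(0, 2.5, 1.2, 0.4, 2))
  expect_equal(res$code, c(0L, 3L, 2L, 1L, 3L))
  z <- compute_pma(5, 0)
  expect_false(z$applicable)
  expect_equal(z$reason, "ALB is zero")
})

test_that("combined inflammation-protein index value matches its formula", {
  res <- compute_pmac(2, 5, 4, 200)
  expect_equal(res$value, 7 / 204)
  expect_true(res$applicable && is.na(res$code)) # code is cohort-relative
  expect_equal(compute_pmac(0, 0, 4, 200)$value, 0)
  na <- compute_pmac(2, 5, NA, 200)
  expect_false(na$applicable)
  expect_equal(na$reason, "missing ALB")
})

test_that("iron deficit follows Ganzoni with the Hb difference in g/dL", {
  # the additive constant alone when actual equals ideal hemoglobin
  for (w in c(1, 40, 70, 200)) {
    expect_identical(compute_idm(w, 150, 150)$value, 500)
  }
  expect_equal(compute_idm(70, 150, 100)$value, 70 * 5 * 2.4 + 500) # 1340
  guard <- compute_idm(70, 100, 150)
  expect_false(guard$applicable)
  expect_equal(guard$reason, "IHB lower than AHB")
  expect_equal(compute_idm(70, 150, NA)$reason, "missing AHB")
})

test_that("vitamin B deficit needs macrocytosis under the default rule", {
  res <- classify_vbd(c(105, 90, 105, 105), c(36, 30, 30, 30), c(33, 33, 33, 31))
  expect_equal(res$code, c(1L, 0L, 0L, 1L))
  # alternative precedence: lowered MCHC alone suffices
  alt <- classify_vbd(90, 30, 31, rule = "or_mchc")
  expect_equal(alt$code, 1L)
  expect_equal(classify_vbd(90, 30, 31)$code, 0L)
  expect_equal(classify_vbd(NA, 30, 33)$reason, "missing MCV")
  # reference ranges are configurable
  refs <- vbd_ref_ranges(mcv_high = 95, mch_high = 32, mchc_low = 30)
  expect_equal(classify_vbd(96, 33, 33, refs)$code, 1L)
})

test_that("continuous scores are monotone in their drivers", {
  alb <- seq(10, 50, by = 5)
  gnri <- compute_gnri(alb, 70, 70)$value
  expect_true(all(diff(gnri) > 0))
  crp <- seq(0, 40, by = 5)
  pma <- compute_pma(crp, 4)$value
  expect_true(all(diff(pma) > 0))
  expect_true(all(diff(compute_pma(10, seq(2, 6, by = 0.5))$value) < 0))
  expect_true(all(diff(compute_idm(seq(40, 100, 10), 150, 120)$value) > 0))
  expect_true(all(diff(compute_idm(70, seq(120, 150, 5), 110)$value) > 0))
  expect_true(all(diff(compute_lxa(seq(500, 3000, 250), 4)$value) > 0))
  expect_true(all(diff(compute_lxa(1500, seq(2, 5, 0.5))$value) > 0))
})

test_that("every banded classifier assigns exactly one code to any input", {
  set.seed(41)
  n <- 5000
  expect_false(anyNA(compute_gnri(stats::runif(n, 0, 60), 70, 70)$code))
  expect_false(anyNA(compute_lxa(stats::runif(n, 0, 4000), stats::runif(n, 0, 6))$code))
  expect_false(anyNA(compute_pma(stats::runif(n, 0, 50), stats::runif(n, 0.5, 6))$code))
  expect_false(anyNA(classify_ina(stats::runif(n, 1, 6), stats::runif(n, 0, 4000))$code))
  expect_false(anyNA(grade_nlr(stats::runif(n, 0, 20))))
  expect_false(anyNA(compute_bwd(stats::runif(n, 30, 150), 70)$code))
})

test_that("bisection on the classifiers recovers the printed cutoffs", {
  # GNRI: drive the value through albumin at ABW = IBW
  gnri_code <- function(v) compute_gnri((v - 41.7) / 1.489, 70, 70)$code
  for (th in c(82, 92, 98)) {
    expect_equal(bisect_code(gnri_code, th - 3, th + 3), th, tolerance = 1e-9)
  }
  lxa_code <- function(v) compute_lxa(v, 1)$code
  for (th in c(4515, 7920)) {
    expect_equal(bisect_code(lxa_code, th - 100, th + 100), th, tolerance = 1e-9)
  }
  pma_code <- function(v) compute_pma(v, 1)$code
  for (th in c(0.4, 1.2, 2.0)) {
    expect_equal(bisect_code(pma_code, th - 0.1, th + 0.1), th,
                 tolerance = 1e-9)
  }
  nlr_grade <- function(v) as.integer(grade_nlr(v))
  for (th in c(2, 4, 6, 8)) {
    expect_equal(bisect_code(nlr_grade, th - 1, th + 1), th, tolerance = 1e-9)
  }
  ina_alb <- function(a) classify_ina(a, 2000)$code
  expect_equal(bisect_code(ina_alb, 3, 4), 3.5, tolerance = 1e-9)
  ina_lym <- function(l) classify_ina(4, l)$code
  expect_equal(bisect_code(ina_lym, 1000, 2000), 1500, tolerance = 1e-9)
  bwd_code <- function(w) compute_bwd(w, 70)$code
  expect_equal(bisect_code(bwd_code, 60, 70), 63, tolerance = 1e-9)
  expect_equal(bisect_code(bwd_code, 70, 80), 77, tolerance = 1e-9)
})

test_that("the threshold registry mirrors the classifiers", {
  th <- score_thresholds()
  expect_equal(unname(th$GNRI), c(82, 92, 98))
  expect_equal(unname(th$LxA), c(4515, 7920))
  expect_equal(unname(th$PMA), c(0.4, 1.2, 2.0))
  expect_equal(unname(th$NLR), c(2, 4, 6, 8))
  expect_equal(unname(th$GLIM), c(20, 22, 2, 5, 6))
})
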