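test_that("anatomical points follow the inclusive cutoffs and strict ptosis equality", {
  cases <- list(
    # sn_n, n_imf, bw, ptosis, expected points
    list(29, 12, 20, 3, 3L),        # severe worked patient: N-IMF below cutoff
    list(25.9, 13.9, 15.9, 2.5, 0L), # all strictly below; 2.5 != 3
    list(26, 14, 16, 3, 4L)          # boundary values are inclusive
  )
  for (cs in cases) {
    pts <- anatomical_points(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(pts$anatomical_points, cs[[5]])
    expect_equal(pts$anatomical_points,
                 pts$pt_sn_n + pts$pt_n_imf + pts$pt_bw + pts$pt_ptosis)
  }
})

test_that("missing metrics are a hard error naming the field", {
  expect_error(anatomical_points(NA, 14, 16, 3), "sn_n")
  expect_error(anatomical_points(30, 14, 16, NA), "ptosis_grade")
  expect_error(anatomical_points(30, 14, 16, 2.7), "ptosis")
})

test_that("implausible measurements warn but do not error", {
  expect_warning(anatomical_points(45, 14, 16, 3), "sn_n")
  expect_warning(anatomical_points(30, 14, 30, 3), "base_width")
})

test_that("index breast is the heavier one, left on ties, single when unilateral", {
  co <- make_cohort(
    make_patient("bi", left = breast(resection_g = 520),
                 right = breast(resection_g = 440)),
    make_patient("bi2", left = breast(resection_g = 440),
                 right = breast(resection_g = 520)),
    make_patient("uni", left = NULL, right = breast(resection_g = 300)),
    make_patient("tie", left = breast(resection_g = 500),
                 right = breast(resection_g = 500))
  )
  idx <- select_index_breast(co)
  expect_equal(idx$index_side, c("left", "right", "right", "left"))
  expect_equal(idx$resection_g, c(520, 520, 300, 500))
  # literal rule: returned weight is the per-patient maximum
  mx <- pmax(co$l_resection_g, co$r_resection_g, na.rm = TRUE)
  expect_equal(idx$resection_g, mx)
})

test_that("bilateral records missing a resection weight cannot be scored", {
  co <- make_cohort(make_patient("p", left = breast(resection_g = NA),
                                 right = breast(resection_g = 300)))
  expect_error(select_index_breast(co), "bilateral.*resection weight")
})

test_that("worked patients score 5 (severe) and 2 (mild) with assumed symptom and finding", {
  co <- make_cohort(
    make_patient("severe", left = breast(sn_n = 29, n_imf = 12, bw = 20,
                                         ptosis = 3, resection_g = 607)),
    make_patient("mild", left = breast(sn_n = 24, n_imf = 11, bw = 14,
                                       ptosis = 1, resection_g = 310))
  )
  res <- abb_score(co)
  expect_equal(res$abb_score, c(5L, 2L))
  expect_equal(res$category, c("moderate_to_severe", "mild"))
})

test_that("explicit false flags override the assumption; floor of the scale is 0", {
  co <- make_cohort(make_patient(
    "none", left = breast(sn_n = 24, n_imf = 11, bw = 14, ptosis = 1),
    has_symptom = FALSE, has_finding = FALSE))
  res <- abb_score(co, assume_symptom = FALSE, assume_finding = FALSE)
  expect_equal(res$abb_score, 0L)
  expect_equal(res$category, "mild")
})

test_that("unknown symptom status with the assumption disabled is a hard error", {
  co <- make_cohort(make_patient("unk", has_symptom = NA))
  expect_error(abb_score(co, assume_symptom = FALSE), "unknown symptom")
  expect_equal(abb_score(co)$abb_score, 6L) # assumption supplies the point
})

test_that("scores are bounded, decomposable, and monotone in each measurement", {
  set.seed(41)
  for (i in 1:50) {
    b <- breast(sn_n = runif(1, 23, 40), n_imf = runif(1, 9, 22),
                bw = runif(1, 12, 24), ptosis = sample(c(0, 1, 2, 2.5, 3), 1),
                resection_g = runif(1, 100, 1100))
    co <- make_cohort(make_patient("p", left = b))
    res <- abb_score(co)
    expect_gte(res$abb_score, 0)
    expect_lte(res$abb_score, 6)
    expect_equal(res$abb_score,
                 res$anatomical_points + res$symptom_point + res$finding_point)
    # increasing any one measurement never decreases the score
    for (f in c("sn_n", "n_imf", "bw")) {
      b2 <- b; b2[[f]] <- b2[[f]] + runif(1, 0, 10)
      co2 <- make_cohort(make_patient("p", left = b2))
      expect_gte(suppressWarnings(abb_score(co2))$abb_score, res$abb_score)
    }
    b3 <- b; b3$ptosis <- 3 # raising to the qualifying grade
    expect_gte(abb_score(make_cohort(make_patient("p", left = b3)))$abb_score,
               res$abb_score)
  }
})

test_that("configurable cutoffs shift the rubric", {
  co <- make_cohort(make_patient("p", left = breast(sn_n = 27, n_imf = 12,
                                                    bw = 15, ptosis = 2.5)))
  strict <- abb_cutoffs(sn_n_min = 28)
  relaxed <- abb_cutoffs(ptosis_qualifying_grade = 2.5)
  expect_equal(abb_score(co, strict)$anatomical_points, 0L)
  expect_equal(abb_score(co, relaxed)$anatomical_points, 2L)
  expect_error(abb_cutoffs(sn_n_min = -1), "positive")
})
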