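# builds a cohort whose per-patient category/eligibility hit requested counts
cells_cohort <- function(tp, fn, fp, tn) {
  mk <- function(k, severe, eligible, tag) {
    if (k == 0) return(NULL)
    lapply(seq_len(k), function(i) {
      b <- if (severe) breast(sn_n = 30, n_imf = 15, bw = 17, ptosis = 3)
      else breast(sn_n = 24, n_imf = 11, bw = 14, ptosis = 1)
      # BSA 1.50 -> threshold 260 g; pick the resection weight around it
      b$resection_g <- if (eligible) 400 else 150
      make_patient(sprintf("%s%03d", tag, i), height_m = 1.55,
                   weight_kg = 51.8, left = b)
    })
  }
  make_cohort(c(mk(tp, TRUE, TRUE, "tp"), mk(fn, TRUE, FALSE, "fn"),
                mk(fp, FALSE, TRUE, "fp"), mk(tn, FALSE, FALSE, "tn")))
}

test_that("fourfold counts and sensitivity/specificity recompute from the cohort", {
  an <- analyze_cohort(cells_cohort(29, 32, 8, 16))
  conc <- concordance(an)
  expect_equal(c(conc$tp, conc$fn, conc$fp, conc$tn), c(29, 32, 8, 16))
  expect_equal(conc$n, 85)
  expect_equal(conc$sensitivity, 29 / 61)
  expect_equal(conc$specificity, 16 / 24)
})

test_that("concordance equals a brute-force per-patient enumeration", {
  for (seed in 1:20) {
    co <- random_cohort(sample(6:40, 1), seed = 300 + seed)
    an <- analyze_cohort(co)
    conc <- concordance(an)
    pos <- an$category == "moderate_to_severe"
    expect_equal(conc$tp, sum(pos & an$eligible))
    expect_equal(conc$fn, sum(pos & !an$eligible))
    expect_equal(conc$fp, sum(!pos & an$eligible))
    expect_equal(conc$tn, sum(!pos & !an$eligible))
    expect_equal(conc$n, nrow(co))
  }
})

test_that("degenerate margins flag the undefined statistic instead of dividing by zero", {
  an <- analyze_cohort(cells_cohort(10, 5, 0, 0))
  conc <- concordance(an)
  expect_true(is.na(conc$specificity))
  expect_equal(conc$sensitivity, 2 / 3)
  an2 <- an
  an2$eligible[1] <- NA
  expect_error(concordance(an2), "every patient")
})

test_that("spearman panel matches the brute-force rank-and-Pearson oracle", {
  # small tied sample, planted ties
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(stats::cor(x, y, method = "spearman"), oracle_spearman(x, y),
               tolerance = 1e-12)
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:30, 1)
    co <- random_cohort(n, seed = 600 + seed)
    an <- analyze_cohort(co)
    pan <- spearman_panel(an, "abb_score")
    for (j in seq_len(nrow(pan))) {
      v <- switch(pan$variable[j], ptosis_grade = an$ptosis,
                  base_width = an$bw, sn_n = an$sn_n, n_imf = an$n_imf,
                  resection_weight = an$actual_resection_g, bsa = an$bsa,
                  bmi = an$bmi, mismatch_weight = an$mismatch_g)
      if (pan$defined[j]) {
        expect_equal(pan$rho[j], oracle_spearman(v, an$abb_score),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("perfect monotone sequences give rho of +1 and -1 with p below alpha", {
  an <- tibble::tibble(
    ptosis = 1:8, bw = 8:1, sn_n = 1:8, n_imf = 1:8,
    actual_resection_g = 1:8, bsa = 1:8, bmi = 1:8, mismatch_g = 1:8,
    abb_score = 1:8, schnur_threshold_g = 1:8)
  pan <- spearman_panel(an, "abb_score")
  expect_equal(pan$rho[pan$variable == "ptosis_grade"], 1)
  expect_equal(pan$rho[pan$variable == "base_width"], -1)
  expect_true(all(pan$p_value < 0.05))
})

test_that("constant variables are flagged undefined, tiny samples are rejected", {
  an <- tibble::tibble(
    ptosis = rep(2, 10), bw = 1:10, sn_n = 1:10, n_imf = 1:10,
    actual_resection_g = 1:10, bsa = 1:10, bmi = 1:10, mismatch_g = 1:10,
    abb_score = 1:10, schnur_threshold_g = 1:10)
  pan <- spearman_panel(an, "abb_score")
  expect_false(pan$defined[pan$variable == "ptosis_grade"])
  expect_error(spearman_panel(an[1:3, ], "abb_score"), ">= 4")
})

test_that("p-values follow the two-tailed t approximation on n - 2 df", {
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30, 0, 2)
  an <- tibble::tibble(ptosis = x, bw = x, sn_n = x, n_imf = x,
                       actual_resection_g = x, bsa = x, bmi = x,
                       mismatch_g = x, abb_score = y,
                       schnur_threshold_g = y)
  pan <- spearman_panel(an, "abb_score")
  rho <- oracle_spearman(x, y)
  tval <- rho * sqrt((30 - 2) / (1 - rho^2))
  expect_equal(pan$p_value[1], 2 * pt(-abs(tval), 28), tolerance = 1e-12)
})

test_that("score strata carry exact percentages and per-stratum mean identities", {
  co <- random_cohort(60, seed = 9)
  an <- analyze_cohort(co)
  st <- stratify(an, "by_score")
  expect_equal(sum(st$n), nrow(co))
  expect_equal(st$stratum, sprintf("abb_%d", 0:6))
  nz <- st$n > 0
  expect_equal(st$met_pct[nz], 100 * st$met_n[nz] / st$n[nz])
  expect_true(all(st$resection_min[nz] <= st$resection_mean[nz] &
                    st$resection_mean[nz] <= st$resection_max[nz]))
  # linearity: mean mismatch = mean actual - mean threshold in every stratum
  expect_equal(st$mismatch_mean[nz],
               st$resection_mean[nz] - st$schnur_threshold_mean[nz])
  # empty strata are emitted with n = 0 and NA statistics
  if (any(!nz)) expect_true(all(is.na(st$bsa_mean[!nz])))
})

test_that("category-by-eligibility strata mirror the fourfold counts", {
  an <- analyze_cohort(cells_cohort(7, 9, 2, 6))
  st <- stratify(an, "by_category_x_eligibility")
  expect_equal(sum(st$n), 24)
  conc <- concordance(an)
  expect_equal(st$n[st$stratum == "moderate_to_severe_met_schnur"], conc$tp)
  expect_equal(st$n[st$stratum == "mild_not_met_schnur"], conc$tn)
})

test_that("single-patient strata have mean = min = max and undefined SD", {
  co <- make_cohort(make_patient("solo", left = breast(sn_n = 29, n_imf = 12,
                                                       bw = 20, ptosis = 3,
                                                       resection_g = 607)))
  st <- stratify(analyze_cohort(co), "by_score")
  row <- st[st$stratum == "abb_5", ]
  expect_equal(row$n, 1)
  expect_equal(row$resection_mean, row$resection_min)
  expect_equal(row$resection_mean, row$resection_max)
  expect_true(is.na(row$resection_sd))
})
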