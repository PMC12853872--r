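# Builders for small in-code cohorts and independent brute-force oracles.

breast <- function(sn_n = 30, n_imf = 14, bw = 16, ptosis = 3,
                   resection_g = 450) {
  list(sn_n = sn_n, n_imf = n_imf, bw = bw, ptosis = ptosis,
       resection_g = resection_g)
}

make_patient <- function(id = "P1", age = 45, height_m = 1.63,
                         weight_kg = 75, left = breast(), right = NULL,
                         has_symptom = TRUE, has_finding = TRUE) {
  side <- function(b, p) {
    if (is.null(b)) b <- list(sn_n = NA_real_, n_imf = NA_real_, bw = NA_real_,
                              ptosis = NA_real_, resection_g = NA_real_)
    stats::setNames(b, paste0(p, "_", names(b)))
  }
  tibble::as_tibble(c(list(patient_id = id, age = age, height_m = height_m,
                           weight_kg = weight_kg),
                      side(left, "l"), side(right, "r"),
                      list(has_symptom = has_symptom, has_finding = has_finding)))
}

make_cohort <- function(...) dplyr::bind_rows(...)

# random bilateral cohort with values inside the plausibility ranges
random_cohort <- function(n, seed) {
  set.seed(seed)
  make_cohort(lapply(seq_len(n), function(i) {
    w <- round(runif(2, 100, 1100))
    make_patient(
      id = sprintf("R%03d", i), age = round(runif(1, 18, 80)),
      height_m = round(runif(1, 1.5, 1.8), 2),
      weight_kg = round(runif(1, 55, 115), 1),
      left = breast(sn_n = round(runif(1, 23, 40), 1),
                    n_imf = round(runif(1, 9, 22), 1),
                    bw = round(runif(1, 12, 24), 1),
                    ptosis = sample(c(1, 2, 2.5, 3), 1),
                    resection_g = w[1]),
      right = breast(sn_n = round(runif(1, 23, 40), 1),
                     n_imf = round(runif(1, 9, 22), 1),
                     bw = round(runif(1, 12, 24), 1),
                     ptosis = sample(c(1, 2, 2.5, 3), 1),
                     resection_g = w[2]))
  }))
}

# independent Spearman oracle: average ranks by pairwise comparison, then the
# Pearson product-moment formula written out by hand
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- rk(x); ry <- rk(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# independent group-mean scan oracle: naive per-candidate filtering
oracle_scan <- function(vals, weights, ptosis, cand) {
  below <- vals[vals < cand]
  list(n_below = length(below), n_above = sum(vals >= cand),
       mw_below = if (length(below)) mean(weights[vals < cand]) else NA_real_,
       mw_above = if (any(vals >= cand)) mean(weights[vals >= cand]) else NA_real_,
       mp_below = if (length(below)) mean(ptosis[vals < cand]) else NA_real_,
       mp_above = if (any(vals >= cand)) mean(ptosis[vals >= cand]) else NA_real_)
}
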