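#' Full per-patient analysis table
#'
#' Joins the ABB scoring ([abb_score()]) and Schnur assessment
#' ([assess_schnur()]) of a cohort into one per-patient tibble, adding BMI
#' (`weight / height^2`, always derived, never ingested). This is the input
#' to [concordance()], [spearman_panel()] and [stratify()].
#'
#' @inheritParams abb_score
#' @inheritParams assess_schnur
#' @return A tibble, one row per patient.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 1))
#' analyze_cohort(cohort)
#' @export
analyze_cohort <- function(cohort, cutoffs = abb_cutoffs(),
                           table = schnur_table(), policy = "nearest",
                           assume_symptom = TRUE, assume_finding = TRUE) {
  scored <- abb_score(cohort, cutoffs, assume_symptom, assume_finding)
  schnur <- assess_schnur(cohort, table, policy)
  out <- dplyr::inner_join(scored, schnur, by = "patient_id")
  if (nrow(out) != nrow(cohort)) {
    stop("scoring and Schnur assessment cover different patients", call. = FALSE)
  }
  out$age <- cohort$age[match(out$patient_id, cohort$patient_id)]
  out$bmi <- with(cohort[match(out$patient_id, cohort$patient_id), ],
                  weight_kg / height_m^2)
  out
}

#' Fourfold concordance of ABB category and Schnur eligibility
#'
#' Cross-classifies the cohort with moderate-to-severe ABB (score 3-6) as the
#' condition positive and Schnur eligibility as the test positive, and
#' derives the Schnur scale's sensitivity and specificity against the ABB
#' reference. Degenerate margins (no positives or no negatives) leave the
#' corresponding statistic `NA`.
#'
#' @param analyzed output of [analyze_cohort()], or any tibble with
#'   `category` and `eligible` columns covering every patient.
#' @return An object of class `abb_concordance`: counts `tp`, `fn`, `fp`,
#'   `tn`, `n`, exact `sensitivity`/`specificity` fractions and
#'   `sensitivity_pct`/`specificity_pct`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 1))
#' concordance(analyze_cohort(cohort))
#' @export
concordance <- function(analyzed) {
  stopifnot(is.data.frame(analyzed),
            all(c("category", "eligible") %in% names(analyzed)))
  if (anyNA(analyzed$category) || anyNA(analyzed$eligible)) {
    stop("every patient must carry an ABB category and a Schnur eligibility flag",
         call. = FALSE)
  }
  pos <- analyzed$category == "moderate_to_severe"
  test <- analyzed$eligible
  tp <- sum(pos & test); fn <- sum(pos & !test)
  fp <- sum(!pos & test); tn <- sum(!pos & !test)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, n = tp + fn + fp + tn,
         sensitivity = sens, specificity = spec,
         sensitivity_pct = 100 * sens, specificity_pct = 100 * spec),
    class = "abb_concordance")
}

#' @export
print.abb_concordance <- function(x, ...) {
  cat("ABB vs Schnur eligibility (condition = moderate-to-severe ABB)\n")
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d  (n = %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$n))
  cat(sprintf("  sensitivity %s   specificity %s\n",
              if (is.na(x$sensitivity)) "undefined" else
                sprintf("%.1f%%", x$sensitivity_pct),
              if (is.na(x$specificity)) "undefined" else
                sprintf("%.1f%%", x$specificity_pct)))
  invisible(x)
}

# Spearman rho with average-rank ties plus the two-tailed t approximation on
# n - 2 df. rho is NA for a constant variable (undefined, flagged upstream).
spearman_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) stop("need >= 4 complete pairs", call. = FALSE)
  if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

#' Spearman correlation panel
#'
#' Correlates a target (the ABB score or the Schnur threshold weight) with
#' the standard panel of patient variables: ptosis grade, base width, SN-N,
#' N-IMF, resection weight, BSA, BMI, and mismatch weight. Two-tailed
#' p-values use the t approximation on n - 2 degrees of freedom; ties get
#' average ranks. Constant variables return `NA` rho, flagged in the output.
#'
#' @param analyzed output of [analyze_cohort()].
#' @param target `"abb_score"` or `"schnur_threshold"`.
#' @return A tibble with `variable`, `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_panel <- function(analyzed, target = c("abb_score", "schnur_threshold")) {
  target <- match.arg(target)
  tcol <- if (target == "abb_score") "abb_score" else "schnur_threshold_g"
  vars <- c(ptosis_grade = "ptosis", base_width = "bw", sn_n = "sn_n",
            n_imf = "n_imf", resection_weight = "actual_resection_g",
            bsa = "bsa", bmi = "bmi", mismatch_weight = "mismatch_g")
  rows <- lapply(names(vars), function(nm) {
    r <- spearman_t(analyzed[[vars[[nm]]]], analyzed[[tcol]])
    tibble::tibble(target = target, variable = nm, rho = r$rho,
                   p_value = r$p, n = r$n, defined = !is.na(r$rho))
  })
  dplyr::bind_rows(rows)
}

summ_stats <- function(x, prefix) {
  out <- if (length(x) == 0) {
    list(NA_real_, NA_real_, NA_real_, NA_real_)
  } else {
    list(mean(x), min(x), max(x), if (length(x) > 1) sd(x) else NA_real_)
  }
  names(out) <- paste0(prefix, c("_mean", "_min", "_max", "_sd"))
  out
}

#' Stratified cohort summaries
#'
#' Summarizes BSA, BMI, actual resection weight, mismatch weight, and Schnur
#' threshold weight per stratum, either by individual ABB score (0-6, all
#' levels emitted, empty strata with n = 0 and `NA` statistics) or by the
#' four ABB-category x Schnur-eligibility cells. SD is the sample (n - 1)
#' standard deviation; single-patient strata have `NA` SD. Score strata also
#' carry met / did-not-meet Schnur counts and exact percentages.
#'
#' @param analyzed output of [analyze_cohort()].
#' @param scheme `"by_score"` or `"by_category_x_eligibility"`.
#' @return A tibble, one row per stratum.
#' @export
stratify <- function(analyzed, scheme = c("by_score", "by_category_x_eligibility")) {
  scheme <- match.arg(scheme)
  vars <- c(bsa = "bsa", bmi = "bmi", resection = "actual_resection_g",
            mismatch = "mismatch_g", schnur_threshold = "schnur_threshold_g")
  strata <- if (scheme == "by_score") {
    lapply(0:6, function(s) list(
      label = sprintf("abb_%d", s),
      rows = which(analyzed$abb_score == s)))
  } else {
    cells <- expand.grid(category = c("moderate_to_severe", "mild"),
                         eligible = c(TRUE, FALSE), stringsAsFactors = FALSE)
    lapply(seq_len(nrow(cells)), function(i) list(
      label = sprintf("%s_%s", cells$category[i],
                      if (cells$eligible[i]) "met_schnur" else "not_met_schnur"),
      rows = which(analyzed$category == cells$category[i] &
                     analyzed$eligible == cells$eligible[i])))
  }
  rows <- lapply(strata, function(st) {
    sub <- analyzed[st$rows, ]
    stats <- unlist(lapply(names(vars),
                           function(v) summ_stats(sub[[vars[[v]]]], v)))
    met <- sum(sub$eligible)
    tibble::tibble(
      stratum = st$label, n = nrow(sub),
      met_n = met, met_pct = if (nrow(sub) > 0) 100 * met / nrow(sub) else NA_real_,
      unmet_n = nrow(sub) - met,
      unmet_pct = if (nrow(sub) > 0) 100 * (nrow(sub) - met) / nrow(sub) else NA_real_,
      tibble::as_tibble(as.list(stats))
    )
  })
  dplyr::bind_rows(rows)
}
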