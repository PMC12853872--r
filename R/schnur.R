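#' DuBois body surface area
#'
#' Computes body surface area (m^2) from height and weight with the DuBois
#' formula, `0.007184 * height_cm^0.725 * weight_kg^0.425`. Vectorized;
#' strictly increasing in both arguments.
#'
#' @param height_m height in metres.
#' @param weight_kg weight in kilograms.
#' @return Body surface area in m^2.
#' @examples
#' dubois_bsa(1.70, 70) # about 1.810
#' @export
dubois_bsa <- function(height_m, weight_kg) {
  check_positive(height_m, "height_m")
  check_positive(weight_kg, "weight_kg")
  0.007184 * (height_m * 100)^0.725 * weight_kg^0.425
}

#' Load and validate a Schnur sliding-scale table
#'
#' Reads a two-column CSV (`bsa_m2`, `threshold_g`) mapping body surface area
#' to the minimum per-breast resection weight an insurer requires. The table
#' ships as data, not code: the default is the widely published sliding scale
#' on a regular 0.05 m^2 BSA grid. Validation enforces the schema, a strictly
#' increasing regular BSA grid, and strictly increasing thresholds.
#'
#' @param path path to the table CSV; `NULL` (default) loads the shipped scale.
#' @return A tibble of class `schnur_table` with attribute `spacing` (the BSA
#'   grid step).
#' @examples
#' tab <- schnur_table()
#' head(tab)
#' @export
schnur_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "schnur_scale.csv",
                                package = "abburden", mustWork = TRUE)
  raw <- read.csv(path)
  if (!identical(names(raw), c("bsa_m2", "threshold_g"))) {
    stop(sprintf("Schnur table must have columns {bsa_m2, threshold_g}; found {%s}",
                 paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) < 2 || anyNA(raw)) {
    stop("Schnur table must have >= 2 complete rows", call. = FALSE)
  }
  dg <- diff(raw$bsa_m2)
  if (any(dg <= 0) || diff(range(dg)) > 1e-9) {
    stop("Schnur table BSA grid must be strictly increasing with regular spacing",
         call. = FALSE)
  }
  if (any(diff(raw$threshold_g) <= 0)) {
    stop("Schnur table thresholds must be strictly increasing with BSA",
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  attr(out, "spacing") <- dg[1]
  class(out) <- c("schnur_table", class(out))
  out
}

#' Schnur threshold weight for a body surface area
#'
#' Resolves a BSA value to a row of the sliding scale under a grid-matching
#' policy and returns the threshold weight. `"nearest"` (default) matches the
#' closest grid value with halves rounding up; `"floor"`/`"ceil"` take the
#' grid value at or below/above; `"linear"` interpolates between grid rows.
#' All policies are monotone non-decreasing in BSA.
#'
#' @param bsa body surface area, m^2 (vectorized).
#' @param table a [schnur_table()].
#' @param policy grid-matching policy.
#' @return A tibble with `bsa`, `matched_grid_bsa` (equal to `bsa` under
#'   `"linear"`), and `threshold_g`.
#' @export
schnur_threshold <- function(bsa, table = schnur_table(),
                             policy = c("nearest", "floor", "ceil", "linear")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "schnur_table"))
  check_positive(bsa, "bsa")
  grid <- table$bsa_m2
  sp <- attr(table, "spacing")
  lo <- if (policy == "nearest") grid[1] - sp / 2 else grid[1]
  hi <- grid[length(grid)]
  eps <- 1e-9
  if (any(bsa < lo - eps | bsa > hi + eps)) {
    stop(sprintf("BSA outside the resolvable range [%.3f, %.2f] m^2 under policy '%s'",
                 lo, hi, policy), call. = FALSE)
  }
  pos <- (bsa - grid[1]) / sp
  if (policy == "linear") {
    thr <- stats::approx(grid, table$threshold_g, xout = bsa, rule = 1)$y
    return(tibble::tibble(bsa = bsa, matched_grid_bsa = bsa, threshold_g = thr))
  }
  i <- switch(policy,
              nearest = floor(pos + 0.5 + eps),  # half rounds up
              floor = floor(pos + eps),
              ceil = ceiling(pos - eps))
  i <- pmin(pmax(i, 0), length(grid) - 1) + 1
  tibble::tibble(bsa = bsa, matched_grid_bsa = grid[i],
                 threshold_g = table$threshold_g[i])
}

#' Per-patient Schnur eligibility assessment
#'
#' Computes each patient's DuBois BSA from height and weight (BSA is always
#' derived, never ingested, to keep provenance single-sourced), looks up the
#' Schnur threshold weight, and forms the mismatch weight
#' `actual resection - threshold`. A non-negative mismatch means the patient
#' meets the threshold and is eligible for coverage; an exact zero is counted
#' as eligible (meeting a minimum) and reported with a message.
#'
#' The resected weight compared against the threshold is the index (heavier)
#' breast by default, consistent with the ABB per-patient rule;
#' `resection = "average"` averages the two breasts for sensitivity analyses
#' (averaging tends to understate asymmetric burden).
#'
#' @param cohort a cohort tibble (see [read_cohort()]); every index breast
#'   needs a resection weight.
#' @param table a [schnur_table()].
#' @param policy grid-matching policy, see [schnur_threshold()].
#' @param resection `"index"` (default) or `"average"`.
#' @return A tibble with `patient_id`, `bsa`, `matched_grid_bsa`,
#'   `schnur_threshold_g`, `actual_resection_g`, `mismatch_g`, `eligible`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 1))
#' assess_schnur(cohort)
#' @export
assess_schnur <- function(cohort, table = schnur_table(),
                          policy = c("nearest", "floor", "ceil", "linear"),
                          resection = c("index", "average")) {
  policy <- match.arg(policy)
  resection <- match.arg(resection)
  check_cohort(cohort)
  idx <- select_index_breast(cohort)
  actual <- if (resection == "index") {
    idx$resection_g
  } else {
    rowMeans(cbind(cohort$l_resection_g, cohort$r_resection_g), na.rm = TRUE)
  }
  if (anyNA(actual)) {
    stop(sprintf("missing resection weight for: %s",
                 paste(cohort$patient_id[is.na(actual)], collapse = ", ")),
         call. = FALSE)
  }
  check_positive(actual, "resection weight")
  bsa <- dubois_bsa(cohort$height_m, cohort$weight_kg)
  thr <- schnur_threshold(bsa, table, policy)
  mismatch <- actual - thr$threshold_g
  if (any(mismatch == 0)) {
    message(sum(mismatch == 0),
            " patient(s) exactly at the Schnur threshold: counted eligible")
  }
  tibble::tibble(
    patient_id = cohort$patient_id,
    bsa = bsa,
    matched_grid_bsa = thr$matched_grid_bsa,
    schnur_threshold_g = thr$threshold_g,
    actual_resection_g = actual,
    mismatch_g = mismatch,
    eligible = mismatch >= 0
  )
}
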