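#' ABB rubric cutoffs and point weights
#'
#' Constructs the cutoff set used by the anatomical breast burden (ABB)
#' rubric. A breast earns one point for each anatomical criterion it meets:
#' sternal notch-to-nipple distance (SN-N) at or above `sn_n_min`,
#' nipple-to-inframammary fold distance (N-IMF) at or above `n_imf_min`,
#' base width (BW) at or above `bw_min`, and Regnault ptosis grade exactly
#' equal to `ptosis_qualifying_grade` (severe ptosis only; lower grades,
#' including the interpolated 2.5, score zero). One further point each comes
#' from the symptom and physical-finding domains.
#'
#' All cutoffs are inclusive ("or greater"). The defaults give a maximum
#' score of 4 anatomical + 1 symptom + 1 finding = 6 points.
#'
#' @param sn_n_min SN-N cutoff in cm (default 26).
#' @param n_imf_min N-IMF cutoff in cm (default 14).
#' @param bw_min base width cutoff in cm (default 16).
#' @param ptosis_qualifying_grade the single Regnault grade that earns the
#'   ptosis point, matched by strict equality (default 3).
#' @param symptom_points,finding_points point weight of the symptom and
#'   physical-finding domains (defaults 1).
#' @return An object of class `abb_cutoffs`.
#' @examples
#' abb_cutoffs()
#' abb_cutoffs(sn_n_min = 28) # stricter SN-N for a sensitivity analysis
#' @export
abb_cutoffs <- function(sn_n_min = 26, n_imf_min = 14, bw_min = 16,
                        ptosis_qualifying_grade = 3,
                        symptom_points = 1L, finding_points = 1L) {
  check_positive(sn_n_min, "sn_n_min")
  check_positive(n_imf_min, "n_imf_min")
  check_positive(bw_min, "bw_min")
  check_ptosis(ptosis_qualifying_grade, "ptosis_qualifying_grade")
  if (symptom_points < 0 || finding_points < 0) {
    stop("point weights must be >= 0", call. = FALSE)
  }
  structure(
    list(sn_n_min = sn_n_min, n_imf_min = n_imf_min, bw_min = bw_min,
         ptosis_qualifying_grade = ptosis_qualifying_grade,
         symptom_points = as.integer(symptom_points),
         finding_points = as.integer(finding_points)),
    class = "abb_cutoffs"
  )
}

#' @export
print.abb_cutoffs <- function(x, ...) {
  cat("ABB rubric cutoffs\n")
  cat(sprintf("  SN-N  >= %g cm\n  N-IMF >= %g cm\n  BW    >= %g cm\n",
              x$sn_n_min, x$n_imf_min, x$bw_min))
  cat(sprintf("  ptosis grade == %g\n", x$ptosis_qualifying_grade))
  cat(sprintf("  symptom domain: %d point(s); physical findings: %d point(s)\n",
              x$symptom_points, x$finding_points))
  max_score <- 4L + x$symptom_points + x$finding_points
  cat(sprintf("  maximum score: %d\n", max_score))
  invisible(x)
}

#' Anatomical points for one or more breasts
#'
#' Scores the four binary anatomical criteria of the ABB rubric for each
#' breast and returns the per-criterion breakdown together with the 0-4
#' anatomical point total. Inputs are vectorized over breasts.
#'
#' @param sn_n sternal notch-to-nipple distance, cm.
#' @param n_imf nipple-to-inframammary fold distance, cm.
#' @param base_width base width, cm.
#' @param ptosis_grade Regnault grade in \{0, 1, 2, 2.5, 3\}; a documented
#'   "Grade 2-3" is represented as 2.5.
#' @param cutoffs an [abb_cutoffs()] object.
#' @return A tibble with indicator columns `pt_sn_n`, `pt_n_imf`, `pt_bw`,
#'   `pt_ptosis` and their sum `anatomical_points`.
#' @examples
#' anatomical_points(sn_n = 29, n_imf = 12, base_width = 20, ptosis_grade = 3)
#' @export
anatomical_points <- function(sn_n, n_imf, base_width, ptosis_grade,
                              cutoffs = abb_cutoffs()) {
  stopifnot(inherits(cutoffs, "abb_cutoffs"))
  vals <- list(sn_n = sn_n, n_imf = n_imf, base_width = base_width,
               ptosis_grade = ptosis_grade)
  for (nm in names(vals)) {
    if (anyNA(vals[[nm]])) {
      stop(sprintf("missing anatomical metric `%s`: all four metrics are required to score", nm),
           call. = FALSE)
    }
  }
  check_positive(sn_n, "sn_n")
  check_positive(n_imf, "n_imf")
  check_positive(base_width, "base_width")
  check_ptosis(ptosis_grade)
  warn_plausibility(sn_n, n_imf, base_width)
  out <- tibble::tibble(
    pt_sn_n = as.integer(sn_n >= cutoffs$sn_n_min),
    pt_n_imf = as.integer(n_imf >= cutoffs$n_imf_min),
    pt_bw = as.integer(base_width >= cutoffs$bw_min),
    pt_ptosis = as.integer(ptosis_grade == cutoffs$ptosis_qualifying_grade)
  )
  out$anatomical_points <- out$pt_sn_n + out$pt_n_imf + out$pt_bw + out$pt_ptosis
  out
}

# plausibility bounds are the observed cohort ranges; violations warn, never
# error (screening for unit mix-ups, not hard constraints)
warn_plausibility <- function(sn_n, n_imf, base_width) {
  msgs <- character()
  if (any(sn_n < 22.5 | sn_n > 40)) {
    msgs <- c(msgs, "sn_n outside the plausible 22.5-40 cm range")
  }
  if (any(n_imf < 9 | n_imf > 22)) {
    msgs <- c(msgs, "n_imf outside the plausible 9-22 cm range")
  }
  if (any(base_width < 12 | base_width > 24)) {
    msgs <- c(msgs, "base_width outside the plausible 12-24 cm range")
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(NULL)
}

#' Select the index breast for each patient
#'
#' Scoring is per patient, not per breast. For bilateral patients the index
#' breast is the one with the heavier resection weight: the heavier breast
#' represents the patient's true burden, and averaging would underestimate it
#' in asymmetric patients. Unilateral patients contribute their single
#' breast. Equal resection weights are broken deterministically in favour of
#' the left breast.
#'
#' @param cohort a cohort tibble in the standard schema (see [read_cohort()]):
#'   one row per patient with `l_`/`r_`-prefixed measurement columns.
#' @return A tibble with one row per patient: `patient_id`, `index_side`,
#'   and the index breast's `sn_n`, `n_imf`, `bw`, `ptosis`, `resection_g`.
#' @export
select_index_breast <- function(cohort) {
  check_cohort(cohort)
  meas_cols <- c("sn_n", "n_imf", "bw", "ptosis", "resection_g")
  l <- cohort[paste0("l_", meas_cols)]
  r <- cohort[paste0("r_", meas_cols)]
  names(l) <- names(r) <- meas_cols
  has_l <- rowSums(!is.na(l)) > 0
  has_r <- rowSums(!is.na(r)) > 0
  if (any(!has_l & !has_r)) {
    stop(sprintf("patients with no breast measurements: %s",
                 paste(cohort$patient_id[!has_l & !has_r], collapse = ", ")),
         call. = FALSE)
  }
  bilateral <- has_l & has_r
  missing_w <- bilateral & (is.na(l$resection_g) | is.na(r$resection_g))
  if (any(missing_w)) {
    stop(sprintf("bilateral patients missing a resection weight (needed to pick the index breast): %s",
                 paste(cohort$patient_id[missing_w], collapse = ", ")),
         call. = FALSE)
  }
  # tie (equal weights) goes to the left breast
  take_left <- has_l & (!has_r | (bilateral & l$resection_g >= r$resection_g))
  out <- l
  out[!take_left, ] <- r[!take_left, ]
  tibble::tibble(
    patient_id = cohort$patient_id,
    index_side = ifelse(take_left, "left", "right"),
    out
  )
}

#' Score a cohort on the ABB rubric
#'
#' Computes the 0-6 ABB score for every patient: anatomical points from the
#' index breast (see [select_index_breast()]) plus the symptom and
#' physical-finding points. With `assume_symptom`/`assume_finding` enabled
#' (the default, mirroring the model's use on functional-reduction cohorts
#' where at least one symptom and one finding are assumed present), a patient
#' with unknown status receives the point; an explicit `FALSE` flag always
#' overrides the assumption. With the assumption disabled, unknown status is
#' a hard error because the patient cannot be scored.
#'
#' @param cohort a cohort tibble (see [read_cohort()]).
#' @param cutoffs an [abb_cutoffs()] object.
#' @param assume_symptom,assume_finding treat unknown symptom / physical
#'   finding status as present (default `TRUE`).
#' @return A tibble with one row per patient: index-breast measurements, the
#'   per-criterion breakdown, `anatomical_points`, `symptom_point`,
#'   `finding_point`, `abb_score`, and `category` (`"mild"` for scores 0-2,
#'   `"moderate_to_severe"` for 3-6).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 1))
#' abb_score(cohort)
#' @export
abb_score <- function(cohort, cutoffs = abb_cutoffs(),
                      assume_symptom = TRUE, assume_finding = TRUE) {
  idx <- select_index_breast(cohort)
  pts <- anatomical_points(idx$sn_n, idx$n_imf, idx$bw, idx$ptosis, cutoffs)
  symptom_point <- domain_point(cohort$has_symptom, assume_symptom,
                                cutoffs$symptom_points, "symptom",
                                cohort$patient_id)
  finding_point <- domain_point(cohort$has_finding, assume_finding,
                                cutoffs$finding_points, "physical finding",
                                cohort$patient_id)
  score <- pts$anatomical_points + symptom_point + finding_point
  tibble::tibble(
    idx, pts,
    symptom_point = symptom_point,
    finding_point = finding_point,
    abb_score = score,
    category = ifelse(score <= 2, "mild", "moderate_to_severe")
  )
}

domain_point <- function(flag, assume, weight, label, ids) {
  unknown <- is.na(flag)
  if (any(unknown) && !assume) {
    stop(sprintf("unknown %s status for %s and assumption disabled: cannot score",
                 label, paste(ids[unknown], collapse = ", ")), call. = FALSE)
  }
  as.integer(flag | (unknown & assume)) * weight
}
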