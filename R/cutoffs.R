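#' Group-mean scan over integer cutoff candidates
#'
#' Reproduces the cutoff-determination scan used to build the ABB rubric: for
#' every integer candidate value of a metric (SN-N, N-IMF, or base width),
#' the cohort is partitioned into below (`value < candidate`) and above
#' (`value >= candidate`) groups on the index breast, and the mean resection
#' weight and mean ptosis grade are computed in each group. Candidates run
#' from `floor(min) + 1` to `ceiling(max)` of the observed metric. Empty
#' groups get `NA` means and are flagged in `below_defined`/`above_defined`.
#'
#' @param cohort a cohort tibble (see [read_cohort()]); every index breast
#'   needs the metric, a ptosis grade and a resection weight.
#' @param metric which measurement to scan.
#' @return A tibble with one row per candidate: counts, group means of
#'   resection weight (g) and ptosis grade, and defined-group flags.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 30, seed = 1))
#' cutoff_scan(cohort, "n_imf")
#' @export
cutoff_scan <- function(cohort, metric = c("sn_n", "n_imf", "base_width")) {
  metric <- match.arg(metric)
  idx <- select_index_breast(cohort)
  col <- if (metric == "base_width") "bw" else metric
  x <- idx[[col]]
  need <- list(x, idx$ptosis, idx$resection_g)
  names(need) <- c(metric, "ptosis", "resection_g")
  for (nm in names(need)) {
    if (anyNA(need[[nm]])) {
      stop(sprintf("index breast missing `%s` for: %s", nm,
                   paste(idx$patient_id[is.na(need[[nm]])], collapse = ", ")),
           call. = FALSE)
    }
  }
  candidates <- seq(floor(min(x)) + 1, ceiling(max(x)))
  rows <- lapply(candidates, function(cand) {
    below <- x < cand
    tibble::tibble(
      metric = metric,
      candidate = cand,
      n_below = sum(below),
      n_above = sum(!below),
      mean_weight_below = if (any(below)) mean(idx$resection_g[below]) else NA_real_,
      mean_weight_above = if (any(!below)) mean(idx$resection_g[!below]) else NA_real_,
      mean_ptosis_below = if (any(below)) mean(idx$ptosis[below]) else NA_real_,
      mean_ptosis_above = if (any(!below)) mean(idx$ptosis[!below]) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$below_defined <- out$n_below > 0
  out$above_defined <- out$n_above > 0
  out
}

#' Select an anatomical cutoff from a scan
#'
#' Formalizes the published selection logic as a smallest-candidate rule.
#' Default rule (`weight_ptosis_transition`): the smallest candidate whose
#' below-group mean resection weight is under the 500 g landmark, whose
#' above-group mean is at or over it, and whose above-group mean ptosis has
#' reached the moderate-to-severe band (>= `ptosis_low`). With
#' `sn_n_leniency`, the landmark is reduced (default 350 g): SN-N doubles as
#' a ptosis surrogate and severe ptosis already carries its own point, so a
#' stricter SN-N cutoff would double-count nipple descent. When several
#' candidates satisfy the rule the smallest wins. If none does, a structured
#' no-transition result is returned rather than a silent default.
#'
#' @param scan output of [cutoff_scan()].
#' @param weight_landmark resection-weight transition landmark, g.
#' @param ptosis_low,ptosis_high the ptosis transition band (moderate-to-severe
#'   ~2.5 to severe ~3.0); the above-group mean must reach `ptosis_low`.
#' @param sn_n_leniency apply the lenient reduced-landmark rule.
#' @param lenient_landmark the reduced landmark used under leniency, g.
#' @return An object of class `abb_cutoff_selection`: `metric`,
#'   `selected_cutoff` (`NA` when no transition exists), `rule_applied`,
#'   the full `scan`, and a `rationale` string.
#' @export
select_cutoff <- function(scan, weight_landmark = 500,
                          ptosis_low = 2.5, ptosis_high = 3.0,
                          sn_n_leniency = FALSE, lenient_landmark = 350) {
  stopifnot(is.data.frame(scan),
            all(c("candidate", "mean_weight_below", "mean_weight_above",
                  "mean_ptosis_above", "below_defined", "above_defined")
                %in% names(scan)))
  usable <- scan$below_defined & scan$above_defined
  if (sum(usable) < 2) {
    stop("scan needs at least 2 candidates with both groups nonempty",
         call. = FALSE)
  }
  landmark <- if (sn_n_leniency) lenient_landmark else weight_landmark
  rule <- if (sn_n_leniency) "lenient_sn_n" else "weight_ptosis_transition"
  ok <- usable &
    scan$mean_weight_below < landmark &
    scan$mean_weight_above >= landmark &
    scan$mean_ptosis_above >= ptosis_low
  metric <- scan$metric[1]
  if (!any(ok)) {
    return(structure(
      list(metric = metric, selected_cutoff = NA_real_,
           rule_applied = "no_transition", scan = scan,
           rationale = sprintf(
             "no candidate for %s crosses the %g g landmark with above-group mean ptosis >= %g",
             metric, landmark, ptosis_low)),
      class = "abb_cutoff_selection"))
  }
  sel <- min(scan$candidate[ok])
  row <- scan[scan$candidate == sel, ]
  structure(
    list(metric = metric, selected_cutoff = sel, rule_applied = rule,
         scan = scan,
         rationale = sprintf(
           paste0("%s cutoff %g cm: mean resection weight %0.0f g below vs ",
                  "%0.0f g above crosses the %g g landmark; above-group mean ",
                  "ptosis %0.2f is in the %g-%g transition band (rule: %s, ",
                  "smallest qualifying candidate)"),
           metric, sel, row$mean_weight_below, row$mean_weight_above,
           landmark, row$mean_ptosis_above, ptosis_low, ptosis_high, rule)),
    class = "abb_cutoff_selection")
}

#' @export
print.abb_cutoff_selection <- function(x, ...) {
  if (is.na(x$selected_cutoff)) {
    cat(sprintf("No transition found for %s\n  %s\n", x$metric, x$rationale))
  } else {
    cat(sprintf("Selected cutoff for %s: %g cm\n  %s\n",
                x$metric, x$selected_cutoff, x$rationale))
  }
  invisible(x)
}
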