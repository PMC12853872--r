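cohort_columns <- c(
  "patient_id", "age", "height_m", "weight_kg",
  "l_sn_n", "l_n_imf", "l_bw", "l_ptosis", "l_resection_g",
  "r_sn_n", "r_n_imf", "r_bw", "r_ptosis", "r_resection_g",
  "has_symptom", "has_finding"
)

check_cohort <- function(cohort) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing) > 0) {
    stop(sprintf("cohort is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient_id values in cohort", call. = FALSE)
  }
  invisible(cohort)
}

parse_ptosis <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  # surgeons sometimes chart an in-between "2-3"; interpolate to 2.5
  x[!is.na(x) & x == "2-3"] <- "2.5"
  suppressWarnings(as.numeric(x))
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a cohort CSV
#'
#' Reads the standard cohort schema (one row per patient; columns
#' `patient_id, age, height_m, weight_kg`, side-prefixed measurement columns
#' `l_sn_n, l_n_imf, l_bw, l_ptosis, l_resection_g` and the `r_*`
#' counterparts, and `has_symptom`/`has_finding`). Textual ptosis "2-3" is
#' parsed to the interpolated 2.5; blank symptom/finding cells become unknown
#' (`NA`). Rows failing validation (nonpositive height/weight, nonpositive
#' lengths or resection weights, unknown ptosis codes, no breast present) are
#' rejected, reported via message, and returned in the `validation`
#' attribute; accepted + rejected always equals the input row count. A height
#' that looks like centimetres entered as metres draws a warning.
#'
#' @param path CSV path.
#' @return A cohort tibble with attribute `validation` (a tibble of rejected
#'   rows and reasons).
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  if (nrow(raw) == 0) stop("empty cohort file: ", path, call. = FALSE)
  missing <- setdiff(cohort_columns, names(raw))
  extra <- setdiff(names(raw), cohort_columns)
  if (length(missing) > 0 || length(extra) > 0) {
    stop(sprintf("cohort schema mismatch in %s\n  missing: %s\n  unexpected: %s",
                 path,
                 if (length(missing)) paste(missing, collapse = ", ") else "(none)",
                 if (length(extra)) paste(extra, collapse = ", ") else "(none)"),
         call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(trimws(x) == "", NA, x)))
  out <- tibble::tibble(
    patient_id = raw$patient_id,
    age = num(raw$age),
    height_m = num(raw$height_m),
    weight_kg = num(raw$weight_kg),
    l_sn_n = num(raw$l_sn_n), l_n_imf = num(raw$l_n_imf),
    l_bw = num(raw$l_bw), l_ptosis = parse_ptosis(raw$l_ptosis),
    l_resection_g = num(raw$l_resection_g),
    r_sn_n = num(raw$r_sn_n), r_n_imf = num(raw$r_n_imf),
    r_bw = num(raw$r_bw), r_ptosis = parse_ptosis(raw$r_ptosis),
    r_resection_g = num(raw$r_resection_g),
    has_symptom = parse_flag(raw$has_symptom),
    has_finding = parse_flag(raw$has_finding)
  )
  if (any(out$height_m > 3, na.rm = TRUE)) {
    warning("height_m > 3 m: heights look like centimetres entered as metres",
            call. = FALSE)
  }
  reasons <- vapply(seq_len(nrow(out)), function(i) row_problem(out[i, ]),
                    character(1))
  bad <- reasons != ""
  validation <- tibble::tibble(row = which(bad),
                               patient_id = out$patient_id[bad],
                               reason = reasons[bad])
  if (any(bad)) {
    message(sprintf("read_cohort: accepted %d row(s), rejected %d row(s)",
                    sum(!bad), sum(bad)))
  }
  out <- out[!bad, ]
  check_cohort(out)
  attr(out, "validation") <- validation
  out
}

row_problem <- function(r) {
  probs <- character()
  if (is.na(r$height_m) || r$height_m <= 0) probs <- c(probs, "nonpositive or missing height")
  if (is.na(r$weight_kg) || r$weight_kg <= 0) probs <- c(probs, "nonpositive or missing weight")
  for (side in c("l", "r")) {
    cols <- paste0(side, c("_sn_n", "_n_imf", "_bw", "_resection_g"))
    v <- unlist(r[cols])
    if (any(!is.na(v) & v <= 0)) probs <- c(probs, sprintf("nonpositive %s-side measurement", side))
    pt <- r[[paste0(side, "_ptosis")]]
    if (!is.na(pt) && !(pt %in% ptosis_levels)) {
      probs <- c(probs, sprintf("unknown %s-side ptosis grade", side))
    }
  }
  has_l <- any(!is.na(unlist(r[paste0("l_", c("sn_n", "n_imf", "bw", "ptosis", "resection_g"))])))
  has_r <- any(!is.na(unlist(r[paste0("r_", c("sn_n", "n_imf", "bw", "ptosis", "resection_g"))])))
  if (!has_l && !has_r) probs <- c(probs, "no breast measurements")
  paste(probs, collapse = "; ")
}

#' Write a cohort CSV
#'
#' Serializes a cohort tibble to the standard schema with blank cells for
#' missing values; [read_cohort()] of the written file round-trips to the
#' same records. Output is byte-deterministic for identical input.
#'
#' @param cohort a cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(as.data.frame(cohort)[cohort_columns], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Read rubric cutoffs from a YAML config
#'
#' Loads a flat key-value YAML mirroring the [abb_cutoffs()] fields; absent
#' keys keep their defaults.
#'
#' @param path YAML path.
#' @return An [abb_cutoffs()] object.
#' @export
read_rubric_config <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("rubric config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(abb_cutoffs))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown rubric config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(abb_cutoffs, cfg)
}

report_stage <- function(status, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    status[[name]] <<- conditionMessage(e)
    NULL
  })
  if (is.null(status[[name]])) status[[name]] <- "ok"
  list(status = status, value = res)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Scores the cohort, assesses Schnur eligibility, and writes the standard
#' bundle to `output_dir`: `scored_cohort.csv`, `schnur_assessment.csv`,
#' `concordance.json`, `correlations.csv`, `strata_by_score.csv`,
#' `strata_by_cell.csv`, and a plain-text `summary.txt`. Every artifact is
#' stamped (in `summary.txt`) with a hash of the configuration and the seed.
#' A failing stage is recorded as failed in the summary while earlier outputs
#' are preserved.
#'
#' @param cohort a cohort tibble.
#' @param output_dir directory for the bundle (created if needed).
#' @param cutoffs an [abb_cutoffs()] object.
#' @param table a [schnur_table()].
#' @param policy Schnur grid policy.
#' @param assume_symptom,assume_finding see [abb_score()]; these add two
#'   points to every unknown-status patient and are echoed prominently in the
#'   summary.
#' @param seed seed to stamp into the report (informational; the pipeline
#'   itself is deterministic).
#' @return Invisibly, a list with the per-stage status, the analyzed tibble,
#'   and the output paths.
#' @export
run_report <- function(cohort, output_dir, cutoffs = abb_cutoffs(),
                       table = schnur_table(), policy = "nearest",
                       assume_symptom = TRUE, assume_finding = TRUE,
                       seed = NA_integer_) {
  check_cohort(cohort)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(cutoffs = unclass(cutoffs), policy = policy,
              assume_symptom = assume_symptom, assume_finding = assume_finding,
              table = as.data.frame(table))
  tf <- tempfile(fileext = ".txt")
  writeLines(deparse(cfg), tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  status <- list()
  paths <- list()

  analyzed <- NULL
  st <- report_stage(status, "analyze", {
    analyze_cohort(cohort, cutoffs, table, policy, assume_symptom, assume_finding)
  })
  status <- st$status
  analyzed <- st$value

  if (!is.null(analyzed)) {
    paths$scored <- file.path(output_dir, "scored_cohort.csv")
    write.csv(as.data.frame(analyzed), paths$scored, row.names = FALSE, na = "")

    st <- report_stage(status, "concordance", concordance(analyzed))
    status <- st$status
    conc <- st$value
    if (!is.null(conc)) {
      paths$concordance <- file.path(output_dir, "concordance.json")
      jsonlite::write_json(unclass(conc), paths$concordance,
                           auto_unbox = TRUE, digits = NA, na = "null")
    }

    st <- report_stage(status, "correlations", {
      dplyr::bind_rows(spearman_panel(analyzed, "abb_score"),
                       spearman_panel(analyzed, "schnur_threshold"))
    })
    status <- st$status
    if (!is.null(st$value)) {
      paths$correlations <- file.path(output_dir, "correlations.csv")
      write.csv(as.data.frame(st$value), paths$correlations,
                row.names = FALSE, na = "")
    }

    for (scheme in c("by_score", "by_category_x_eligibility")) {
      nm <- if (scheme == "by_score") "strata_by_score" else "strata_by_cell"
      st <- report_stage(status, nm, stratify(analyzed, scheme))
      status <- st$status
      if (!is.null(st$value)) {
        paths[[nm]] <- file.path(output_dir, paste0(nm, ".csv"))
        write.csv(as.data.frame(st$value), paths[[nm]], row.names = FALSE, na = "")
      }
    }

    st <- report_stage(status, "schnur_csv", {
      assess_schnur(cohort, table, policy)
    })
    status <- st$status
    if (!is.null(st$value)) {
      paths$schnur <- file.path(output_dir, "schnur_assessment.csv")
      write.csv(as.data.frame(st$value), paths$schnur, row.names = FALSE, na = "")
    }
  }

  paths$summary <- file.path(output_dir, "summary.txt")
  lines <- c(
    "abburden report",
    sprintf("config_hash: %s", cfg_hash),
    sprintf("seed: %s", seed),
    sprintf("n_patients: %d", nrow(cohort)),
    sprintf("assume_symptom: %s  assume_finding: %s (each unknown-status patient gains the domain point)",
            assume_symptom, assume_finding),
    "stages:",
    sprintf("  %s: %s", names(status), unlist(status))
  )
  if (!is.null(analyzed)) {
    conc <- tryCatch(concordance(analyzed), error = function(e) NULL)
    if (!is.null(conc)) {
      lines <- c(lines,
                 sprintf("concordance: TP %d FN %d FP %d TN %d", conc$tp,
                         conc$fn, conc$fp, conc$tn),
                 sprintf("sensitivity: %s  specificity: %s",
                         if (is.na(conc$sensitivity)) "undefined" else
                           sprintf("%.1f%%", conc$sensitivity_pct),
                         if (is.na(conc$specificity)) "undefined" else
                           sprintf("%.1f%%", conc$specificity_pct)))
    }
  }
  writeLines(lines, paths$summary)
  invisible(list(status = status, analyzed = analyzed, paths = paths))
}
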