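latent_vars <- c("age", "height_m", "weight_kg", "sn_n", "n_imf", "bw", "severity")

default_latent_correlation <- function() {
  r <- diag(7)
  dimnames(r) <- list(latent_vars, latent_vars)
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_r("height_m", "weight_kg", 0.30)
  set_r("age", "sn_n", 0.20)
  set_r("age", "n_imf", 0.10)
  set_r("age", "bw", 0.10)
  set_r("age", "severity", 0.15)
  set_r("height_m", "sn_n", 0.10)
  set_r("height_m", "n_imf", 0.10)
  set_r("height_m", "bw", 0.10)
  set_r("weight_kg", "sn_n", 0.45)
  set_r("weight_kg", "n_imf", 0.40)
  set_r("weight_kg", "bw", 0.45)
  set_r("weight_kg", "severity", 0.25)
  set_r("sn_n", "n_imf", 0.50)
  set_r("sn_n", "bw", 0.50)
  set_r("n_imf", "bw", 0.50)
  set_r("sn_n", "severity", 0.60)
  set_r("n_imf", "severity", 0.40)
  set_r("bw", "severity", 0.40)
  r
}

default_marginals <- function() {
  list(
    age = c(mean = 48.8, sd = 15.9, min = 16, max = 86),
    height_m = c(mean = 1.63, sd = 0.07, min = 1.47, max = 1.78),
    weight_kg = c(mean = 75.1, sd = 11.4, min = 53.3, max = 118.8),
    sn_n = c(mean = 30.5, sd = 4.04, min = 22.5, max = 40),
    n_imf = c(mean = 13.8, sd = 2.58, min = 9, max = 22),
    bw = c(mean = 15.7, sd = 2.32, min = 12, max = 24)
  )
}

#' Specification for a synthetic reduction-mammaplasty cohort
#'
#' Bundles every knob of the synthetic-cohort generator: sample size, seed,
#' per-variable marginal targets (mean, sd, min, max) for the demographics
#' and breast measurements, ptosis category probabilities, the latent
#' correlation matrix of the Gaussian copula, the resection-weight model, and
#' bilateral-asymmetry noise. Defaults emulate a therapeutic-reduction cohort
#' of 84 patients with the published marginal summaries (e.g. SN-N
#' 30.5 +/- 4.04 cm on 22.5-40, resection weight around 452 +/- 211 g per
#' breast, 57% severe ptosis).
#'
#' @param n cohort size (default 84).
#' @param seed integer seed; the generator is deterministic given the spec.
#' @param marginals named list of `c(mean, sd, min, max)` targets for `age`,
#'   `height_m`, `weight_kg`, `sn_n`, `n_imf`, `bw`.
#' @param ptosis_probs named probabilities over Regnault grades.
#' @param latent_correlation symmetric positive-definite 7x7 matrix over
#'   (age, height, weight, SN-N, N-IMF, BW, ptosis severity latent).
#' @param weight_model resection-weight model: linear in the four anatomical
#'   inputs plus Gaussian noise, floored at `floor_g` (see the package
#'   vignette for the calibration to the 452/211 g cohort moments).
#' @param asymmetry sd of per-breast deviations from the patient-level value,
#'   cm for lengths and g for weights.
#' @param prop_unilateral expected fraction of unilateral reductions.
#' @return An object of class `abb_cohort_spec`.
#' @export
cohort_spec <- function(n = 84, seed = 1,
                        marginals = default_marginals(),
                        ptosis_probs = c(`1` = 0.02, `2` = 0.31,
                                         `2.5` = 0.10, `3` = 0.57),
                        latent_correlation = default_latent_correlation(),
                        weight_model = list(type = "linear",
                                            intercept = -932.5,
                                            sn_n = 12, n_imf = 30, bw = 25,
                                            ptosis = 80, noise_sd = 123,
                                            floor_g = 50),
                        asymmetry = list(length_sd_cm = 0.3, weight_sd_g = 40),
                        prop_unilateral = 0.05) {
  stopifnot(n >= 1, length(seed) == 1, is.finite(seed))
  if (!setequal(names(marginals), names(default_marginals()))) {
    stop("marginals must be given for exactly: ",
         paste(names(default_marginals()), collapse = ", "), call. = FALSE)
  }
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (m["sd"] < 0) stop("marginal sd must be >= 0", call. = FALSE)
    if (m["min"] >= m["max"]) {
      stop(sprintf("infeasible truncation for `%s`: min >= max", nm),
           call. = FALSE)
    }
  }
  check_ptosis(as.numeric(names(ptosis_probs)), "ptosis_probs levels")
  if (abs(sum(ptosis_probs) - 1) > 1e-8 || any(ptosis_probs < 0)) {
    stop("ptosis_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  r <- latent_correlation
  if (!isSymmetric(unname(r)) || any(eigen(r, symmetric = TRUE,
                                           only.values = TRUE)$values <= 1e-10)) {
    stop("latent_correlation must be symmetric positive-definite", call. = FALSE)
  }
  if (prop_unilateral < 0 || prop_unilateral > 1) {
    stop("prop_unilateral must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marginals,
         ptosis_probs = ptosis_probs, latent_correlation = r,
         weight_model = weight_model, asymmetry = asymmetry,
         prop_unilateral = prop_unilateral),
    class = "abb_cohort_spec")
}

#' Plant a recoverable cutoff into a cohort spec
#'
#' Replaces the resection-weight model with a step model: patients below the
#' planted cutoff `k` on the chosen metric have expected weight
#' `base_weight`, patients at or above it `base_weight + gap`. With the
#' defaults (350 + 200 g) the group expectations straddle the 500 g landmark
#' by construction, so [select_cutoff()] on a generated cohort should recover
#' `k` up to sampling noise; this is the test harness for the derivation
#' procedure.
#'
#' @param base a [cohort_spec()].
#' @param metric metric carrying the planted transition.
#' @param k planted cutoff, cm; must lie inside the metric's truncation range.
#' @param base_weight expected weight below the cutoff, g.
#' @param gap expected weight increase at the cutoff, g; a warning is issued
#'   when the plant cannot cross the 500 g landmark or the gap is small
#'   relative to the noise (recovery not guaranteed).
#' @param noise_sd Gaussian noise sd around the step, g.
#' @return A modified `abb_cohort_spec`.
#' @export
planted_cutoff_spec <- function(base, metric = c("sn_n", "n_imf", "base_width"),
                                k, base_weight = 350, gap = 200,
                                noise_sd = 50) {
  stopifnot(inherits(base, "abb_cohort_spec"))
  metric <- match.arg(metric)
  key <- if (metric == "base_width") "bw" else metric
  m <- base$marginals[[key]]
  if (k <= m["min"] || k >= m["max"]) {
    stop(sprintf("planted cutoff k = %g outside the %s range (%g, %g)",
                 k, metric, m["min"], m["max"]), call. = FALSE)
  }
  if (base_weight + gap < 500) {
    warning("planted step never reaches the 500 g landmark; the default selection rule cannot recover it",
            call. = FALSE)
  } else if (gap < 4 * noise_sd) {
    warning("planted gap is small relative to the noise sd; recovery is not guaranteed",
            call. = FALSE)
  }
  base$weight_model <- list(type = "planted", metric = key, k = k,
                            base_weight = base_weight, gap = gap,
                            noise_sd = noise_sd, floor_g = 50)
  # the derivation scans the index (heavier) breast, and the maximum of two
  # noisy per-breast weights sits above the patient-level expectation; zero
  # the weight asymmetry so the step expectations hold for the scanned value
  base$asymmetry$weight_sd_g <- 0
  base
}

draw_ptosis <- function(u, probs) {
  lv <- as.numeric(names(probs))
  cum <- cumsum(probs)
  idx <- 1 + rowSums(outer(u, cum[-length(cum)], ">"))
  lv[idx]
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: a Gaussian copula with the spec's
#' latent correlation supplies correlated uniforms, each continuous variable
#' is transformed to a truncated normal whose underlying parameters are
#' moment-matched so the truncated mean and sd hit the marginal targets, and
#' the ptosis grade is cut from a latent severity score (so ptosis co-varies
#' positively with the measurements) at the exact category probabilities.
#' Per-breast values are the patient-level value plus asymmetry noise;
#' resection weight follows the spec's weight model, floored at a positive
#' minimum; symptom and finding flags are set `TRUE`, mirroring a
#' functional-reduction cohort. Deterministic given the spec (the RNG state
#' is saved and restored around the draw).
#'
#' @param spec a [cohort_spec()].
#' @return A cohort tibble in the standard schema (see [read_cohort()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 84, seed = 42))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "abb_cohort_spec"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  n <- spec$n
  z <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = spec$latent_correlation)
  if (n == 1) z <- matrix(z, nrow = 1)
  colnames(z) <- latent_vars
  u <- pnorm(z)

  vals <- lapply(names(spec$marginals), function(nm) {
    m <- spec$marginals[[nm]]
    tn_quantile(u[, nm], tn_solve(m["mean"], m["sd"], m["min"], m["max"]))
  })
  names(vals) <- names(spec$marginals)
  ptosis <- draw_ptosis(u[, "severity"], spec$ptosis_probs)

  wm <- spec$weight_model
  w_patient <- if (identical(wm$type, "planted")) {
    wm$base_weight + wm$gap * (vals[[wm$metric]] >= wm$k) +
      rnorm(n, 0, wm$noise_sd)
  } else {
    wm$intercept + wm$sn_n * vals$sn_n + wm$n_imf * vals$n_imf +
      wm$bw * vals$bw + wm$ptosis * ptosis + rnorm(n, 0, wm$noise_sd)
  }

  unilateral <- runif(n) < spec$prop_unilateral
  uni_side <- sample(c("left", "right"), n, replace = TRUE)
  lsd <- spec$asymmetry$length_sd_cm
  wsd <- spec$asymmetry$weight_sd_g
  clamp <- function(x, nm) {
    m <- spec$marginals[[nm]]
    pmin(pmax(x, m["min"]), m["max"])
  }
  side_vals <- function() {
    list(sn_n = clamp(vals$sn_n + rnorm(n, 0, lsd), "sn_n"),
         n_imf = clamp(vals$n_imf + rnorm(n, 0, lsd), "n_imf"),
         bw = clamp(vals$bw + rnorm(n, 0, lsd), "bw"),
         ptosis = ptosis,
         resection_g = pmax(w_patient + rnorm(n, 0, wsd), wm$floor_g))
  }
  left <- side_vals()
  right <- side_vals()
  blank_l <- unilateral & uni_side == "right"
  blank_r <- unilateral & uni_side == "left"
  for (f in names(left)) {
    left[[f]][blank_l] <- NA
    right[[f]][blank_r] <- NA
  }

  out <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = vals$age, height_m = vals$height_m, weight_kg = vals$weight_kg,
    l_sn_n = left$sn_n, l_n_imf = left$n_imf, l_bw = left$bw,
    l_ptosis = left$ptosis, l_resection_g = left$resection_g,
    r_sn_n = right$sn_n, r_n_imf = right$n_imf, r_bw = right$bw,
    r_ptosis = right$ptosis, r_resection_g = right$resection_g,
    has_symptom = TRUE, has_finding = TRUE
  )
  bmi <- out$weight_kg / out$height_m^2
  if (mean(bmi < 16 | bmi > 45) > 0.02) {
    warning("generated BMI distribution strays well outside the 18.8-40.4 reference range",
            call. = FALSE)
  }
  attr(out, "spec") <- spec
  out
}
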