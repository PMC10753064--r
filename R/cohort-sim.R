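#' Default clinical-scale definitions
#'
#' Admissible ranges, abnormality cut-offs and cut-off directions for the
#' seven scales: Montreal Cognitive Assessment (MoCA, cognition, abnormal
#' below 26), Fatigue Severity Scale (FSS), Pittsburgh Sleep Quality Index
#' (PSQI), Patient Health Questionnaire-9 (PHQ-9), Generalized Anxiety
#' Disorder-7 (GAD-7), Hamilton Depression Scale (HAMD) and Hamilton
#' Anxiety Scale (HAMA); all but MoCA flag high scores, inclusively
#' (score >= cut-off).
#'
#' @return A tibble with one row per scale: `scale`, `lo`, `hi`,
#'   `cutoff`, `direction` ("below" strict or "above" inclusive).
#' @export
clinical_scales <- function() {
  tibble::tribble(
    ~scale,  ~lo, ~hi, ~cutoff, ~direction,
    "moca",    0,  30,      26,    "below",
    "fss",     9,  63,      36,    "above",
    "psqi",    0,  21,       8,    "above",
    "phq9",    0,  27,      10,    "above",
    "gad7",    0,  21,      10,    "above",
    "hamd",    0,  52,      17,    "above",
    "hama",    0,  56,      14,    "above"
  )
}

#' Cohort simulation parameters
#'
#' Defines the generative model of a simulated patient/control cohort:
#' per-subgroup bivariate Gaussian left/right ALPS indices, a control
#' Gaussian per side, a Gaussian age distribution with a (non-positive)
#' patient ALPS-vs-age slope, and per-scale truncated-Gaussian clinical
#' scores calibrated so the expected fraction beyond each scale's cut-off
#' matches a target. Defaults reproduce the study conditions of a
#' 61-patient / 38-control post-COVID cohort: subgroup 1 (n = 37) with
#' left 1.66 +/- 0.13 and right 1.44 +/- 0.18, subgroup 2 (n = 24) with
#' left 1.39 +/- 0.20 and right 1.60 +/- 0.23, controls 1.66 +/- 0.15
#' left and 1.63 +/- 0.15 right, patient age 43.7 +/- 13.5 years
#' (controls 42.9 +/- 7.9), and the printed score means/SDs and
#' abnormality fractions (e.g. 11/61 MoCA below 26).
#'
#' @param n_patients,n_controls Cohort sizes.
#' @param subgroups List of subgroup definitions, each with `n`,
#'   `left` = c(mean, sd), `right` = c(mean, sd); `n`s must sum to
#'   `n_patients`.
#' @param controls List with `left`, `right` c(mean, sd) pairs.
#' @param age List with `patient` and `control` c(mean, sd) pairs (years).
#' @param alps_age_slope Index units per year added to patient ALPS as
#'   `slope * (age - mean age)`; must be <= 0 (older patients have lower
#'   indices).
#' @param scores Tibble with one row per scale: `scale`, `mean`, `sd`,
#'   `target` (fraction beyond the cut-off); ranges/cut-offs joined from
#'   [clinical_scales()].
#' @param sex_prob_male Named vector, probability of male sex per cohort.
#' @param days Named list of c(mean, sd) for `infection_to_scan`,
#'   `symptom_resolution_to_scan`, `course` (days, truncated at 0).
#' @param education c(mean, sd) of patient education years (controls NA).
#' @param seed Integer seed.
#' @return An object of class `alps_cohort_params`.
#' @export
cohort_sim_params <- function(
    n_patients = 61L, n_controls = 38L,
    subgroups = list(
      sg1 = list(n = 37L, left = c(1.66, 0.13), right = c(1.44, 0.18)),
      sg2 = list(n = 24L, left = c(1.39, 0.20), right = c(1.60, 0.23))),
    controls = list(left = c(1.66, 0.15), right = c(1.63, 0.15)),
    age = list(patient = c(43.7, 13.5), control = c(42.9, 7.9)),
    alps_age_slope = -0.005,
    scores = tibble::tribble(
      ~scale,  ~mean, ~sd,  ~target,
      "moca",   27.3, 2.3,  11 / 61,
      "fss",    26.3, 16.6, 19 / 61,
      "psqi",    4.4, 3.9,  13 / 61,
      "phq9",    4.7, 4.8,   7 / 61,
      "gad7",    2.8, 4.1,   4 / 61,
      "hamd",    6.0, 6.5,   4 / 61,
      "hama",    4.9, 5.4,   8 / 61),
    sex_prob_male = c(patient = 29 / 61, control = 17 / 38),
    days = list(infection_to_scan = c(80.8, 31.3),
                symptom_resolution_to_scan = c(71.5, 33.7),
                course = c(9.3, 7.6)),
    education = c(11.9, 5.9),
    seed = 1L) {
  if (sum(vapply(subgroups, `[[`, 0L, "n")) != n_patients) {
    stop("subgroup sizes must sum to n_patients")
  }
  sds <- c(vapply(subgroups, function(s) c(s$left[2], s$right[2]),
                  numeric(2)),
           controls$left[2], controls$right[2], scores$sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (alps_age_slope > 0) stop("alps_age_slope must be <= 0")
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 subgroups = subgroups, controls = controls, age = age,
                 alps_age_slope = alps_age_slope, scores = scores,
                 sex_prob_male = sex_prob_male, days = days,
                 education = education, seed = as.integer(seed)),
            class = "alps_cohort_params")
}

# Truncated-normal helpers ---------------------------------------------------

# P(X beyond cut-off) for X ~ N(mu, sigma) truncated to [lo, hi]. At
# extreme mu the window mass underflows; return the limiting 0/1 so root
# brackets stay well defined.
trunc_exceedance <- function(mu, sigma, lo, hi, cutoff, direction) {
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  if (b - a <= 0) {
    hi_side <- mu > (lo + hi) / 2
    return(if (direction == "below") as.numeric(!hi_side)
           else as.numeric(hi_side))
  }
  p_c <- stats::pnorm((cutoff - mu) / sigma)
  if (direction == "below") (p_c - a) / (b - a) else (b - p_c) / (b - a)
}

trunc_mean <- function(mu, sigma, lo, hi) {
  al <- (lo - mu) / sigma
  be <- (hi - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  if (z <= 0) return(if (mu > (lo + hi) / 2) hi else lo)
  mu + sigma * (stats::dnorm(al) - stats::dnorm(be)) / z
}

# Solve for the latent location mu so a truncated N(mu, sigma) on [lo, hi]
# puts exactly `target` expected mass beyond the cut-off. sigma stays at the
# printed SD: the truncated-Gaussian family cannot in general match mean,
# SD and tail fraction at once on skewed scales, and the exceedance
# expectation is the calibrated quantity. Exceedance is monotone in mu, so
# a root exists for any target in (0, 1) with the cut-off inside the range.
calibrate_trunc_normal <- function(sigma, lo, hi, cutoff, direction,
                                   target) {
  if (target <= 0 || target >= 1) {
    stop("calibration error: exceedance target must be in (0, 1)")
  }
  if (cutoff <= lo || cutoff >= hi) {
    stop("calibration error: cut-off ", cutoff, " outside the admissible ",
         "range (", lo, ", ", hi, "), target unreachable")
  }
  f <- function(mu) trunc_exceedance(mu, sigma, lo, hi, cutoff,
                                     direction) - target
  span <- 20 * sigma + (hi - lo)
  root <- tryCatch(
    stats::uniroot(f, c(lo - span, hi + span), tol = 1e-12),
    error = function(e) stop("calibration error: exceedance ",
                             signif(target, 3), " unreachable within [",
                             lo, ", ", hi, "] for cut-off ", cutoff))
  list(mu = root$root, sigma = sigma)
}

rtrunc_normal <- function(n, mu, sigma, lo, hi) {
  if (sigma == 0) return(rep(mu, n))
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  u <- stats::runif(n, a, b)
  mu + sigma * stats::qnorm(u)
}

#' Simulate a patient/control cohort
#'
#' Draws one row per subject. Patients are assigned to subgroups in the
#' stated sizes; each subject's left/right ALPS pair is drawn from its
#' subgroup (or control) Gaussian; ages are drawn from the cohort age
#' Gaussian (truncated at 18) and patient ALPS values are then shifted by
#' `slope * (age - mean age)`, producing the negative age association.
#' Patient clinical scores are drawn from truncated Gaussians calibrated
#' (see [cohort_sim_params()]) so the expected abnormality fraction per
#' scale matches its target; control scores are absent, mirroring a study
#' design where controls were not scored. Deterministic given the seed.
#'
#' @param params An [cohort_sim_params()] object.
#' @return A tibble (class `alps_cohort` prepended) with columns `id`,
#'   `cohort`, `subgroup`, `age`, `sex`, `education`,
#'   `days_infection_to_scan`, `days_symptom_resolution_to_scan`,
#'   `course_days`, the seven scale scores, `alps_left`, `alps_right`,
#'   `alps_diff`.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(seed = 7))
#' dplyr::count(cohort, cohort, subgroup)
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "alps_cohort_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  scales <- dplyr::left_join(params$scores, clinical_scales(), by = "scale")
  np <- params$n_patients
  nc <- params$n_controls

  subgroup_lab <- rep(names(params$subgroups),
                      vapply(params$subgroups, `[[`, 0L, "n"))
  draw <- function(n, ms) stats::rnorm(n, ms[1], ms[2])

  age_p <- rtrunc_normal(np, params$age$patient[1], params$age$patient[2],
                         18, 95)
  age_c <- rtrunc_normal(nc, params$age$control[1], params$age$control[2],
                         18, 95)

  left_p <- right_p <- numeric(np)
  for (sg in names(params$subgroups)) {
    idx <- which(subgroup_lab == sg)
    left_p[idx] <- draw(length(idx), params$subgroups[[sg]]$left)
    right_p[idx] <- draw(length(idx), params$subgroups[[sg]]$right)
  }
  shift <- params$alps_age_slope * (age_p - params$age$patient[1])
  left_p <- left_p + shift
  right_p <- right_p + shift

  left_c <- draw(nc, params$controls$left)
  right_c <- draw(nc, params$controls$right)

  score_cols <- purrr::map(seq_len(nrow(scales)), function(i) {
    row <- scales[i, ]
    if (row$sd == 0) return(rep(row$mean, np))
    cal <- calibrate_trunc_normal(row$sd, row$lo, row$hi,
                                  row$cutoff, row$direction, row$target)
    rtrunc_normal(np, cal$mu, cal$sigma, row$lo, row$hi)
  })
  names(score_cols) <- scales$scale

  sex_p <- ifelse(stats::runif(np) < params$sex_prob_male["patient"],
                  "male", "female")
  sex_c <- ifelse(stats::runif(nc) < params$sex_prob_male["control"],
                  "male", "female")
  pos_days <- function(n, ms) {
    if (ms[2] == 0) rep(ms[1], n) else rtrunc_normal(n, ms[1], ms[2], 0, Inf)
  }

  patients <- tibble::tibble(
    id = sprintf("P%03d", seq_len(np)),
    cohort = "patient",
    subgroup = subgroup_lab,
    age = age_p, sex = sex_p,
    education = if (params$education[2] == 0) rep(params$education[1], np)
                else rtrunc_normal(np, params$education[1],
                                   params$education[2], 0, 30),
    days_infection_to_scan = pos_days(np, params$days$infection_to_scan),
    days_symptom_resolution_to_scan =
      pos_days(np, params$days$symptom_resolution_to_scan),
    course_days = pos_days(np, params$days$course),
    !!!score_cols,
    alps_left = left_p, alps_right = right_p,
    alps_diff = left_p - right_p
  )
  controls <- tibble::tibble(
    id = sprintf("C%03d", seq_len(nc)),
    cohort = "control",
    subgroup = NA_character_,
    age = age_c, sex = sex_c,
    education = NA_real_,
    days_infection_to_scan = NA_real_,
    days_symptom_resolution_to_scan = NA_real_,
    course_days = NA_real_,
    !!!stats::setNames(rep(list(rep(NA_real_, nc)), nrow(scales)),
                       scales$scale),
    alps_left = left_c, alps_right = right_c,
    alps_diff = left_c - right_c
  )
  out <- dplyr::bind_rows(patients, controls)
  class(out) <- c("alps_cohort", class(out))
  out
}

#' Write / read a cohort table as CSV
#'
#' One header row, comma-separated, UTF-8, "." decimal separator.
#'
#' @param cohort A cohort tibble.
#' @param path CSV path.
#' @return `write_cohort_csv()` the path invisibly; `read_cohort_csv()` a
#'   tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           fileEncoding = "UTF-8"))
  class(out) <- c("alps_cohort", class(out))
  out
}
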