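fmt_mean_sd <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("NA")
  paste0(formatC(mean(x), format = "f", digits = digits), " ± ",
         formatC(stats::sd(x), format = "f", digits = digits))
}

fmt_n_pct <- function(count, n) {
  paste0(count, " (", formatC(100 * count / n, format = "f", digits = 1),
         ")")
}

#' Format a p-value for report tables
#'
#' Three decimals, printing `< 0.001` below that.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "< 0.001", formatC(p, format = "f", digits = 3)))
}

#' Demographics and clinical-characteristics table
#'
#' Builds the cohort-description table: continuous variables as
#' `mean +/- SD` per cohort with a patient-vs-control p-value where both
#' cohorts carry the variable, sex as `N (%)` with a chi-square p, and
#' threshold-abnormality flags as `N (%)` among patients. Cells a cohort
#' does not have (e.g. control clinical scores) print `NA`.
#'
#' @param cohort A cohort tibble.
#' @param policy Two-sample test policy for continuous contrasts.
#' @return A tibble with `characteristic`, `patients`, `controls`, `p`.
#' @examples
#' make_table1(simulate_cohort(cohort_sim_params(seed = 1)))
#' @export
make_table1 <- function(cohort, policy = "auto") {
  pat <- cohort[cohort$cohort == "patient", ]
  ctl <- cohort[cohort$cohort == "control", ]
  if (nrow(ctl) == 0) {
    warning("empty control group: patient column only")
  }
  contrasts <- cohort_contrasts(cohort, policy = policy)
  p_of <- function(v) {
    p <- contrasts$p_value[contrasts$variable == v]
    if (length(p) == 0) NA_real_ else p
  }
  both <- function(v) sum(!is.na(pat[[v]])) > 0 && sum(!is.na(ctl[[v]])) > 0
  cont_row <- function(v, label, digits = 1) {
    tibble::tibble(
      characteristic = label,
      patients = fmt_mean_sd(pat[[v]], digits),
      controls = fmt_mean_sd(ctl[[v]], digits),
      p = if (both(v)) fmt_p(p_of(v)) else "NA")
  }
  rows <- list(
    cont_row("age", "Age, years"),
    tibble::tibble(
      characteristic = "Male, N (%)",
      patients = fmt_n_pct(sum(pat$sex == "male"), nrow(pat)),
      controls = if (nrow(ctl) > 0)
        fmt_n_pct(sum(ctl$sex == "male"), nrow(ctl)) else "NA",
      p = fmt_p(p_of("sex"))),
    cont_row("education", "Education, years"),
    cont_row("days_infection_to_scan", "Infection time to scan, days"),
    cont_row("days_symptom_resolution_to_scan",
             "Respiratory symptoms disappear to scan, days"),
    cont_row("course_days", "Course of disease, days"),
    cont_row("moca", "Montreal Cognitive Assessment score"),
    cont_row("fss", "Fatigue Severity Scale score"),
    cont_row("psqi", "Pittsburgh Sleep Quality Index"),
    cont_row("phq9", "Patient Health Questionnaire-9 score"),
    cont_row("gad7", "Generalized Anxiety Disorder-7 score"),
    cont_row("hamd", "Hamilton Depression Scale"),
    cont_row("hama", "Hamilton Anxiety Scale"),
    cont_row("alps_left", "Left DTI-ALPS", 2),
    cont_row("alps_right", "Right DTI-ALPS", 2)
  )
  flags <- flag_thresholds(pat)
  flag_rows <- purrr::pmap_dfr(flags, function(scale, n, count, pct) {
    tibble::tibble(
      characteristic = paste0("Abnormal ", toupper(scale), ", N (%)"),
      patients = fmt_n_pct(count, n), controls = "NA", p = "NA")
  })
  dplyr::bind_rows(dplyr::bind_rows(rows), flag_rows)
}

#' Subgroup contrast and standardized-regression tables
#'
#' `make_table2_3()` produces the two report tables of a subgroup
#' analysis: (2) per-subgroup `mean +/- SD` of ALPS indices, demographics
#' and clinical scores with between-subgroup p-values, and (3) per
#' clinical outcome, the standardized coefficients of the left and right
#' ALPS indices as joint covariates, fitted within each subgroup.
#' Regression is skipped (with a logged reason) for any subgroup with too
#' few subjects.
#'
#' @param solution An `alps_cluster_solution` with a selected k.
#' @param cohort The cohort the solution was built from.
#' @return A list with `table2` (tibble), `table3` (tibble: subgroup,
#'   outcome, term, beta, p), and `skipped` (character log of skipped
#'   regressions).
#' @export
make_table2_3 <- function(solution, cohort) {
  rep <- subgroup_report(solution, cohort)
  sgs <- rep$sizes$subgroup
  tb2 <- rep$summary
  digits <- ifelse(grepl("^alps", tb2$variable), 2, 1)
  for (s in sgs) {
    m <- tb2[[paste0(s, "_mean")]]
    sd_ <- tb2[[paste0(s, "_sd")]]
    tb2[[s]] <- vapply(seq_along(m), function(i) {
      paste0(formatC(m[i], format = "f", digits = digits[i]), " ± ",
             formatC(sd_[i], format = "f", digits = digits[i]))
    }, character(1))
  }
  tb2$p <- fmt_p(tb2$p_value)

  pats <- assign_subgroups(cohort, solution)
  pats <- pats[pats$cohort == "patient", ]
  outcomes <- clinical_scales()$scale[clinical_scales()$scale %in%
                                        names(pats)]
  skipped <- character(0)
  tb3 <- purrr::map_dfr(sgs, function(s) {
    sub <- pats[pats$subgroup == s, ]
    purrr::map_dfr(outcomes, function(out) {
      ok <- stats::complete.cases(sub[, c(out, "alps_left", "alps_right")])
      sub_ok <- sub[ok, ]
      if (nrow(sub_ok) <= 3) {
        skipped <<- c(skipped, paste0(s, "/", out, ": n = ", nrow(sub_ok),
                                      " too small for 2-covariate regression"))
        return(NULL)
      }
      fit <- tryCatch(
        standardized_regression(
          sub_ok[[out]],
          cbind(left_alps = sub_ok$alps_left,
                right_alps = sub_ok$alps_right)),
        error = function(e) {
          skipped <<- c(skipped, paste0(s, "/", out, ": ",
                                        conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) return(NULL)
      dplyr::bind_cols(tibble::tibble(subgroup = s, outcome = out), fit)
    })
  })
  list(table2 = tb2, table3 = tb3, skipped = skipped)
}

#' Default pipeline configuration
#'
#' Assembles the full run configuration with the study-condition
#' defaults: a 33-volume 32-direction b = 1000 acquisition, the
#' ALPS-plane phantom, phantom-matched 3x3 ROIs, WLS tensor fitting, the
#' default cohort generator, the auto test policy, and Ward clustering
#' over k = 2..6 on the (left, left - right) feature pair.
#'
#' @param stages Stages to run, in order, from `phantom`, `fit`, `alps`,
#'   `cohort`, `stats`, `cluster`, `report`.
#' @param phantom An `alps_phantom_spec` (default [alps_plane_phantom()]).
#' @param n_directions,b,n_b0 Acquisition scheme.
#' @param rois An `alps_roi_set` or `NULL` to derive from the phantom.
#' @param fit_method `"wls"` or `"ols"`.
#' @param cohort_params An [cohort_sim_params()] object.
#' @param stats_policy Two-sample policy.
#' @param linkage,kmin,kmax,feature_mode,scale_features Clustering
#'   options.
#' @param seed Master seed (propagated to every stochastic stage).
#' @param out_dir Output directory.
#' @return A `RunConfig`-style named list of class `alps_run_config`.
#' @export
pipeline_config <- function(stages = c("phantom", "fit", "alps", "cohort",
                                       "stats", "cluster", "report"),
                            phantom = alps_plane_phantom(),
                            n_directions = 32L, b = 1000, n_b0 = 1L,
                            rois = NULL, fit_method = "wls",
                            cohort_params = NULL, stats_policy = "auto",
                            linkage = "ward", kmin = 2L, kmax = 6L,
                            feature_mode = "left+diff",
                            scale_features = FALSE,
                            seed = 1L, out_dir = tempfile("alps_run_")) {
  if (is.null(cohort_params)) cohort_params <- cohort_sim_params(seed = seed)
  structure(list(stages = stages, phantom = phantom,
                 n_directions = n_directions, b = b, n_b0 = n_b0,
                 rois = rois, fit_method = fit_method,
                 cohort_params = cohort_params, stats_policy = stats_policy,
                 linkage = linkage, kmin = kmin, kmax = kmax,
                 feature_mode = feature_mode,
                 scale_features = scale_features,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "alps_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — phantom simulation, tensor
#' fit, ALPS computation, cohort simulation, cohort statistics,
#' subgrouping, report tables — writing every artifact (NIfTI phantom
#' with bval/bvec sidecars, cohort CSV carrying `alps_left`,
#' `alps_right`, `alps_diff` and `subgroup` columns, stats CSV, CH curve
#' CSV, Newick dendrogram, report tables) plus a machine-readable JSON
#' run log (config echo, seeds, package version, clamp counts) into the
#' configured output directory. A stage whose prerequisite stage is not
#' requested raises a dependency error naming the missing artifact.
#' Identical config and seeds reproduce byte-identical outputs.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list of in-memory results (`phantom_alps`,
#'   `cohort`, `stats`, `solution`, `tables`, paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "alps_run_config"))
  st <- config$stages
  need <- function(stage, dep, artifact) {
    if (stage %in% st && !dep %in% st) {
      stop("dependency error: stage '", stage, "' requires '", dep,
           "' (missing artifact: ", artifact, ")")
    }
  }
  need("fit", "phantom", "simulated DWI volume")
  need("alps", "fit", "fitted tensor field")
  need("stats", "cohort", "cohort table")
  need("cluster", "cohort", "cohort table")
  need("report", "cluster", "cluster solution")
  if ("alps" %in% st && is.null(config$rois) &&
      is.null(attr(config$phantom, "roi_centers"))) {
    stop("dependency error: alps stage requires an ROI set (missing ",
         "artifact: alps_roi_set)")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(out_dir = config$out_dir)
  log <- list(package = "alpsindex",
              version = as.character(utils::packageVersion("alpsindex")),
              seed = config$seed, stages = st,
              fit_method = config$fit_method,
              linkage = config$linkage, feature_mode = config$feature_mode,
              scale_features = config$scale_features)

  if ("phantom" %in% st) {
    gtab <- make_gradient_table(config$n_directions, config$b, config$n_b0,
                                seed = config$seed)
    sim <- simulate_dwi(config$phantom, gtab)
    write_dwi(sim$dwi, file.path(config$out_dir, "phantom"))
    out$sim <- sim
    log$phantom <- list(dim = config$phantom$dim, snr = config$phantom$snr,
                        n_directions = config$n_directions, b = config$b)
  }
  if ("fit" %in% st) {
    tf <- fit_tensor(out$sim$dwi, method = config$fit_method)
    out$tf <- tf
    log$fit <- list(method = tf$method, clamped = tf$clamped,
                    excluded = tf$excluded)
  }
  if ("alps" %in% st) {
    rois <- if (is.null(config$rois)) phantom_roi_set(config$phantom)
            else config$rois
    write_roi_set(rois, file.path(config$out_dir, "rois.txt"))
    res <- compute_alps(out$tf, rois)
    out$phantom_alps <- res
    utils::write.csv(as.data.frame(tidy(res)),
                     file.path(config$out_dir, "phantom_alps.csv"),
                     row.names = FALSE, quote = FALSE)
    log$phantom_alps <- list(left = res$left, right = res$right)
  }
  if ("cohort" %in% st) {
    out$cohort <- simulate_cohort(config$cohort_params)
    log$cohort <- list(n_patients = config$cohort_params$n_patients,
                       n_controls = config$cohort_params$n_controls,
                       seed = config$cohort_params$seed)
  }
  if ("stats" %in% st) {
    stats_tb <- cohort_contrasts(out$cohort, policy = config$stats_policy)
    flags <- flag_thresholds(out$cohort[out$cohort$cohort == "patient", ])
    out$stats <- stats_tb
    out$flags <- flags
    utils::write.csv(as.data.frame(stats_tb),
                     file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(flags),
                     file.path(config$out_dir, "threshold_flags.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if ("cluster" %in% st) {
    X <- build_features(out$cohort, mode = config$feature_mode,
                        scale_features = config$scale_features)
    sol <- select_k(X, linkage = config$linkage, kmin = config$kmin,
                    kmax = config$kmax)
    out$solution <- sol
    out$cohort <- assign_subgroups(out$cohort, sol)
    utils::write.csv(as.data.frame(sol$ch),
                     file.path(config$out_dir, "ch_curve.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(dendrogram_newick(sol),
               file.path(config$out_dir, "dendrogram.newick"))
    log$cluster <- list(selected_k = sol$selected_k,
                        sizes = as.integer(table(
                          sol$labels[, as.character(sol$selected_k)])))
  }
  if ("cohort" %in% st) {
    write_cohort_csv(out$cohort, file.path(config$out_dir, "cohort.csv"))
  }
  if ("report" %in% st) {
    out$table1 <- make_table1(out$cohort, policy = config$stats_policy)
    t23 <- make_table2_3(out$solution, out$cohort)
    out$table2 <- t23$table2
    out$table3 <- t23$table3
    utils::write.csv(as.data.frame(out$table1),
                     file.path(config$out_dir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(out$table2),
                     file.path(config$out_dir, "table2.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(out$table3),
                     file.path(config$out_dir, "table3.csv"),
                     row.names = FALSE)
    log$report <- list(skipped_regressions = t23$skipped)
  }
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Scatter plot of ALPS index against age
#'
#' @param cohort A cohort tibble.
#' @param side `"left"` or `"right"`.
#' @return A ggplot with per-cohort linear trends.
#' @export
plot_alps_age <- function(cohort, side = c("left", "right")) {
  side <- match.arg(side)
  col <- paste0("alps_", side)
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$age, y = .data[[col]],
                               color = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "age (years)",
                  y = paste(side, "DTI-ALPS index")) +
    ggplot2::theme_minimal()
}

#' Box plot of ALPS indices by group
#'
#' @param cohort A cohort tibble.
#' @param by Grouping column, `"cohort"` or `"subgroup"`.
#' @return A ggplot of left/right index distributions per group.
#' @export
plot_alps_by_group <- function(cohort, by = c("cohort", "subgroup")) {
  by <- match.arg(by)
  long <- tidyr::pivot_longer(cohort, c("alps_left", "alps_right"),
                              names_to = "side", values_to = "alps")
  long <- long[!is.na(long[[by]]), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$alps,
                                     fill = .data$side)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "DTI-ALPS index") +
    ggplot2::theme_minimal()
}
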