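#' Build the clustering feature matrix
#'
#' The primary feature pair for data-driven patient subgrouping is the
#' left ALPS index together with the left-minus-right difference, which
#' separates subjects by which hemisphere's glymphatic function declined.
#' Alternative modes mirror sensitivity analyses with the left index
#' alone or the raw left/right pair.
#'
#' @param cohort A cohort tibble; only `cohort == "patient"` rows are
#'   used when a `cohort` column is present.
#' @param mode `"left+diff"` (default), `"left-only"` or `"left+right"`.
#' @param scale_features z-score the columns before clustering (default
#'   `FALSE`: both features are already in index units).
#' @return A numeric matrix with subject ids as row names.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(seed = 1))
#' head(build_features(cohort))
#' @export
build_features <- function(cohort,
                           mode = c("left+diff", "left-only", "left+right"),
                           scale_features = FALSE) {
  mode <- match.arg(mode)
  if ("cohort" %in% names(cohort)) {
    cohort <- cohort[cohort$cohort == "patient", ]
  }
  need <- if (mode == "left-only") "alps_left" else c("alps_left",
                                                      "alps_right")
  missing_ids <- cohort$id[!stats::complete.cases(cohort[, need])]
  if (length(missing_ids) > 0) {
    stop("incomplete record: missing ALPS values for ",
         paste(missing_ids, collapse = ", "))
  }
  X <- switch(mode,
    "left+diff" = cbind(alps_left = cohort$alps_left,
                        alps_diff = cohort$alps_left - cohort$alps_right),
    "left-only" = cbind(alps_left = cohort$alps_left),
    "left+right" = cbind(alps_left = cohort$alps_left,
                         alps_right = cohort$alps_right))
  rownames(X) <- if ("id" %in% names(cohort)) cohort$id else
    as.character(seq_len(nrow(X)))
  if (scale_features) X <- scale(X)
  X
}

#' Agglomerative hierarchical clustering over a range of k
#'
#' Euclidean distances, agglomerative merge tree (Ward by default —
#' variance-minimizing, consistent with the sums-of-squares objective of
#' the Calinski-Harabasz criterion), labels from cutting the tree at each
#' candidate k. Deterministic given input order; equal-distance merges
#' follow the stable lowest-index order of [stats::hclust()].
#'
#' @param X Numeric feature matrix (subjects in rows).
#' @param linkage `"ward"` (ward.D2 on unsquared Euclidean distances),
#'   `"average"` or `"complete"`.
#' @param kmin,kmax Candidate range of cluster counts (2 <= kmin <= kmax
#'   <= n).
#' @return An object of class `alps_cluster_solution` with the merge tree
#'   (`hclust`), `labels` (matrix, one column per k), and (until
#'   [select_k()] fills them) empty `ch` and `selected_k`.
#' @export
hierarchical_cluster <- function(X, linkage = c("ward", "average",
                                                "complete"),
                                 kmin = 2L, kmax = 6L) {
  linkage <- match.arg(linkage)
  X <- as.matrix(X)
  n <- nrow(X)
  if (kmin < 2) stop("range error: kmin must be >= 2")
  if (n < kmax) stop("range error: need at least kmax subjects (n = ", n,
                     ", kmax = ", kmax, ")")
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  tree <- stats::hclust(stats::dist(X), method = method)
  ks <- kmin:kmax
  labels <- vapply(ks, function(k) stats::cutree(tree, k), integer(n))
  colnames(labels) <- as.character(ks)
  rownames(labels) <- rownames(X)
  structure(list(X = X, linkage = linkage, tree = tree,
                 kmin = kmin, kmax = kmax, labels = labels,
                 ch = NULL, selected_k = NA_integer_),
            class = "alps_cluster_solution")
}

#' Calinski-Harabasz pseudo-F
#'
#' `CH = [B / (k - 1)] / [W / (n - k)]` with between-cluster dispersion
#' `B = sum_j n_j ||centroid_j - grand mean||^2` and within-cluster
#' dispersion `W = sum_j sum_{i in j} ||x_i - centroid_j||^2`. Larger is
#' better; `W = 0` (all points coincide with their centroids) returns
#' `Inf`.
#'
#' @param X Numeric matrix, points in rows.
#' @param labels Cluster assignment per row (k >= 2 non-empty clusters,
#'   k < n).
#' @return The pseudo-F (scalar, possibly `Inf`).
#' @examples
#' calinski_harabasz(matrix(c(0, 1, 10, 11)), c(1, 1, 2, 2))  # 200
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2 || k >= n) {
    stop("invalid partition: need 2 <= k < n non-empty clusters")
  }
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (l in labs) {
    pts <- X[labels == l, , drop = FALSE]
    cen <- colMeans(pts)
    B <- B + nrow(pts) * sum((cen - grand)^2)
    W <- W + sum(sweep(pts, 2, cen)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of subgroups by the Calinski-Harabasz criterion
#'
#' Clusters, evaluates the pseudo-F at every tree cut in `[kmin, kmax]`
#' and selects the argmax (ties go to the smallest k). The full curve is
#' retained for inspection and plotting. If the best CH is barely above
#' the worst (flat curve), a low-confidence warning is raised: the data
#' may hold no real cluster structure.
#'
#' @inheritParams hierarchical_cluster
#' @return An `alps_cluster_solution` with `ch` (tibble of k and
#'   pseudo-F) and `selected_k` filled in, plus per-subgroup sizes.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(seed = 1))
#' sol <- select_k(build_features(cohort))
#' sol$selected_k
#' @export
select_k <- function(X, linkage = "ward", kmin = 2L, kmax = 6L) {
  sol <- hierarchical_cluster(X, linkage = linkage, kmin = kmin,
                              kmax = kmax)
  ks <- kmin:kmax
  ch <- vapply(seq_along(ks), function(i) {
    calinski_harabasz(sol$X, sol$labels[, i])
  }, numeric(1))
  sol$ch <- tibble::tibble(k = ks, ch = ch)
  sol$selected_k <- ks[which.max(ch)]   # which.max takes the first maximum
  if (all(is.finite(ch)) && max(ch) < 1.5 * min(ch)) {
    warning("low confidence: CH curve is nearly flat over the candidate ",
            "range; the data may hold no real cluster structure")
  }
  sol
}

#' @export
print.alps_cluster_solution <- function(x, ...) {
  cat("<alps_cluster_solution> n = ", nrow(x$X), ", linkage = ", x$linkage,
      ", k in [", x$kmin, ", ", x$kmax, "]", sep = "")
  if (!is.na(x$selected_k)) {
    sizes <- table(x$labels[, as.character(x$selected_k)])
    cat(", selected k = ", x$selected_k, " (sizes ",
        paste(sizes, collapse = "/"), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy methods for cluster solutions
#'
#' `tidy()` returns one row per subject with the label at the selected k
#' (or at every candidate k with `all_k = TRUE`); `glance()` returns a
#' one-row model summary.
#'
#' @param x An `alps_cluster_solution`.
#' @param all_k Return labels for every candidate k.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.alps_cluster_solution <- function(x, all_k = FALSE, ...) {
  base <- tibble::tibble(id = rownames(x$labels))
  if (all_k || is.na(x$selected_k)) {
    dplyr::bind_cols(base, tibble::as_tibble(x$labels,
                                             .name_repair = ~ paste0("k", .x)))
  } else {
    base$subgroup <- paste0("sg", x$labels[, as.character(x$selected_k)])
    base
  }
}

#' @rdname tidy.alps_cluster_solution
#' @exportS3Method generics::glance
glance.alps_cluster_solution <- function(x, ...) {
  tibble::tibble(n = nrow(x$X), linkage = x$linkage,
                 kmin = x$kmin, kmax = x$kmax,
                 selected_k = x$selected_k,
                 ch_max = if (is.null(x$ch)) NA_real_ else max(x$ch$ch))
}

#' Plot the Calinski-Harabasz curve
#'
#' @param object An `alps_cluster_solution` from [select_k()].
#' @param ... Unused.
#' @return A ggplot: pseudo-F against candidate k, selected k marked.
#' @exportS3Method ggplot2::autoplot
autoplot.alps_cluster_solution <- function(object, ...) {
  if (is.null(object$ch)) stop("run select_k() first")
  ggplot2::ggplot(object$ch, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "number of subgroups (k)",
                  y = "Calinski-Harabasz pseudo-F",
                  title = paste0("Cluster-number selection (chosen k = ",
                                 object$selected_k, ")")) +
    ggplot2::theme_minimal()
}

#' Attach subgroup labels to a cohort
#'
#' @param cohort A cohort tibble.
#' @param solution An `alps_cluster_solution` with a selected k.
#' @return The cohort with its patients' `subgroup` column replaced by
#'   the cluster labels (`sg1`, `sg2`, ...); controls keep `NA`.
#' @export
assign_subgroups <- function(cohort, solution) {
  lab <- tidy(solution)
  out <- cohort
  out$subgroup <- lab$subgroup[match(out$id, lab$id)]
  out
}

#' Per-subgroup summary table
#'
#' For each subgroup at the selected k: size, percentage of the patient
#' cohort, mean and SD of the ALPS indices and every clinical variable,
#' and (for the two-subgroup solution) between-subgroup p-values from
#' [two_sample_compare()] plus threshold-flag proportions.
#'
#' @param solution An `alps_cluster_solution` with a selected k.
#' @param cohort The cohort the solution was built from.
#' @param variables Continuous variables to summarize; default the ALPS
#'   indices, age and all scale scores present.
#' @return A list with `summary` (tibble: variable x subgroup mean/sd and
#'   p), `sizes` (tibble: subgroup, n, pct) and `flags` (per-subgroup
#'   [flag_thresholds()] output).
#' @export
subgroup_report <- function(solution, cohort, variables = NULL) {
  if (is.na(solution$selected_k)) stop("run select_k() first")
  cohort <- assign_subgroups(cohort, solution)
  pats <- cohort[cohort$cohort == "patient", ]
  if (is.null(variables)) {
    cand <- c("alps_left", "alps_right", "alps_diff", "age", "education",
              "days_infection_to_scan", "days_symptom_resolution_to_scan",
              "course_days", clinical_scales()$scale)
    variables <- cand[cand %in% names(pats)]
  }
  sgs <- sort(unique(pats$subgroup))
  sizes <- pats |>
    dplyr::count(.data$subgroup, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1))

  summary_tb <- purrr::map_dfr(variables, function(v) {
    row <- tibble::tibble(variable = v)
    vals_by <- lapply(sgs, function(s) {
      x <- pats[[v]][pats$subgroup == s]
      x[!is.na(x)]
    })
    for (i in seq_along(sgs)) {
      row[[paste0(sgs[i], "_mean")]] <- mean(vals_by[[i]])
      row[[paste0(sgs[i], "_sd")]] <- stats::sd(vals_by[[i]])
    }
    row$p_value <- if (length(sgs) == 2 &&
                       all(lengths(vals_by) >= 3) &&
                       any(vapply(vals_by, stats::sd, 0) > 0)) {
      two_sample_compare(vals_by[[1]], vals_by[[2]])$p_value
    } else NA_real_
    row
  })
  has_scales <- any(clinical_scales()$scale %in% names(pats))
  flags <- if (has_scales) {
    purrr::map(stats::setNames(sgs, sgs), function(s) {
      flag_thresholds(pats[pats$subgroup == s, ])
    })
  } else NULL
  list(summary = summary_tb, sizes = sizes, flags = flags)
}

#' Serialize a merge tree as Newick text
#'
#' Nested-parenthesis serialization of the dendrogram with merge heights
#' as branch lengths, readable by any phylogenetics tool.
#'
#' @param solution An `alps_cluster_solution`.
#' @return A single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(solution) {
  tree <- solution$tree
  lab <- tree$labels
  if (is.null(lab)) lab <- as.character(seq_len(nrow(solution$X)))
  node_str <- function(i, parent_h) {
    if (i < 0) {               # leaf, hclust convention: negative index
      paste0(lab[-i], ":", format(parent_h, digits = 10))
    } else {
      h <- tree$height[i]
      paste0("(", node_str(tree$merge[i, 1], h), ",",
             node_str(tree$merge[i, 2], h), "):",
             format(parent_h - h, digits = 10))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node_str(tree$merge[root, 1], h), ",",
         node_str(tree$merge[root, 2], h), ");")
}
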