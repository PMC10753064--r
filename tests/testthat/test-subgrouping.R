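two_cloud_cohort <- function(n1 = 37, n2 = 24, sep = 10, sd = 0.05,
                             seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n1 + n2)),
    cohort = "patient",
    alps_left = c(stats::rnorm(n1, 1.66, sd), stats::rnorm(n2, 1.66 - sep * sd, sd)),
    alps_right = c(stats::rnorm(n1, 1.44, sd), stats::rnorm(n2, 1.44 + sep * sd, sd))
  )
}

test_that("feature construction follows the requested mode", {
  co <- tibble::tibble(id = c("a", "b"), cohort = "patient",
                       alps_left = c(1.66, 1.39),
                       alps_right = c(1.44, 1.60))
  X <- build_features(co)
  expect_equal(unname(X[1, ]), c(1.66, 1.66 - 1.44))
  expect_equal(colnames(X), c("alps_left", "alps_diff"))
  expect_equal(ncol(build_features(co, mode = "left-only")), 1)
  same <- dplyr::mutate(co, alps_right = alps_left)
  expect_true(all(build_features(same)[, 2] == 0))
  incomplete <- dplyr::mutate(co, alps_right = c(NA, 1.6))
  expect_error(build_features(incomplete), "incomplete record.*a")
})

test_that("well-separated clouds are split exactly at k = 2", {
  co <- two_cloud_cohort(sep = 40)
  sol <- hierarchical_cluster(build_features(co))
  lab <- sol$labels[, "2"]
  expect_equal(length(unique(lab[1:37])), 1)
  expect_equal(length(unique(lab[38:61])), 1)
  expect_false(lab[1] == lab[61])
})

test_that("k = n yields singletons and small n errors on the range", {
  X <- matrix(stats::rnorm(12), 6, 2)
  sol <- hierarchical_cluster(X, kmin = 2, kmax = 6)
  expect_equal(sort(unique(sol$labels[, "6"])), 1:6)
  expect_error(hierarchical_cluster(X[1:4, ], kmax = 6), "range error")
  expect_error(hierarchical_cluster(X, kmin = 1), "range error")
})

test_that("1-D Ward clustering matches the brute-force optimum", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  sol <- hierarchical_cluster(X, linkage = "ward", kmin = 2, kmax = 3)
  lab <- sol$labels[, "2"]
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
})

test_that("the CH pseudo-F reproduces hand-computed sums of squares", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(X, c(1, 1, 2, 2)), 200)  # (100/1)/(1/2)
  expect_equal(calinski_harabasz(matrix(c(0, 0, 5, 5), ncol = 1),
                                 c(1, 1, 2, 2)), Inf)     # W = 0
  expect_error(calinski_harabasz(X, rep(1, 4)), "invalid partition")
})

test_that("true labels maximize CH over balanced relabelings", {
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(8, 0, 0.3), 4, 2),
             matrix(stats::rnorm(8, 8, 0.3), 4, 2))
  truth <- rep(1:2, each = 4)
  ch_true <- calinski_harabasz(X, truth)
  splits <- utils::combn(8, 4)
  for (j in seq_len(ncol(splits))) {
    lab <- rep(2, 8)
    lab[splits[, j]] <- 1
    if (!all(lab == truth) && !all(lab == 3 - truth)) {
      expect_lt(calinski_harabasz(X, lab), ch_true)
    }
  }
})

test_that("CH is translation-invariant and scale-invariant", {
  set.seed(12)
  X <- matrix(stats::rnorm(40), 20, 2)
  lab <- rep(1:2, 10)
  base <- calinski_harabasz(X, lab)
  expect_equal(calinski_harabasz(X + 100, lab), base, tolerance = 1e-10)
  expect_equal(calinski_harabasz(X * 3.7, lab), base, tolerance = 1e-10)
})

test_that("CH matches the total-minus-within oracle on random data", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    d <- sample(1:3, 1)
    X <- matrix(stats::rnorm(n * d), n, d)
    k <- sample(2:3, 1)
    lab <- sample(rep_len(seq_len(k), n))
    expect_equal(calinski_harabasz(X, lab), ch_oracle(X, lab),
                 tolerance = 1e-10)
  }
})

test_that("cluster labels are invariant to subject order", {
  skip_if_not_installed("mclust")
  co <- two_cloud_cohort(sep = 6, seed = 3)
  sol1 <- suppressWarnings(select_k(build_features(co)))
  perm <- sample(nrow(co))
  sol2 <- suppressWarnings(select_k(build_features(co[perm, ])))
  lab1 <- sol1$labels[, "2"]
  lab2 <- sol2$labels[, "2"][match(co$id, co$id[perm])]
  expect_equal(mclust::adjustedRandIndex(lab1, lab2), 1)
})

test_that("CH selection finds the generative number of clouds", {
  co <- two_cloud_cohort(sep = 10, seed = 2)
  expect_equal(select_k(build_features(co))$selected_k, 2)

  set.seed(14)
  centers <- cbind(seq(0, 50, by = 10), seq(0, 100, by = 20))
  X6 <- do.call(rbind, lapply(1:6, function(i) {
    cbind(stats::rnorm(8, centers[i, 1], 0.2),
          stats::rnorm(8, centers[i, 2], 0.2))
  }))
  expect_equal(select_k(X6)$selected_k, 6)

  set.seed(15)
  blob <- matrix(stats::rnorm(80), 40, 2)
  expect_warning(select_k(blob), "low confidence")
})

test_that("the subgroup report carries sizes, percentages and contrasts", {
  co <- two_cloud_cohort(sep = 40, seed = 4)
  sol <- select_k(build_features(co))
  rep <- subgroup_report(sol, co, variables = c("alps_left", "alps_right"))
  expect_equal(sort(rep$sizes$n), c(24, 37))
  expect_equal(sort(rep$sizes$pct), c(39.3, 60.7))
  expect_true(all(c("sg1_mean", "sg2_mean", "p_value") %in%
                    names(rep$summary)))
  expect_true(all(rep$summary$p_value < 0.05))
})

test_that("the dendrogram serializes to valid Newick", {
  co <- two_cloud_cohort(seed = 5)
  sol <- select_k(build_features(co))
  nwk <- dendrogram_newick(sol)
  expect_match(nwk, ";$")
  tree <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tree), 61)
  expect_setequal(tree$tip.label, co$id)
  # root-to-tip distance equals the final merge height for every tip
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  expect_equal(unname(depths), rep(max(sol$tree$height), 61),
               tolerance = 1e-8)
})
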