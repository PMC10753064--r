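roi_fixture <- function() {
  alps_roi_set(slice = 2,
               left = list(projection = c(15, 4), association = c(15, 10)),
               right = list(projection = c(6, 4), association = c(6, 10)))
}

test_that("ROI means are plain arithmetic means of the square", {
  const <- array(3.7, c(20, 14, 3))
  m <- roi_means(const, roi_fixture())
  expect_equal(m$mean, rep(3.7, 4))

  vals <- array(0, c(20, 14, 3))
  vals[14:16, 3:5, 2] <- matrix(1:9, 3, 3)   # 3x3 patch holding 1..9
  m2 <- roi_means(vals, roi_fixture())
  expect_equal(m2$mean[m2$hemisphere == "left" & m2$roi == "projection"], 5)
})

test_that("out-of-bounds and overlapping ROI placements error", {
  map <- array(1, c(20, 14, 3))
  bad <- alps_roi_set(slice = 2,
                      left = list(projection = c(1, 1),
                                  association = c(15, 10)),
                      right = list(projection = c(6, 4),
                                   association = c(6, 10)))
  expect_error(roi_means(map, bad), "placement error")
  overlap <- alps_roi_set(slice = 2,
                          left = list(projection = c(15, 4),
                                      association = c(15, 5)),
                          right = list(projection = c(6, 4),
                                       association = c(6, 10)))
  expect_error(roi_means(map, overlap), "overlap")
})

test_that("the ALPS ratio reproduces the printed index values", {
  expect_equal(alps_index(1.107e-3, 0.885e-3, 0.600e-3, 0.600e-3), 1.66,
               tolerance = 1e-12)
  expect_equal(alps_index(1.008e-3, 0.840e-3, 0.600e-3, 0.600e-3), 1.54,
               tolerance = 1e-12)
  expect_equal(alps_index(1e-3, 1e-3, 1e-3, 1e-3), 1)
  expect_error(alps_index(1e-3, -1e-3, 1e-3, 1e-3), "invalid diffusivity")
})

test_that("the ALPS index is scale-invariant and directionally monotone", {
  set.seed(4)
  for (i in 1:20) {
    d <- stats::runif(4, 0.3e-3, 1.6e-3)
    c_scale <- stats::runif(1, 0.1, 10)
    expect_equal(alps_index(d[1], d[2], d[3], d[4]),
                 alps_index(c_scale * d[1], c_scale * d[2],
                            c_scale * d[3], c_scale * d[4]),
                 tolerance = 1e-12)
    base <- alps_index(d[1], d[2], d[3], d[4])
    expect_gt(alps_index(d[1] * 1.01, d[2], d[3], d[4]), base)
    expect_gt(alps_index(d[1], d[2] * 1.01, d[3], d[4]), base)
    expect_lt(alps_index(d[1], d[2], d[3] * 1.01, d[4]), base)
    expect_lt(alps_index(d[1], d[2], d[3], d[4] * 1.01), base)
  }
})

test_that("the phantom pipeline reproduces the closed-form index end to end", {
  ph <- alps_plane_phantom()
  tf <- fit_tensor(simulate_dwi(ph, std_gtab())$dwi)
  res <- compute_alps(tf, phantom_roi_set(ph))
  expect_equal(res$left, mean(c(1.107, 0.885)) / mean(c(0.600, 0.600)),
               tolerance = 1e-9)
  expect_equal(res$diff, res$left - res$right)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("mirrored phantoms swap hemispheres and scaling leaves indices", {
  proj_r <- c(1.008e-3, 0.600e-3, 1.400e-3)
  assoc_r <- c(0.840e-3, 1.400e-3, 0.600e-3)
  ph <- alps_plane_phantom(proj_diag_right = proj_r,
                           assoc_diag_right = assoc_r)
  res <- compute_alps(fit_tensor(simulate_dwi(ph, std_gtab())$dwi),
                      phantom_roi_set(ph))
  mir <- alps_plane_phantom(proj_diag = proj_r, assoc_diag = assoc_r,
                            proj_diag_right = c(1.107e-3, 0.6e-3, 1.4e-3),
                            assoc_diag_right = c(0.885e-3, 1.4e-3, 0.6e-3))
  res_m <- compute_alps(fit_tensor(simulate_dwi(mir, std_gtab())$dwi),
                        phantom_roi_set(mir))
  expect_equal(res_m$left, res$right, tolerance = 1e-9)
  expect_equal(res_m$right, res$left, tolerance = 1e-9)
  expect_equal(res_m$diff, -res$diff, tolerance = 1e-9)

  dbl <- alps_plane_phantom(proj_diag = 2 * c(1.107e-3, 0.6e-3, 1.4e-3),
                            assoc_diag = 2 * c(0.885e-3, 1.4e-3, 0.6e-3))
  res_d <- compute_alps(fit_tensor(simulate_dwi(dbl, std_gtab())$dwi),
                        phantom_roi_set(dbl))
  ph0 <- alps_plane_phantom()
  res_0 <- compute_alps(fit_tensor(simulate_dwi(ph0, std_gtab())$dwi),
                        phantom_roi_set(ph0))
  expect_equal(res_d$left, res_0$left, tolerance = 1e-9)
})

test_that("ICC(3,1) has its analytic properties", {
  x <- c(9, 7.5, 8, 6, 10)
  expect_equal(icc_single_rater(cbind(x, x)), 1)
  expect_equal(icc_single_rater(cbind(x, x + 2.5)), 1)  # offset-invariant
  expect_lt(icc_single_rater(cbind(c(1, 2, 3), c(3, 2, 1))), 0)
  expect_error(icc_single_rater(cbind(1:5)), "incomplete design")
  expect_warning(icc_single_rater(matrix(c(1, 1, 1, 2, 2, 2), 3, 2)),
                 "degenerate")
})

test_that("ICC matches the two-way ANOVA oracle on random matrices", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(20), 10, 2)
    expect_equal(icc_single_rater(m), icc_aov_oracle(m), tolerance = 1e-10)
  }
})

test_that("jittered re-placement reliability behaves at its limits", {
  ph <- alps_plane_phantom()
  tf <- fit_tensor(simulate_dwi(ph, std_gtab())$dwi)
  rois <- phantom_roi_set(ph)
  expect_equal(roi_jitter_reliability(tf, rois, jitter = 0,
                                      n_repeats = 3)$icc, 1)
  # patches are 5x5 and ROIs 3x3: jitter 1 stays region-pure, values repeat
  rel <- roi_jitter_reliability(list(tf, tf, tf), rois, jitter = 1,
                                n_repeats = 2, seed = 2)
  expect_equal(rel$icc, 1)
})

test_that("jitter across heterogeneous phantoms yields an ICC in (0, 1]", {
  set.seed(8)
  gtab <- std_gtab()
  tfs <- lapply(1:20, function(i) {
    scale_i <- stats::runif(1, 0.8, 1.2)
    ph <- alps_plane_phantom(
      proj_diag = scale_i * c(1.107e-3, 0.6e-3, 1.4e-3),
      assoc_diag = c(0.885e-3, 1.4e-3, 0.6e-3),
      patch = 3)   # 3x3 patches: jitter 1 pushes ROIs into background
    fit_tensor(simulate_dwi(ph, gtab)$dwi)
  })
  rois <- phantom_roi_set(alps_plane_phantom(patch = 3))
  rel <- roi_jitter_reliability(tfs, rois, jitter = 1, n_repeats = 2,
                                seed = 5)
  expect_gt(rel$icc, 0)
  expect_lte(rel$icc, 1)
  expect_equal(rel$icc, icc_aov_oracle(rel$ratings), tolerance = 1e-10)
})

test_that("ROI sets round-trip through the text format", {
  rois <- roi_fixture()
  path <- file.path(withr::local_tempdir(), "rois.txt")
  write_roi_set(rois, path)
  expect_equal(read_roi_set(path), rois)
})
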