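# Shared fixtures: gradient tables, single-voxel phantoms, random tensors.

std_gtab <- function(seed = 1L) make_gradient_table(32L, 1000, 1L, seed = seed)

# Minimal hand-built 6-direction scheme (axes + face diagonals): rank-6
# design, lets closed-form signal values be read off single gradients.
axes_gtab <- function(b = 1000) {
  s <- 1 / sqrt(2)
  bvecs <- rbind(c(0, 0, 0),
                 c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(s, s, 0), c(s, 0, s), c(0, s, s))
  structure(list(bvals = c(0, rep(b, 6)), bvecs = bvecs),
            class = "alps_gradient_table")
}

# One-voxel phantom with a given tensor (diagonal vector or 3x3 matrix).
single_voxel_spec <- function(D, S0 = 1000, snr = Inf, seed = 1L) {
  phantom_spec(dim = c(1, 1, 1), background = D, S0 = S0, snr = snr,
               seed = seed)
}

# Random symmetric positive-definite tensor scaled to brain-like
# diffusivities (~1e-3 mm^2/s).
random_pd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  D <- crossprod(A) + diag(3) * 0.1
  D / max(abs(D)) * 1.5e-3
}

# Independent tensor oracle: solve the exact 6-unknown linear system
# adc = Q d from six gradients (no S0 unknown: uses the b=0 volume
# directly), brute-force via solve().
oracle_fit_single <- function(signal, gtab) {
  w <- which(gtab$bvals > 0)[1:6]
  S0 <- signal[which(gtab$bvals == 0)[1]]
  g <- gtab$bvecs[w, , drop = FALSE]
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  adc <- -log(signal[w] / S0) / gtab$bvals[w]
  d <- solve(Q, adc)
  matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
}

# Patient-only cohort table with exact flag counts per scale, used to
# check printed-proportion reproduction from counts alone.
cohort_with_counts <- function(n = 61, moca_low = 11, fss_high = 19,
                               psqi_high = 13) {
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    cohort = "patient",
    moca = c(rep(20, moca_low), rep(28, n - moca_low)),
    fss = c(rep(50, fss_high), rep(20, n - fss_high)),
    psqi = c(rep(10, psqi_high), rep(3, n - psqi_high))
  )
}

# ICC oracle via stats::aov two-way decomposition (independent of the
# direct sums-of-squares path in icc_single_rater).
icc_aov_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# Calinski-Harabasz oracle through the total/within decomposition
# (T = B + W), formulated independently of the implementation.
ch_oracle <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(unique(labels))
  total <- sum(sweep(X, 2, colMeans(X))^2)
  within <- sum(vapply(unique(labels), function(l) {
    pts <- X[labels == l, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
  ((total - within) / (k - 1)) / (within / (n - k))
}

# Exact Mann-Whitney two-sided p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled sample.
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
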