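#' Build a diffusion gradient table
#'
#' Constructs an acquisition scheme of `n_b0` unweighted volumes followed by
#' `n_directions` diffusion-weighted directions at a single shell `b`.
#' Directions are laid out by a spherical Fibonacci spiral, which spreads
#' points approximately uniformly over the sphere and keeps the tensor
#' design matrix well conditioned; a seeded random rotation is applied to
#' the whole set so distinct seeds give distinct (but equally well-spread)
#' schemes. The default mirrors a clinical single-shell protocol with 32
#' directions at b = 1000 s/mm^2.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6; six
#'   is the minimum to determine the six unique tensor components).
#' @param b b-value in s/mm^2 applied to every weighted direction.
#' @param n_b0 Number of b = 0 volumes (>= 1).
#' @param seed Integer seed for the global rotation; the same seed always
#'   yields the same table.
#' @return An object of class `alps_gradient_table`: a list with `bvals`
#'   (length `n_b0 + n_directions`) and `bvecs` (matrix, one row per
#'   volume, unit rows for weighted volumes, zero rows for b = 0).
#' @examples
#' gtab <- make_gradient_table(32, b = 1000, n_b0 = 1, seed = 1)
#' table(gtab$bvals)
#' @export
make_gradient_table <- function(n_directions, b = 1000, n_b0 = 1, seed = 1L) {
  if (n_directions < 6) {
    stop("invalid acquisition: need at least 6 diffusion directions to ",
         "determine the 6 unique tensor components, got ", n_directions)
  }
  if (n_b0 < 1) stop("invalid acquisition: need at least one b = 0 volume")
  if (b <= 0) stop("invalid acquisition: b must be positive (s/mm^2)")

  # the n = 6 Fibonacci spiral is a degenerate configuration for the
  # tensor design (rank 5); the classical icosahedral six-direction DTI
  # scheme is used at the minimum instead
  dirs <- if (n_directions == 6) {
    s <- 1 / sqrt(2)
    rbind(c(s, s, 0), c(s, -s, 0), c(s, 0, s),
          c(s, 0, -s), c(0, s, s), c(0, s, -s))
  } else {
    fibonacci_sphere(n_directions)
  }
  # seeded uniform rotation so the direction set is deterministic per seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dirs <- dirs %*% random_rotation()

  bvals <- c(rep(0, n_b0), rep(b, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  structure(list(bvals = bvals, bvecs = bvecs),
            class = "alps_gradient_table")
}

# Spherical Fibonacci point set: n approximately equidistributed unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(phi), r * sin(phi), z)
  m / sqrt(rowSums(m^2))
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.alps_gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat("<alps_gradient_table> ", length(x$bvals), " volumes: ",
      nb0, " b=0, ", length(x$bvals) - nb0, " weighted (b = ",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "),
      " s/mm^2)\n", sep = "")
  invisible(x)
}

#' Validate a gradient table
#'
#' Checks the invariants required for tensor fitting: unit-norm weighted
#' directions, at least one b = 0 volume, and at least six unique
#' non-collinear weighted directions.
#'
#' @param gtab An `alps_gradient_table`.
#' @param tol Norm tolerance for unit vectors.
#' @return `gtab`, invisibly; errors if invalid.
#' @export
validate_gradient_table <- function(gtab, tol = 1e-6) {
  stopifnot(inherits(gtab, "alps_gradient_table"))
  if (length(gtab$bvals) != nrow(gtab$bvecs)) {
    stop("invalid acquisition: bvals and bvecs lengths differ")
  }
  if (!any(gtab$bvals == 0)) {
    stop("invalid acquisition: no b = 0 volume")
  }
  w <- gtab$bvals > 0
  norms <- sqrt(rowSums(gtab$bvecs[w, , drop = FALSE]^2))
  if (any(abs(norms - 1) > tol)) {
    stop("invalid acquisition: weighted directions must be unit vectors")
  }
  # rank of the quadratic-form design determines tensor solvability
  g <- gtab$bvecs[w, , drop = FALSE]
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  if (qr(X)$rank < 6) {
    stop("invalid acquisition: directions do not span the 6 tensor ",
         "components (need >= 6 unique non-collinear directions)")
  }
  invisible(gtab)
}

#' Write / read FSL-style gradient files
#'
#' `write_bval_bvec()` writes whitespace-separated `.bval` (one row of
#' b-values) and `.bvec` (three rows, x/y/z components, one column per
#' volume) files; `read_bval_bvec()` reads them back.
#'
#' @param gtab An `alps_gradient_table`.
#' @param prefix Path prefix; `.bval`/`.bvec` are appended.
#' @return `write_bval_bvec()` the prefix invisibly; `read_bval_bvec()` an
#'   `alps_gradient_table`.
#' @export
write_bval_bvec <- function(gtab, prefix) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- t(gtab$bvecs)
  lines <- apply(bv, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(lines, paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvec_rows <- strsplit(trimws(readLines(paste0(prefix, ".bvec"))), "\\s+")
  # .bvec holds 3 rows (x, y, z) x N columns; assemble one row per volume
  bvecs <- vapply(bvec_rows, as.numeric, numeric(length(bvals)))
  structure(list(bvals = bvals, bvecs = bvecs),
            class = "alps_gradient_table")
}
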