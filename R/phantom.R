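#' Specify a DWI phantom
#'
#' A phantom is a voxel grid in which every voxel carries a known
#' ground-truth diffusion tensor, assigned by region. Regions model the
#' tissue classes at the ALPS plane: projection fibers (dominant diffusion
#' along z, the inferior-superior axis), association fibers (dominant
#' along y, anterior-posterior), and isotropic background. The simulated
#' magnitude signal follows the monoexponential tensor model
#' S = S0 exp(-b g' D g), optionally corrupted by Rician noise.
#'
#' @param dim Integer length-3 grid size in voxels (x, y, z).
#' @param voxel_size Numeric length-3 voxel edge length in mm.
#' @param regions Named list of regions. Each region is a list with
#'   `indices` (integer matrix, one voxel per row, 1-based x/y/z) and
#'   `tensor` (length-3 diagonal in mm^2/s, or a 3x3 symmetric matrix).
#'   Voxels not covered by any region take the `background` tensor.
#' @param background Tensor for uncovered voxels (default isotropic
#'   0.8e-3 mm^2/s, a typical white-matter mean diffusivity).
#' @param S0 Baseline (b = 0) signal, arbitrary units.
#' @param snr Signal-to-noise ratio S0 / sigma of each Gaussian quadrature
#'   channel; `Inf` means noise-free.
#' @param seed Integer seed used when `snr` is finite.
#' @return An object of class `alps_phantom_spec`.
#' @export
phantom_spec <- function(dim, voxel_size = c(1.8, 1.8, 2.5), regions = list(),
                         background = c(0.8e-3, 0.8e-3, 0.8e-3),
                         S0 = 1000, snr = Inf, seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 1), length(voxel_size) == 3)
  if (!(is.infinite(snr) || snr > 0)) {
    stop("invalid spec: SNR must be positive or infinite")
  }
  regions <- lapply(regions, function(r) {
    r$tensor <- as_tensor_matrix(r$tensor)
    check_positive_definite(r$tensor)
    r$indices <- as.matrix(r$indices)
    if (ncol(r$indices) != 3) stop("region indices must be n x 3 (x, y, z)")
    if (any(r$indices < 1) || any(t(r$indices) > dim)) {
      stop("invalid spec: region voxel indices outside the grid")
    }
    r
  })
  background <- as_tensor_matrix(background)
  check_positive_definite(background)
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 regions = regions, background = background,
                 S0 = S0, snr = snr, seed = as.integer(seed)),
            class = "alps_phantom_spec")
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3, 3)))
    if (max(abs(tensor - t(tensor))) > 1e-12) stop("tensor must be symmetric")
    tensor
  } else {
    stopifnot(length(tensor) == 3)
    diag(as.numeric(tensor))
  }
}

check_positive_definite <- function(tensor) {
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("invalid spec: ground-truth tensor is not positive-definite")
  }
  invisible(tensor)
}

# Per-voxel 3x3 tensor array (x, y, z, 3, 3) from a phantom spec.
phantom_tensor_array <- function(spec) {
  d <- spec$dim
  tens <- array(0, c(d, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    tens[, , , i, j] <- spec$background[i, j]
  }
  for (r in spec$regions) {
    for (v in seq_len(nrow(r$indices))) {
      ix <- r$indices[v, ]
      tens[ix[1], ix[2], ix[3], , ] <- r$tensor
    }
  }
  tens
}

#' Simulate a diffusion-weighted dataset from a phantom
#'
#' Evaluates the monoexponential tensor signal model per voxel and gradient,
#' `S = S0 exp(-b g' D g)`, then (for finite SNR) applies Rician
#' corruption `S' = sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, S0/snr)`,
#' the standard magnitude-MRI noise model. Returns the dataset together
#' with the ground-truth tensor field so downstream estimates can be
#' checked exactly.
#'
#' @param spec An [phantom_spec()] object.
#' @param gtab An [make_gradient_table()] gradient table.
#' @return A list with `dwi` (class `alps_dwi`: 4D signal array, affine,
#'   gradient table) and `truth` (class `alps_tensor_field`, the
#'   ground-truth field).
#' @examples
#' gtab <- make_gradient_table(32, 1000, 1, seed = 1)
#' ph <- alps_plane_phantom()
#' sim <- simulate_dwi(ph, gtab)
#' dim(sim$dwi$signal)
#' @export
simulate_dwi <- function(spec, gtab) {
  stopifnot(inherits(spec, "alps_phantom_spec"))
  validate_gradient_table(gtab)
  d <- spec$dim
  nvol <- length(gtab$bvals)
  tens <- phantom_tensor_array(spec)
  nvox <- prod(d)
  # flatten voxels x 6 unique components, compute quadratic form per gradient
  D6 <- cbind(as.vector(tens[, , , 1, 1]), as.vector(tens[, , , 2, 2]),
              as.vector(tens[, , , 3, 3]), as.vector(tens[, , , 1, 2]),
              as.vector(tens[, , , 1, 3]), as.vector(tens[, , , 2, 3]))
  g <- gtab$bvecs
  # quadratic form coefficients per volume: gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  adc <- D6 %*% t(Q)                                 # nvox x nvol
  S <- spec$S0 * exp(-sweep(adc, 2, gtab$bvals, `*`))
  if (is.finite(spec$snr)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    sigma <- spec$S0 / spec$snr
    e1 <- matrix(stats::rnorm(nvox * nvol, 0, sigma), nvox, nvol)
    e2 <- matrix(stats::rnorm(nvox * nvol, 0, sigma), nvox, nvol)
    S <- sqrt((S + e1)^2 + e2^2)
  }
  signal <- array(S, c(d, nvol))
  affine <- diag(c(spec$voxel_size, 1))
  dwi <- structure(list(signal = signal, affine = affine, gtab = gtab),
                   class = "alps_dwi")
  truth <- tensor_field_from_array(tens, mask = array(TRUE, d),
                                   affine = affine)
  list(dwi = dwi, truth = truth)
}

#' Build the canonical ALPS-plane phantom
#'
#' Convenience phantom reproducing the geometry the ALPS method assumes at
#' the level of the lateral-ventricle body: for each hemisphere, a square
#' patch of projection fibers (z-dominant tensor) and, anterior to it, a
#' patch of association fibers (y-dominant tensor), embedded in isotropic
#' background. Patch centers are returned so ROIs can be placed
#' region-pure. Defaults give a healthy-control left index of
#' mean(1.107, 0.885) / mean(0.600, 0.600) = 1.66.
#'
#' @param proj_diag,assoc_diag Ground-truth tensor diagonals (mm^2/s) for
#'   the projection and association regions of the left hemisphere.
#' @param proj_diag_right,assoc_diag_right Right-hemisphere diagonals;
#'   default mirrors the left.
#' @param patch Side of each square fiber patch in voxels.
#' @param S0,snr,seed Passed to [phantom_spec()].
#' @return An `alps_phantom_spec` with an attached `roi_centers` attribute
#'   (list of left/right projection/association patch centers and the
#'   axial slice index, 1-based).
#' @export
alps_plane_phantom <- function(proj_diag = c(1.107e-3, 0.600e-3, 1.400e-3),
                               assoc_diag = c(0.885e-3, 1.400e-3, 0.600e-3),
                               proj_diag_right = proj_diag,
                               assoc_diag_right = assoc_diag,
                               patch = 5, S0 = 1000, snr = Inf, seed = 1L) {
  dim <- c(20L, 14L, 3L)
  slice <- 2L
  half <- patch %/% 2
  patch_idx <- function(cx, cy) {
    as.matrix(expand.grid(x = (cx - half):(cx + half),
                          y = (cy - half):(cy + half), z = slice))
  }
  centers <- list(
    left  = list(projection = c(15L, 4L), association = c(15L, 10L)),
    right = list(projection = c(6L, 4L),  association = c(6L, 10L))
  )
  regions <- list(
    proj_left   = list(indices = patch_idx(15, 4),  tensor = proj_diag),
    assoc_left  = list(indices = patch_idx(15, 10), tensor = assoc_diag),
    proj_right  = list(indices = patch_idx(6, 4),   tensor = proj_diag_right),
    assoc_right = list(indices = patch_idx(6, 10),  tensor = assoc_diag_right)
  )
  spec <- phantom_spec(dim = dim, regions = regions, S0 = S0, snr = snr,
                       seed = seed)
  attr(spec, "roi_centers") <- c(centers, list(slice = slice))
  spec
}

#' @export
print.alps_phantom_spec <- function(x, ...) {
  cat("<alps_phantom_spec> grid ", paste(x$dim, collapse = " x "),
      ", ", length(x$regions), " regions, S0 = ", x$S0,
      ", SNR = ", x$snr, "\n", sep = "")
  invisible(x)
}

#' Write a DWI dataset as NIfTI-1 with FSL sidecars
#'
#' @param dwi An `alps_dwi` object.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  img <- RNifti::asNifti(dwi$signal)
  img <- RNifti::`pixdim<-`(img, c(diag(dwi$affine)[1:3], 1))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  write_bval_bvec(dwi$gtab, prefix)
  invisible(prefix)
}

#' Read a DWI dataset from NIfTI-1 with FSL sidecars
#'
#' @param prefix Path prefix as used by [write_dwi()].
#' @return An `alps_dwi` object.
#' @export
read_dwi <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  gtab <- read_bval_bvec(prefix)
  vox <- RNifti::pixdim(img)[1:3]
  structure(list(signal = array(as.numeric(img), dim(img)),
                 affine = diag(c(vox, 1)), gtab = gtab),
            class = "alps_dwi")
}
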