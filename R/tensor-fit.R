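#' @title Voxel-wise diffusion tensor field
#' @description An `alps_tensor_field` stores the six unique components of
#' the symmetric diffusion tensor per voxel (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz,
#' in mm^2/s) as a 4D array `(x, y, z, 6)`, a logical mask, and the
#' voxel-to-world affine. Derived maps (eigenvalues, fractional
#' anisotropy, principal direction) are computed on demand.
#' @name alps_tensor_field
NULL

tensor_field <- function(D6, mask, affine, clamped = 0L, excluded = 0L,
                         method = NA_character_) {
  structure(list(D6 = D6, mask = mask, affine = affine,
                 clamped = clamped, excluded = excluded, method = method),
            class = "alps_tensor_field")
}

# Build a tensor field from a per-voxel (x, y, z, 3, 3) tensor array.
tensor_field_from_array <- function(tens, mask, affine) {
  d <- dim(tens)[1:3]
  D6 <- array(0, c(d, 6))
  D6[, , , 1] <- tens[, , , 1, 1]
  D6[, , , 2] <- tens[, , , 2, 2]
  D6[, , , 3] <- tens[, , , 3, 3]
  D6[, , , 4] <- tens[, , , 1, 2]
  D6[, , , 5] <- tens[, , , 1, 3]
  D6[, , , 6] <- tens[, , , 2, 3]
  tensor_field(D6, mask, affine, method = "ground-truth")
}

#' @export
print.alps_tensor_field <- function(x, ...) {
  cat("<alps_tensor_field> grid ", paste(dim(x$D6)[1:3], collapse = " x "),
      ", ", sum(x$mask), " voxels in mask, fit = ", x$method,
      if (x$clamped > 0) paste0(", ", x$clamped, " diagonals clamped to 0"),
      "\n", sep = "")
  invisible(x)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per masked voxel, solves the linearized monoexponential model
#' `log S = log S0 - b g' D g` for the six tensor components plus
#' `log S0` by ordinary least squares, optionally followed by one
#' weighted pass with weights equal to the squared predicted signal
#' (the standard one-step reweighted WLS estimator; on noise-free data
#' both estimators are exact and identical). Negative fitted diagonal
#' components are clamped to zero and counted; voxels containing
#' non-positive signals are excluded from the mask and counted.
#'
#' @param dwi An `alps_dwi` dataset (from [simulate_dwi()] or
#'   [read_dwi()]).
#' @param mask Logical array matching the spatial grid; default all
#'   voxels.
#' @param method `"wls"` (default, one reweighting pass) or `"ols"`.
#' @return An `alps_tensor_field` with `clamped` and `excluded` counts.
#' @examples
#' sim <- simulate_dwi(alps_plane_phantom(), make_gradient_table(32))
#' tf <- fit_tensor(sim$dwi)
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("wls", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "alps_dwi"))
  validate_gradient_table(dwi$gtab)
  check_axis_alignment(dwi$affine)
  d <- dim(dwi$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  stopifnot(all(dim(mask) == d))

  g <- dwi$gtab$bvecs
  b <- dwi$gtab$bvals
  # design: columns = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  nvol <- length(b)
  S <- matrix(dwi$signal, ncol = nvol)       # voxels x volumes
  vox_ids <- which(as.vector(mask))
  bad <- vox_ids[apply(S[vox_ids, , drop = FALSE] <= 0, 1, any)]
  use <- setdiff(vox_ids, bad)
  mask_out <- array(FALSE, d)
  mask_out[use] <- TRUE

  D6 <- array(0, c(d, 6))
  D6_flat <- matrix(0, prod(d), 6)
  if (length(use) > 0) {
    Y <- t(log(S[use, , drop = FALSE]))      # volumes x voxels
    beta <- qr.solve(X, Y)                   # 7 x voxels, OLS
    if (method == "wls") {
      pred <- X %*% beta
      for (j in seq_along(use)) {
        w <- exp(pred[, j])^2                # weights = squared predicted signal
        Xw <- X * w
        beta[, j] <- solve(crossprod(X, Xw), crossprod(Xw, Y[, j]))
      }
    }
    D6_flat[use, ] <- t(beta[-1, , drop = FALSE])
  }
  diag_part <- D6_flat[use, 1:3, drop = FALSE]
  clamped <- sum(diag_part < 0)
  diag_part[diag_part < 0] <- 0
  D6_flat[use, 1:3] <- diag_part
  D6 <- array(D6_flat, c(d, 6))
  tensor_field(D6, mask_out, dwi$affine, clamped = clamped,
               excluded = length(bad), method = method)
}

# Warn if the affine's rotation part deviates from axis alignment by > 5
# degrees: the ALPS diagonal-diffusivity reading assumes image axes are
# anatomical axes.
check_axis_alignment <- function(affine, tol_deg = 5) {
  R <- affine[1:3, 1:3]
  R <- sweep(R, 2, sqrt(colSums(R^2)), `/`)
  angles <- acos(pmin(1, abs(diag(R)))) * 180 / pi
  if (any(angles > tol_deg)) {
    warning("volume axes deviate from axis alignment by more than ",
            tol_deg, " degrees; diagonal diffusivities may not correspond ",
            "to anatomical x/y/z")
  }
  invisible(affine)
}

#' Extract the diagonal-diffusivity maps
#'
#' Returns the three scalar volumes Dxx, Dyy, Dzz (mm^2/s) that the ALPS
#' index reads: diffusivity along each image axis, taken as the tensor's
#' diagonal entries in the image frame.
#'
#' @param tf An `alps_tensor_field`.
#' @return Named list of three 3D arrays (`Dxx`, `Dyy`, `Dzz`) sharing the
#'   field's grid and affine (as attribute `affine`).
#' @export
diagonal_maps <- function(tf) {
  stopifnot(inherits(tf, "alps_tensor_field"))
  out <- list(Dxx = tf$D6[, , , 1], Dyy = tf$D6[, , , 2],
              Dzz = tf$D6[, , , 3])
  lapply(out, function(m) structure(m, affine = tf$affine))
}

# Per-voxel eigen decomposition over the mask; returns eigenvalues sorted
# descending and the principal eigenvector.
tensor_eigen <- function(tf) {
  d <- dim(tf$D6)[1:3]
  vals <- array(0, c(d, 3))
  vecs <- array(0, c(d, 3))
  flatD <- matrix(tf$D6, ncol = 6)
  ids <- which(as.vector(tf$mask))
  vals_flat <- matrix(0, prod(d), 3)
  vecs_flat <- matrix(0, prod(d), 3)
  for (i in ids) {
    Dm <- matrix(c(flatD[i, 1], flatD[i, 4], flatD[i, 5],
                   flatD[i, 4], flatD[i, 2], flatD[i, 6],
                   flatD[i, 5], flatD[i, 6], flatD[i, 3]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)
    vals_flat[i, ] <- e$values
    vecs_flat[i, ] <- e$vectors[, 1]
  }
  list(values = array(vals_flat, c(d, 3)),
       principal = array(vecs_flat, c(d, 3)))
}

#' Fractional anisotropy map
#'
#' FA is the normalized dispersion of the tensor eigenvalues, 0 for
#' isotropic diffusion and 1 for diffusion confined to a single axis:
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`.
#'
#' @param tf An `alps_tensor_field`.
#' @return 3D array of FA values in `[0, 1]` (0 outside the mask).
#' @export
fa_map <- function(tf) {
  eig <- tensor_eigen(tf)
  l <- eig$values
  md <- (l[, , , 1] + l[, , , 2] + l[, , , 3]) / 3
  num <- (l[, , , 1] - md)^2 + (l[, , , 2] - md)^2 + (l[, , , 3] - md)^2
  den <- l[, , , 1]^2 + l[, , , 2]^2 + l[, , , 3]^2
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  fa <- array(fa, dim(tf$D6)[1:3])   # keep dims on degenerate grids
  fa[!tf$mask] <- 0
  pmin(fa, 1)
}

#' Direction-encoded color map
#'
#' Standard directionality rendering of a tensor field: per voxel,
#' RGB = |principal eigenvector| scaled by FA, so red encodes x
#' (left-right), green y (anterior-posterior), blue z
#' (inferior-superior), with brightness proportional to anisotropy.
#'
#' @param tf An `alps_tensor_field`.
#' @return 4D array `(x, y, z, 3)` of RGB values in `[0, 1]`.
#' @export
direction_color_map <- function(tf) {
  eig <- tensor_eigen(tf)
  fa <- fa_map(tf)
  rgb <- abs(eig$principal)
  for (c in 1:3) rgb[, , , c] <- rgb[, , , c] * fa
  rgb
}

#' Tidy a tensor field into a per-voxel tibble
#'
#' @param x An `alps_tensor_field`.
#' @param ... Unused.
#' @return A tibble with voxel indices, the six tensor components, FA and
#'   the diagonal diffusivities, one row per in-mask voxel.
#' @exportS3Method generics::tidy
tidy.alps_tensor_field <- function(x, ...) {
  d <- dim(x$D6)[1:3]
  ids <- which(x$mask, arr.ind = TRUE)
  flatD <- matrix(x$D6, ncol = 6)
  lin <- which(as.vector(x$mask))
  fa <- as.vector(fa_map(x))[lin]
  tibble::tibble(
    x = ids[, 1], y = ids[, 2], z = ids[, 3],
    Dxx = flatD[lin, 1], Dyy = flatD[lin, 2], Dzz = flatD[lin, 3],
    Dxy = flatD[lin, 4], Dxz = flatD[lin, 5], Dyz = flatD[lin, 6],
    fa = fa
  )
}

#' Write a scalar map as NIfTI-1
#'
#' @param map 3D array with an `affine` attribute (e.g. from
#'   [diagonal_maps()]), or a plain array.
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path) {
  img <- RNifti::asNifti(unclass(map))
  aff <- attr(map, "affine")
  if (!is.null(aff)) img <- RNifti::`pixdim<-`(img, diag(aff)[1:3])
  RNifti::writeNifti(img, path)
  invisible(path)
}
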