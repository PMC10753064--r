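#' Define the four ALPS regions of interest
#'
#' The ALPS method reads directional diffusivities from four square ROIs
#' on one axial slice at the level of the lateral-ventricle body: a
#' projection-fiber ROI and an association-fiber ROI in each hemisphere.
#' ROIs are squares of `side` voxels (default 3, approximately 5.4 mm at
#' 1.8 mm in-plane resolution) centered on stated voxel coordinates.
#' Coordinates here are 1-based voxel indices in the image frame.
#'
#' @param slice Axial slice index (z, 1-based).
#' @param left,right Named lists with `projection` and `association`
#'   elements, each a length-2 integer `(x, y)` center.
#' @param side ROI side length in voxels (odd, >= 1).
#' @return An object of class `alps_roi_set`.
#' @examples
#' rois <- alps_roi_set(slice = 2,
#'   left  = list(projection = c(15, 4), association = c(15, 10)),
#'   right = list(projection = c(6, 4),  association = c(6, 10)))
#' @export
alps_roi_set <- function(slice, left, right, side = 3L) {
  if (side < 1) stop("ROI side must be >= 1 voxel")
  if (side %% 2 == 0) stop("ROI side must be odd so a center voxel exists")
  for (h in list(left, right)) {
    stopifnot(is.list(h), all(c("projection", "association") %in% names(h)))
    if (all(h$projection == h$association)) {
      stop("projection and association ROIs must not coincide")
    }
  }
  structure(list(slice = as.integer(slice),
                 left = lapply(left, as.integer),
                 right = lapply(right, as.integer),
                 side = as.integer(side)),
            class = "alps_roi_set")
}

#' @export
print.alps_roi_set <- function(x, ...) {
  cat("<alps_roi_set> slice ", x$slice, ", ", x$side, "x", x$side,
      " voxels\n", sep = "")
  for (h in c("left", "right")) {
    cat("  ", h, ": proj (", paste(x[[h]]$projection, collapse = ", "),
        "), assoc (", paste(x[[h]]$association, collapse = ", "), ")\n",
        sep = "")
  }
  invisible(x)
}

#' ROI set matching a phantom's fiber patches
#'
#' Reads the `roi_centers` attribute attached by [alps_plane_phantom()] so
#' ROIs are centered region-pure on the phantom's fiber patches.
#'
#' @param spec An `alps_phantom_spec` from [alps_plane_phantom()].
#' @param side ROI side length in voxels.
#' @return An `alps_roi_set`.
#' @export
phantom_roi_set <- function(spec, side = 3L) {
  centers <- attr(spec, "roi_centers")
  if (is.null(centers)) stop("phantom spec carries no roi_centers attribute")
  alps_roi_set(slice = centers$slice, left = centers$left,
               right = centers$right, side = side)
}

roi_voxels <- function(center, slice, side, dim) {
  half <- side %/% 2
  xs <- (center[1] - half):(center[1] + half)
  ys <- (center[2] - half):(center[2] + half)
  if (min(xs) < 1 || max(xs) > dim[1] || min(ys) < 1 || max(ys) > dim[2] ||
      slice < 1 || slice > dim[3]) {
    stop("ROI placement error: ROI exceeds volume bounds")
  }
  as.matrix(expand.grid(x = xs, y = ys, z = slice))
}

validate_roi_set <- function(rois, dim) {
  for (h in c("left", "right")) {
    p <- roi_voxels(rois[[h]]$projection, rois$slice, rois$side, dim)
    a <- roi_voxels(rois[[h]]$association, rois$slice, rois$side, dim)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    if (any(key(p) %in% key(a))) {
      stop("ROI placement error: projection and association ROIs overlap ",
           "in the ", h, " hemisphere")
    }
  }
  invisible(rois)
}

#' Mean map value over each ALPS ROI
#'
#' Arithmetic mean of the `side^2` voxel values of each single-slice ROI.
#'
#' @param map 3D scalar volume (e.g. one of [diagonal_maps()]).
#' @param rois An `alps_roi_set`.
#' @return A tibble with columns `hemisphere`, `roi`, `mean`.
#' @export
roi_means <- function(map, rois) {
  stopifnot(inherits(rois, "alps_roi_set"))
  d <- dim(map)
  validate_roi_set(rois, d)
  rows <- purrr::map_dfr(c("left", "right"), function(h) {
    purrr::map_dfr(c("projection", "association"), function(r) {
      vox <- roi_voxels(rois[[h]][[r]], rois$slice, rois$side, d)
      tibble::tibble(hemisphere = h, roi = r,
                     mean = mean(map[vox]))
    })
  })
  rows
}

#' The DTI-ALPS index
#'
#' `ALPS = mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)`: x-axis
#' diffusivity (perpendicular to both fiber tracts, along the
#' perivascular spaces of the medullary veins) in the projection and
#' association ROIs, over the diffusivity along each ROI's dominant fiber
#' axis (y in the projection ROI, z in the association ROI). The ratio is
#' dimensionless; a low index indicates impaired glymphatic function.
#'
#' @param d_x_proj,d_x_assoc,d_y_proj,d_z_assoc ROI-mean diffusivities in
#'   mm^2/s, all positive.
#' @return The ALPS index (scalar).
#' @examples
#' alps_index(1.107e-3, 0.885e-3, 0.600e-3, 0.600e-3)  # 1.66
#' @export
alps_index <- function(d_x_proj, d_x_assoc, d_y_proj, d_z_assoc) {
  vals <- c(d_x_proj, d_x_assoc, d_y_proj, d_z_assoc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid diffusivity: all four ROI-mean diffusivities must be ",
         "positive and finite")
  }
  mean(c(d_x_proj, d_x_assoc)) / mean(c(d_y_proj, d_z_assoc))
}

#' Compute left and right ALPS indices from a tensor field
#'
#' Composes [diagonal_maps()], [roi_means()] and [alps_index()] per
#' hemisphere and records provenance.
#'
#' @param tf An `alps_tensor_field`.
#' @param rois An `alps_roi_set`.
#' @return An object of class `alps_result`: a list with `left`, `right`,
#'   `diff` (left minus right), the per-hemisphere diffusivities, and
#'   provenance (ROI set, fit method).
#' @examples
#' sim <- simulate_dwi(alps_plane_phantom(), make_gradient_table(32))
#' tf <- fit_tensor(sim$dwi)
#' compute_alps(tf, phantom_roi_set(alps_plane_phantom()))
#' @export
compute_alps <- function(tf, rois) {
  stopifnot(inherits(tf, "alps_tensor_field"))
  maps <- diagonal_maps(tf)
  hemi_index <- function(h) {
    dx <- roi_means(maps$Dxx, rois)
    dy <- roi_means(maps$Dyy, rois)
    dz <- roi_means(maps$Dzz, rois)
    pick <- function(tb, roi) tb$mean[tb$hemisphere == h & tb$roi == roi]
    diffus <- c(d_x_proj = pick(dx, "projection"),
                d_x_assoc = pick(dx, "association"),
                d_y_proj = pick(dy, "projection"),
                d_z_assoc = pick(dz, "association"))
    list(index = alps_index(diffus[1], diffus[2], diffus[3], diffus[4]),
         diffusivities = diffus)
  }
  L <- hemi_index("left")
  R <- hemi_index("right")
  structure(list(left = L$index, right = R$index,
                 diff = L$index - R$index,
                 diffusivities = list(left = L$diffusivities,
                                      right = R$diffusivities),
                 provenance = list(rois = rois, fit_method = tf$method)),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> left %.3f, right %.3f, diff %+.3f\n",
              x$left, x$right, x$diff))
  invisible(x)
}

#' Tidy an ALPS result
#'
#' @param x An `alps_result`.
#' @param ... Unused.
#' @return One-row tibble with `alps_left`, `alps_right`, `alps_diff`.
#' @exportS3Method generics::tidy
tidy.alps_result <- function(x, ...) {
  tibble::tibble(alps_left = x$left, alps_right = x$right,
                 alps_diff = x$diff)
}

#' Intraclass correlation, single-rater consistency form
#'
#' ICC(3,1): two-way mixed-effects, single-measure, consistency. From the
#' two-way ANOVA decomposition of a subjects-by-raters matrix,
#' `ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`,
#' where `MS_error` is the residual mean square after removing subject and
#' rater effects. Rater offsets (a constant added to one column) do not
#' affect the consistency form. The agreement form ICC(2,1) is available
#' via `form = "agreement"`.
#'
#' @param ratings Numeric matrix, subjects in rows, raters/sessions in
#'   columns; no missing cells.
#' @param form `"consistency"` (default, ICC(3,1)) or `"agreement"`
#'   (ICC(2,1)).
#' @return The ICC (scalar, <= 1).
#' @examples
#' m <- cbind(c(9, 7, 8, 6), c(9.2, 7.1, 8.3, 6.0))
#' icc_single_rater(m)
#' @export
icc_single_rater <- function(ratings, form = c("consistency", "agreement")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2) stop("incomplete design: need at least 2 raters/sessions")
  if (n < 3) stop("incomplete design: need at least 3 subjects")
  if (anyNA(ratings)) stop("incomplete design: missing cells not supported")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))

  if (ms_rows == 0) {
    warning("degenerate design: zero between-subject variance")
  }
  denom_extra <- if (form == "agreement") {
    k / n * (ms_cols - ms_err)
  } else 0
  num <- ms_rows - ms_err
  den <- ms_rows + (k - 1) * ms_err + denom_extra
  if (den == 0) return(if (num == 0) 1 else NaN)  # identical constant columns
  num / den
}

#' ROI-placement reliability by jittered re-placement
#'
#' In-silico surrogate for repeated manual ROI placement: for each
#' subject's tensor field, every ROI center is perturbed independently and
#' uniformly within `+/- jitter` voxels (in-plane) per repeat, the ALPS
#' index is recomputed, and the subjects-by-repeats matrix of left-side
#' indices is summarized by [icc_single_rater()]. Repeat 1 uses the
#' unperturbed ROIs when `include_original = TRUE`. Jittered placements
#' falling outside the volume are resampled (and counted).
#'
#' @param tfs A list of `alps_tensor_field` objects, one per subject (a
#'   single field is accepted but at least 3 subjects are needed for an
#'   ICC).
#' @param rois An `alps_roi_set` applied to every subject.
#' @param jitter Maximum absolute in-plane displacement in voxels (>= 0).
#' @param n_repeats Number of placements per subject (>= 2).
#' @param seed Integer seed.
#' @param include_original Use the unjittered ROI set as the first repeat.
#' @return A list with `icc`, the `ratings` matrix, and `resampled`
#'   (count of out-of-bounds placements that were redrawn).
#' @export
roi_jitter_reliability <- function(tfs, rois, jitter = 1L, n_repeats = 2L,
                                   seed = 1L, include_original = TRUE) {
  if (inherits(tfs, "alps_tensor_field")) tfs <- list(tfs)
  if (jitter < 0) stop("jitter must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  resampled <- 0L
  d <- dim(tfs[[1]]$D6)[1:3]

  jitter_rois <- function() {
    repeat {
      j <- rois
      for (h in c("left", "right")) for (r in c("projection", "association")) {
        j[[h]][[r]] <- rois[[h]][[r]] +
          sample(seq(-jitter, jitter), 2, replace = TRUE)
      }
      ok <- tryCatch({ validate_roi_set(j, d); TRUE },
                     error = function(e) FALSE)
      if (ok) return(j)
      resampled <<- resampled + 1L
    }
  }

  ratings <- matrix(NA_real_, length(tfs), n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    r_set <- if (include_original && rep_i == 1L || jitter == 0) rois
             else jitter_rois()
    for (s in seq_along(tfs)) {
      ratings[s, rep_i] <- compute_alps(tfs[[s]], r_set)$left
    }
  }
  icc <- if (all(ratings == ratings[, 1])) 1.0 else icc_single_rater(ratings)
  list(icc = icc, ratings = ratings, resampled = resampled)
}

#' Write / read an ALPS ROI set as structured text
#'
#' Plain key-value text with one line per ROI:
#' `hemisphere roi center_x center_y`, plus `slice` and `side` headers.
#'
#' @param rois An `alps_roi_set`.
#' @param path File path.
#' @return `write_roi_set()` the path invisibly; `read_roi_set()` an
#'   `alps_roi_set`.
#' @export
write_roi_set <- function(rois, path) {
  lines <- c(paste("slice", rois$slice), paste("side", rois$side))
  for (h in c("left", "right")) for (r in c("projection", "association")) {
    c_xy <- rois[[h]][[r]]
    lines <- c(lines, paste(h, r, c_xy[1], c_xy[2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  toks <- strsplit(trimws(readLines(path)), "\\s+")
  slice <- side <- NA_integer_
  centers <- list(left = list(), right = list())
  for (t in toks) {
    if (t[1] == "slice") slice <- as.integer(t[2])
    else if (t[1] == "side") side <- as.integer(t[2])
    else centers[[t[1]]][[t[2]]] <- as.integer(t[3:4])
  }
  alps_roi_set(slice = slice, left = centers$left, right = centers$right,
               side = side)
}
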