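#' Specify a spherical region of interest
#'
#' A sphere given by a center in the affine's mm space and a radius in mm.
#' The study extracts 8-mm spheres at the peak coordinates of surviving
#' clusters.
#'
#' @param name label for the ROI.
#' @param center_mm numeric length-3 (X, Y, Z) mm coordinate.
#' @param radius_mm positive radius in mm.
#' @return an object of class \code{"roi_spec"}.
#' @export
roi_spec <- function(name, center_mm, radius_mm = 8) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center_mm), length(center_mm) == 3L,
            all(is.finite(center_mm)), radius_mm > 0)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "roi_spec")
}

#' Voxelwise multiscale entropy maps for one subject
#'
#' Computes the [mse_curve()] of every in-mask analyzable voxel of a
#' preprocessed volume and assembles one 3-D entropy map per scale.
#' Because preprocessing standardizes every analyzable voxel to unit SD,
#' the absolute tolerance equals \code{params$r}. Voxels whose entropy is
#' undefined at a scale (zero template matches) are \code{NA} in that
#' scale's map and counted in the run log.
#'
#' @param vol a preprocessed [bold4d()] volume (unit-SD voxels).
#' @param mask 3-D logical array on the volume's grid (e.g. the
#'   analyzability mask from [preprocess_subject()], possibly intersected
#'   with a brain mask).
#' @param params an [mse_params()] object.
#' @param subject optional subject identifier carried in the result.
#' @return an object of class \code{"mse_stack"}: list with \code{maps}
#'   (list of 3-D arrays, one per scale), \code{params}, \code{subject},
#'   \code{mask}, \code{affine}, and \code{log} (per-scale undefined-voxel
#'   counts).
#' @export
voxelwise_mse <- function(vol, mask = NULL, params = mse_params(),
                          subject = NA_character_) {
  stopifnot(inherits(vol, "bold4d"), inherits(params, "mse_params"))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (!identical(dim(mask), d[1:3])) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ", paste(d[1:3], collapse = "x"))
  }
  nt <- d[4]
  nv <- prod(d[1:3])
  y <- t(matrix(as.numeric(vol$data), nrow = nv, ncol = nt))
  finite_ok <- colSums(!is.finite(y)) == 0L
  var_ok <- finite_ok
  var_ok[finite_ok] <- matrixStats_colsd(y[, finite_ok, drop = FALSE]) > 0
  idx <- which(as.logical(mask) & var_ok)
  se <- matrix(NA_real_, nv, length(params$scales))
  n_undef <- integer(length(params$scales))
  if (length(idx) > 0) {
    res <- mse_map_core(y[, idx, drop = FALSE], params$m, params$r,
                        params$scales)
    se[idx, ] <- res$se
    n_undef <- as.integer(res$n_undefined)
  }
  maps <- lapply(seq_along(params$scales), function(s) {
    array(se[, s], dim = d[1:3])
  })
  names(maps) <- paste0("scale", params$scales)
  analyzable <- array(FALSE, dim = d[1:3])
  analyzable[idx] <- TRUE
  structure(list(maps = maps, params = params, subject = subject,
                 mask = analyzable,
                 affine = vol$affine,
                 log = list(n_undefined_by_scale = stats::setNames(
                   n_undef, names(maps)))),
            class = "mse_stack")
}

#' @export
print.mse_stack <- function(x, ...) {
  cat(sprintf("<mse_stack> subject %s, m = %d, r = %.2f, scales %s\n",
              x$subject, x$params$m, x$params$r,
              paste(x$params$scales, collapse = ",")))
  invisible(x)
}

#' Mean entropy within a mask, per scale
#'
#' Per-scale mean over in-mask analyzable (non-\code{NA}) voxels; the
#' study reports these means within whole-brain, GM, WM and CSF masks.
#' Returns \code{NA} for a scale with no contributing voxel; an empty mask
#' gives all-\code{NA} with a warning.
#'
#' @param stack an [voxelwise_mse()] result.
#' @param mask 3-D logical array on the stack's grid.
#' @return named numeric vector, one value per scale.
#' @export
mean_entropy_in_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "mse_stack"))
  if (!identical(dim(mask), dim(stack$maps[[1]]))) {
    stop("mask grid does not match the entropy maps")
  }
  if (!any(mask)) {
    warning("empty mask: returning NA for every scale")
    return(stats::setNames(rep(NA_real_, length(stack$maps)),
                           names(stack$maps)))
  }
  vapply(stack$maps, function(m) mean(m[mask], na.rm = TRUE), numeric(1))
}

#' Average entropy within an ROI sphere, per scale
#'
#' Voxels whose mm-space centers lie within \code{radius_mm} (Euclidean,
#' inclusive boundary) of the ROI center are averaged per scale, excluding
#' undefined (\code{NA}) voxels.
#'
#' @param stack an [voxelwise_mse()] result.
#' @param roi an [roi_spec()].
#' @return named numeric vector, one value per scale.
#' @export
extract_roi_sphere <- function(stack, roi) {
  stopifnot(inherits(stack, "mse_stack"), inherits(roi, "roi_spec"))
  idx <- sphere_voxels(dim(stack$maps[[1]]), stack$affine, roi$center_mm,
                       roi$radius_mm)
  if (length(idx) == 0L) {
    stop("ROI '", roi$name, "' does not intersect the image grid")
  }
  vapply(stack$maps, function(m) mean(m[idx], na.rm = TRUE), numeric(1))
}

#' Linear voxel indices inside a sphere
#'
#' All voxels whose centers (mapped through the affine, 0-based indices)
#' lie within \code{radius_mm} of \code{center_mm}, boundary inclusive.
#'
#' @param dim length-3 grid shape.
#' @param affine 4x4 voxel-to-mm transform.
#' @param center_mm sphere center (mm).
#' @param radius_mm sphere radius (mm).
#' @return integer vector of linear voxel indices (possibly empty).
#' @export
sphere_voxels <- function(dim, affine, center_mm, radius_mm) {
  # voxel center nearest the sphere center, then scan a bounding box
  inv <- solve(affine)
  vc <- (inv %*% c(center_mm, 1))[1:3]  # 0-based fractional voxel coords
  # conservative half-width in voxels along each axis
  pitch <- sqrt(colSums(affine[1:3, 1:3]^2))
  half <- ceiling(radius_mm / pitch) + 1L
  rng <- lapply(1:3, function(k) {
    lo <- max(0L, floor(vc[k]) - half[k])
    hi <- min(dim[k] - 1L, ceiling(vc[k]) + half[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(integer(0))
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  mm <- t(affine[1:3, 1:3] %*% t(g) + affine[1:3, 4])
  keep <- rowSums(sweep(mm, 2L, center_mm)^2) <= radius_mm^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  as.integer(g[, 1] + dim[1] * (g[, 2] + dim[2] * g[, 3]) + 1L)
}

#' Write the entropy maps of a subject as NIfTI files
#'
#' One 3-D NIfTI per scale, named
#' \code{<subject>_m<m>_r<r>_scale<l>.nii.gz}.
#'
#' @param stack an [voxelwise_mse()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_mse_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "mse_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(stack$maps))
  for (s in seq_along(stack$maps)) {
    l <- stack$params$scales[s]
    fn <- sprintf("%s_m%d_r%s_scale%d.nii.gz", stack$subject,
                  stack$params$m, sub("^0\\.", ".", format(stack$params$r)),
                  l)
    paths[s] <- file.path(dir, fn)
    img <- RNifti::asNifti(stack$maps[[s]])
    img <- RNifti::`sform<-`(img, structure(stack$affine, code = 2L))
    RNifti::writeNifti(img, paths[s])
  }
  invisible(paths)
}
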