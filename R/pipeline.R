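#' Generate, preprocess and entropy-map a whole synthetic cohort
#'
#' Streams the cohort subject by subject (regenerating each from its
#' derived seed), applies the full temporal preprocessing, computes the
#' voxelwise multiscale entropy inside the brain mask, and collects the
#' per-scale entropy of every subject into one in-memory stack. This is
#' the workhorse behind the simulation studies; nothing is written to
#' disk.
#'
#' @param config a [cohort_config()].
#' @param params an [mse_params()].
#' @return an object of class \code{"mse_cohort"}: \code{se} (array
#'   voxels-in-mask x subjects x scales), \code{vox_index} (linear voxel
#'   indices of the mask), \code{mask} (3-D logical), \code{affine},
#'   \code{scales}, \code{params}, \code{manifest}, and
#'   \code{n_undefined} (subjects x scales counts of undefined-entropy
#'   voxels).
#' @export
run_study_mse <- function(config, params = mse_params()) {
  stopifnot(inherits(config, "cohort_config"))
  mf <- cohort_manifest(config)
  mask <- brain_mask(config$dim, config$pitch_mm)
  vox <- which(mask)
  nv <- length(vox)
  ns <- nrow(mf)
  nsc <- length(params$scales)
  se <- array(NA_real_, dim = c(nv, ns, nsc))
  n_undef <- matrix(0L, ns, nsc)
  for (i in seq_len(ns)) {
    sub <- generate_subject(config, as.character(mf$group[i]), mf$seed[i],
                            as_matrix = TRUE)
    pm <- preprocess_mat(sub$sig, sub$confounds, config$n_dummy,
                         0.01, 0.2, config$tr_seconds)
    res <- mse_map_core(pm$y, params$m, params$r, params$scales)
    se[pm$analyzable, i, ] <- res$se
    n_undef[i, ] <- as.integer(res$n_undefined)
  }
  structure(list(se = se, vox_index = vox, mask = mask,
                 affine = grid_affine(config$dim, config$pitch_mm),
                 scales = params$scales, params = params, manifest = mf,
                 n_undefined = n_undef, config = config),
            class = "mse_cohort")
}

#' Entropy-map a cohort stored on disk
#'
#' File-based counterpart of [run_study_mse()]: reads each subject's 4-D
#' NIfTI and confound CSV named in the manifest, preprocesses and maps
#' it. Used to check that everything the generator writes is readable by
#' the pipeline.
#'
#' @param manifest manifest data frame with \code{path} column (as
#'   written by [generate_cohort()]); confound files are found by
#'   replacing \code{_bold.nii.gz} with \code{_confounds.csv}.
#' @param params an [mse_params()].
#' @param tr_seconds repetition time of the stored volumes.
#' @param n_drop initial volumes to drop.
#' @param mask optional 3-D logical analysis mask; default is the
#'   ellipsoidal brain mask for the stored grid.
#' @return an \code{mse_cohort} (see [run_study_mse()]).
#' @export
msemap_from_files <- function(manifest, params = mse_params(),
                              tr_seconds = 3, n_drop = 10L, mask = NULL) {
  stopifnot(all(file.exists(manifest$path)))
  first <- RNifti::readNifti(manifest$path[1])
  dim3 <- dim(first)[1:3]
  if (is.null(mask)) mask <- brain_mask(dim3)
  vox <- which(mask)
  nv <- length(vox)
  ns <- nrow(manifest)
  nsc <- length(params$scales)
  se <- array(NA_real_, dim = c(nv, ns, nsc))
  n_undef <- matrix(0L, ns, nsc)
  affine <- NULL
  for (i in seq_len(ns)) {
    img <- RNifti::readNifti(manifest$path[i])
    aff <- RNifti::xform(img)
    if (is.null(affine)) affine <- unclass(aff)
    conf <- utils::read.csv(sub("_bold\\.nii\\.gz$", "_confounds.csv",
                                manifest$path[i]))
    vol <- bold4d(array(as.numeric(img), dim = dim(img)),
                  unclass(aff), tr_seconds)
    pp <- preprocess_subject(vol, conf, n_drop = n_drop, mask = mask)
    d <- dim(pp$vol$data)
    flat <- matrix(as.numeric(pp$vol$data), prod(d[1:3]), d[4])
    ok <- pp$mask[vox]
    res <- mse_map_core(t(flat[vox[ok], , drop = FALSE]), params$m,
                        params$r, params$scales)
    se[ok, i, ] <- res$se
    n_undef[i, ] <- as.integer(res$n_undefined)
  }
  structure(list(se = se, vox_index = vox, mask = mask, affine = affine,
                 scales = params$scales, params = params,
                 manifest = manifest, n_undefined = n_undef,
                 config = NULL),
            class = "mse_cohort")
}

#' @export
print.mse_cohort <- function(x, ...) {
  cat(sprintf("<mse_cohort> %d subjects, %d in-mask voxels, scales %s (m = %d, r = %.2f)\n",
              dim(x$se)[2], dim(x$se)[1],
              paste(x$scales, collapse = ","), x$params$m, x$params$r))
  invisible(x)
}

#' Subset an mse_cohort by subject
#'
#' @param secohort an \code{mse_cohort}.
#' @param rows integer indices of manifest rows to keep.
#' @return the subsetted \code{mse_cohort}.
#' @export
subset_cohort <- function(secohort, rows) {
  stopifnot(inherits(secohort, "mse_cohort"))
  out <- secohort
  out$se <- secohort$se[, rows, , drop = FALSE]
  out$manifest <- secohort$manifest[rows, , drop = FALSE]
  out$n_undefined <- secohort$n_undefined[rows, , drop = FALSE]
  out
}

#' Per-subject mean entropy within an ROI sphere
#'
#' @param secohort an \code{mse_cohort}.
#' @param roi an [roi_spec()].
#' @param scale a single scale, or \code{NULL} for all scales.
#' @return numeric vector (one scale) or matrix subjects x scales.
#' @export
cohort_roi_means <- function(secohort, roi, scale = NULL) {
  stopifnot(inherits(secohort, "mse_cohort"), inherits(roi, "roi_spec"))
  sph <- sphere_voxels(dim(secohort$mask), secohort$affine, roi$center_mm,
                       roi$radius_mm)
  rows <- match(intersect(sph, secohort$vox_index), secohort$vox_index)
  if (length(rows) == 0L) {
    stop("ROI '", roi$name, "' does not intersect the analysis mask")
  }
  m <- apply(secohort$se[rows, , , drop = FALSE], c(2, 3), mean,
             na.rm = TRUE)
  colnames(m) <- paste0("scale", secohort$scales)
  if (is.null(scale)) m else m[, match(scale, secohort$scales)]
}

#' Full group analysis at one scale
#'
#' Runs the inference chain of the study on an entropy-mapped cohort:
#' covariate-adjusted voxelwise ANOVA, permutation cluster correction,
#' 8-mm ROI spheres at surviving peaks, Bonferroni post-hoc pairwise
#' tests on covariate-adjusted ROI values, and Spearman correlations of
#' ROI entropy with the clinical scores in the patient groups.
#'
#' @param secohort an \code{mse_cohort}.
#' @param scale scale to analyze.
#' @param voxel_p,cluster_p,n_perm,seed passed to [cluster_correct()].
#' @param radius_mm ROI sphere radius (default 8 mm).
#' @param covariates manifest columns adjusted for.
#' @param correlation_groups groups pooled for the clinical correlations
#'   (default the patient groups, as in the study).
#' @param adjust multiple-comparison method for the correlation families.
#' @return list: \code{anova}, \code{clusters}, \code{rois},
#'   \code{roi_values} (long data frame), \code{posthoc} (one table per
#'   ROI), \code{correlations}, and \code{settings}.
#' @export
run_group_analysis <- function(secohort, scale, voxel_p = 0.001,
                               cluster_p = 0.05, n_perm = 500L, seed = 1L,
                               radius_mm = 8,
                               covariates = c("age", "sex", "education"),
                               correlation_groups = c("EMCI", "LMCI", "AD"),
                               adjust = "BH") {
  av <- voxelwise_anova(secohort, scale, covariates)
  cc <- cluster_correct(av, voxel_p, cluster_p, n_perm, seed)
  rois <- list()
  roi_values <- NULL
  posthoc <- list()
  correlations <- NULL
  if (nrow(cc$table) > 0) {
    rois <- lapply(seq_len(nrow(cc$table)), function(i) {
      roi_spec(sprintf("cluster%d", i),
               c(cc$table$peak_x[i], cc$table$peak_y[i],
                 cc$table$peak_z[i]), radius_mm)
    })
    mf <- secohort$manifest
    roi_values <- do.call(rbind, lapply(rois, function(roi) {
      data.frame(roi = roi$name, id = mf$id, group = mf$group,
                 mse = cohort_roi_means(secohort, roi, scale),
                 mf[, intersect(c("age", "sex", "education", "MMSE",
                                  "FAQ", "CDR"), names(mf))])
    }))
    cov_mat <- as.matrix(secohort$manifest[, covariates])
    posthoc <- lapply(rois, function(roi) {
      d <- roi_values[roi_values$roi == roi$name, ]
      posthoc_pairwise(d$mse, d$group, cov_mat)
    })
    names(posthoc) <- vapply(rois, `[[`, character(1), "name")
    pat <- roi_values[roi_values$group %in% correlation_groups, ]
    correlations <- clinical_correlations(pat, method = adjust)
  }
  list(anova = av, clusters = cc, rois = rois, roi_values = roi_values,
       posthoc = posthoc, correlations = correlations,
       settings = list(scale = scale, voxel_p = voxel_p,
                       cluster_p = cluster_p, n_perm = n_perm,
                       seed = seed, radius_mm = radius_mm,
                       covariates = covariates, adjust = adjust))
}

#' Write a JSON run manifest
#'
#' Records the seed, thresholds and configuration of an analysis so a
#' run can be reproduced exactly.
#'
#' @param settings a settings list (e.g. from [run_group_analysis()]).
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_run_manifest <- function(settings, path) {
  jsonlite::write_json(settings, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
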