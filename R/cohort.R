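#' Configuration of a synthetic four-group cohort
#'
#' Defines a dementia-cohort-style study: four diagnostic groups (NC,
#' EMCI, LMCI, AD)
#' of sizes 30/33/32/29, 140 volumes at TR = 3 s on an isotropic 3-mm
#' 20x24x20 grid, with signal complexity manipulated inside planted ROIs
#' by mixing spectrally synthesized 1/f ("pink") noise with white noise.
#' Larger pink weight gives a flatter multiscale-entropy curve (more
#' "complex" in the long-range-correlation sense); groups receive
#' monotonically decreasing weights NC > EMCI > LMCI > AD inside the
#' planted ROIs, while background voxels share a group-independent weight.
#' Clinical scores are coupled to each subject's realized planted-ROI
#' weight: MMSE with a positive slope, FAQ and CDR with negative slopes
#' (CDR clamped to [0, 3]). Covariates (age, sex, education) are drawn
#' group-independently so that covariate adjustment is a no-op on average;
#' \code{confounded_age} shifts AD ages upward to exercise adjustment.
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param dim grid shape (voxels).
#' @param pitch_mm voxel size (mm).
#' @param n_timepoints volumes acquired, including the initial dummies.
#' @param tr_seconds repetition time (s).
#' @param n_dummy number of initial dummy volumes carrying the additive
#'   offset (exercises initial-volume dropping).
#' @param dummy_offset additive amplitude of the dummy volumes.
#' @param background_weight pink weight of background voxels (all groups).
#' @param group_weights named vector of pink weights inside planted ROIs,
#'   one per group. \code{NULL} (a "null" cohort) plants no effect: all
#'   groups use \code{background_weight}.
#' @param planted_rois list of [roi_spec()] regions carrying the group
#'   effect.
#' @param subject_weight_sd SD of the per-subject jitter added to the
#'   group weight (truncated to [0, 1]).
#' @param signal_model \code{"mix"} (pink/white mixing, default) or
#'   \code{"ar1"} (autoregressive alternative used for robustness checks).
#' @param ar_coef AR(1) coefficient scale for \code{signal_model = "ar1"}.
#' @param confound_amplitude SD of the per-voxel loadings of the nuisance
#'   regressors mixed into every in-brain voxel.
#' @param mmse_coef,faq_coef,cdr_coef length-2 (intercept, slope) of the
#'   score couplings to the subject's realized planted-ROI weight.
#' @param mmse_sd,faq_sd,cdr_sd score noise SDs.
#' @param gmv_coef,gmv_sd per-ROI gray-matter-volume coupling and noise.
#' @param confounded_age if \code{TRUE}, AD ages are shifted +5 years.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return an object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(group_sizes = c(NC = 30L, EMCI = 33L,
                                          LMCI = 32L, AD = 29L),
                          dim = c(20L, 24L, 20L), pitch_mm = 3,
                          n_timepoints = 140L, tr_seconds = 3,
                          n_dummy = 10L, dummy_offset = 1000,
                          background_weight = 0.4,
                          group_weights = c(NC = 0.90, EMCI = 0.75,
                                            LMCI = 0.60, AD = 0.45),
                          planted_rois = list(
                            roi_spec("planted", c(0, -9, 0), 9)),
                          subject_weight_sd = 0.06,
                          signal_model = c("mix", "ar1"), ar_coef = 0.5,
                          confound_amplitude = 0.25,
                          mmse_coef = c(14, 18), mmse_sd = 1.8,
                          faq_coef = c(28, -33), faq_sd = 2.5,
                          cdr_coef = c(2.0, -2.35), cdr_sd = 0.25,
                          gmv_coef = c(0.5, 0.3), gmv_sd = 0.05,
                          confounded_age = FALSE,
                          seed = 1L) {
  signal_model <- match.arg(signal_model)
  groups <- c("NC", "EMCI", "LMCI", "AD")
  stopifnot(identical(names(group_sizes), groups), all(group_sizes >= 2),
            length(dim) == 3L, all(dim >= 4), n_timepoints > n_dummy + 20,
            tr_seconds > 0, background_weight >= 0, background_weight <= 1)
  if (is.null(group_weights)) {
    group_weights <- stats::setNames(rep(background_weight, 4L), groups)
  }
  stopifnot(identical(names(group_weights), groups),
            all(group_weights >= 0 & group_weights <= 1))
  if (is.unsorted(rev(group_weights))) {
    stop("group weights must be monotone NC >= EMCI >= LMCI >= AD")
  }
  stopifnot(all(vapply(planted_rois, inherits, logical(1), "roi_spec")))
  structure(list(group_sizes = group_sizes, dim = as.integer(dim),
                 pitch_mm = pitch_mm, n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_dummy = as.integer(n_dummy),
                 dummy_offset = dummy_offset,
                 background_weight = background_weight,
                 group_weights = group_weights,
                 planted_rois = planted_rois,
                 subject_weight_sd = subject_weight_sd,
                 signal_model = signal_model, ar_coef = ar_coef,
                 confound_amplitude = confound_amplitude,
                 mmse_coef = mmse_coef, mmse_sd = mmse_sd,
                 faq_coef = faq_coef, faq_sd = faq_sd,
                 cdr_coef = cdr_coef, cdr_sd = cdr_sd,
                 gmv_coef = gmv_coef, gmv_sd = gmv_sd,
                 confounded_age = confounded_age,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Ellipsoidal "brain" mask of a synthetic grid
#'
#' Voxels whose mm coordinates fall inside an ellipsoid with semi-axes
#' 0.9 of the half-extent of the grid (brains do not fill their bounding
#' box; roughly 40 percent of the grid is in-brain).
#'
#' @param dim grid shape.
#' @param pitch_mm voxel size (mm).
#' @param frac semi-axis fraction of the half-extent.
#' @return 3-D logical array.
#' @export
brain_mask <- function(dim, pitch_mm = 3, frac = 0.9) {
  e <- ellipsoid_norm(dim, pitch_mm, frac)
  array(e <= 1, dim = dim)
}

#' Synthetic tissue masks (whole-brain, GM, WM, CSF)
#'
#' Concentric shells of the brain ellipsoid: CSF at the center
#' (normalized radius <= 0.3), WM next (<= 0.6), GM the outer shell.
#' These emulate the topology of tissue masks, not anatomy.
#'
#' @inheritParams brain_mask
#' @return named list of 3-D logical arrays: WB, GM, WM, CSF.
#' @export
tissue_masks <- function(dim, pitch_mm = 3, frac = 0.9) {
  e <- ellipsoid_norm(dim, pitch_mm, frac)
  list(WB = array(e <= 1, dim),
       GM = array(e > 0.6 & e <= 1, dim),
       WM = array(e > 0.3 & e <= 0.6, dim),
       CSF = array(e <= 0.3, dim))
}

ellipsoid_norm <- function(dim, pitch_mm, frac) {
  aff <- grid_affine(dim, pitch_mm)
  semi <- (dim - 1) / 2 * pitch_mm * frac
  ax <- (aff[1, 1] * (seq_len(dim[1]) - 1) + aff[1, 4]) / semi[1]
  ay <- (aff[2, 2] * (seq_len(dim[2]) - 1) + aff[2, 4]) / semi[2]
  az <- (aff[3, 3] * (seq_len(dim[3]) - 1) + aff[3, 4]) / semi[3]
  outer(outer(ax^2, ay^2, "+"), az^2, "+")
}

#' Generate one voxel signal of controllable complexity
#'
#' Standardized mixture \code{w * pink + (1 - w) * white}: pink is
#' spectral-synthesis 1/f noise, white is i.i.d. Gaussian, both
#' unit-variance before mixing. Weight 0 gives white noise (entropy
#' decreasing over scales); weight 1 gives pink noise (flat entropy
#' curve).
#'
#' @param weight pink mixing weight in [0, 1].
#' @param n series length (>= 20).
#' @param seed optional RNG seed.
#' @return standardized numeric vector of length \code{n}.
#' @export
generate_voxel_signal <- function(weight, n, seed = NULL) {
  stopifnot(weight >= 0, weight <= 1, n >= 20)
  if (!is.null(seed)) set.seed(seed)
  p <- pink_noise_mat(n, 1L)
  w <- white_noise_mat(n, 1L)
  standardize(weight * drop(p) + (1 - weight) * drop(w))
}

# Spectral-synthesis 1/f noise: white Gaussian columns, spectrum shaped by
# 1/sqrt(f), inverse FFT, columns standardized to mean 0 / unit
# (population) SD.
pink_noise_mat <- function(n, nv) {
  w <- matrix(stats::rnorm(n * nv), n, nv)
  f <- stats::mvfft(w)
  k <- seq_len(n - 1)
  amp <- c(0, 1 / sqrt(pmin(k, n - k)))
  x <- Re(stats::mvfft(f * amp, inverse = TRUE)) / n
  scale_cols_core(x)
  x
}

# Standardized white-noise matrix.
white_noise_mat <- function(n, nv) {
  x <- matrix(stats::rnorm(n * nv), n, nv)
  scale_cols_core(x)
  x
}

#' Generate one synthetic subject
#'
#' Draws, in a fixed RNG order so that \code{metadata_only} runs are
#' byte-identical to full runs: (1) realized planted-ROI weights (group
#' weight + subject jitter), (2) covariates, (3) clinical scores and GMV,
#' (4) the 4-D volume and nuisance regressors. The volume carries the
#' additive dummy offset on the first \code{n_dummy} volumes and the
#' confound mixture on all in-brain voxels; out-of-brain voxels are
#' constant zero (and hence flagged non-analyzable downstream).
#'
#' @param config a [cohort_config()].
#' @param group one of "NC", "EMCI", "LMCI", "AD".
#' @param subject_seed integer seed for this subject.
#' @param metadata_only if \code{TRUE}, stop after covariates/scores
#'   (no volume is generated).
#' @param as_matrix if \code{TRUE}, return the in-brain voxel series as a
#'   time-by-voxel matrix (\code{sig}, columns ordered by the brain-mask
#'   linear indices in \code{vox_index}) instead of packing a 4-D array —
#'   the streaming fast path used by [run_study_mse()]. The random draws
#'   are identical either way.
#' @return list with \code{vol} ([bold4d()], \code{NULL} if
#'   \code{metadata_only} or \code{as_matrix}), \code{confounds} (data
#'   frame, one row per retained volume), \code{covariates},
#'   \code{scores}, \code{gmv}, \code{weights} (realized per-ROI
#'   weights).
#' @export
generate_subject <- function(config, group, subject_seed,
                             metadata_only = FALSE, as_matrix = FALSE) {
  stopifnot(inherits(config, "cohort_config"),
            group %in% names(config$group_sizes))
  set.seed(as.integer(subject_seed %% 2147483647))
  gw <- config$group_weights[[group]]
  w_roi <- pmin(1, pmax(0, gw + stats::rnorm(length(config$planted_rois),
                                             0, config$subject_weight_sd)))
  w_mean <- mean(w_roi)
  age <- stats::rnorm(1, 73, 7) +
    if (config$confounded_age && group == "AD") 5 else 0
  sex <- stats::rbinom(1, 1, 0.5)
  education <- stats::rnorm(1, 16, 2.3)
  mmse <- clamp(config$mmse_coef[1] + config$mmse_coef[2] * w_mean +
                  stats::rnorm(1, 0, config$mmse_sd), 0, 30)
  faq <- clamp(config$faq_coef[1] + config$faq_coef[2] * w_mean +
                 stats::rnorm(1, 0, config$faq_sd), 0, 30)
  cdr <- clamp(config$cdr_coef[1] + config$cdr_coef[2] * w_mean +
                 stats::rnorm(1, 0, config$cdr_sd), 0, 3)
  gmv <- stats::setNames(
    config$gmv_coef[1] + config$gmv_coef[2] * w_roi +
      stats::rnorm(length(w_roi), 0, config$gmv_sd),
    vapply(config$planted_rois, `[[`, character(1), "name"))
  meta <- list(covariates = list(age = age, sex = sex,
                                 education = education),
               scores = list(MMSE = mmse, FAQ = faq, CDR = cdr),
               gmv = gmv, weights = w_roi, group = group)
  if (metadata_only) {
    return(c(meta, list(vol = NULL, confounds = NULL)))
  }

  nt <- config$n_timepoints
  aff <- grid_affine(config$dim, config$pitch_mm)
  mask <- brain_mask(config$dim, config$pitch_mm)
  idx <- which(mask)
  nv <- length(idx)

  # per-voxel pink weight: background everywhere, realized ROI weight
  # inside each planted sphere
  wv <- rep(config$background_weight, nv)
  for (k in seq_along(config$planted_rois)) {
    sph <- sphere_voxels(config$dim, aff, config$planted_rois[[k]]$center_mm,
                         config$planted_rois[[k]]$radius_mm)
    wv[match(intersect(sph, idx), idx)] <- w_roi[k]
  }

  if (config$signal_model == "mix") {
    sig <- pink_noise_mat(nt, nv) * rep(wv, each = nt) +
      white_noise_mat(nt, nv) * rep(1 - wv, each = nt)
  } else {
    # AR(1) alternative: weight maps onto the autocorrelation
    phi <- config$ar_coef * wv
    e <- matrix(stats::rnorm(nt * nv), nt, nv)
    sig <- matrix(0, nt, nv)
    sig[1, ] <- e[1, ]
    for (t in 2:nt) sig[t, ] <- phi * sig[t - 1, ] + e[t, ]
  }
  scale_cols_core(sig)

  conf <- make_confounds(nt, config$tr_seconds)
  loadings <- matrix(stats::rnorm(ncol(conf) * nv, 0,
                                  config$confound_amplitude),
                     ncol(conf), nv)
  sig <- sig + conf %*% loadings
  sig[seq_len(config$n_dummy), ] <- sig[seq_len(config$n_dummy), ] +
    config$dummy_offset
  conf_kept <- as.data.frame(conf[(config$n_dummy + 1):nt, , drop = FALSE])

  if (as_matrix) {
    return(c(meta, list(vol = NULL, sig = sig, vox_index = idx,
                        confounds = conf_kept)))
  }
  arr <- array(0, dim = c(config$dim, nt))
  flat <- matrix(arr, prod(config$dim), nt)
  flat[idx, ] <- t(sig)
  arr <- array(flat, dim = c(config$dim, nt))
  c(meta, list(vol = bold4d(arr, aff, config$tr_seconds),
               confounds = conf_kept))
}

# Nuisance regressors over the full acquisition: a slow global drift,
# three pseudo-motion random walks, and smooth CSF/WM-like signals; all
# standardized.
make_confounds <- function(nt, tr_seconds) {
  tt <- seq_len(nt) * tr_seconds
  smooth_ar <- function(n, phi = 0.9) {
    as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
  }
  conf <- cbind(
    global = sin(2 * pi * tt / 180) + 0.5 * smooth_ar(nt),
    motion1 = cumsum(stats::rnorm(nt, 0, 0.1)),
    motion2 = cumsum(stats::rnorm(nt, 0, 0.1)),
    motion3 = cumsum(stats::rnorm(nt, 0, 0.1)),
    csf = smooth_ar(nt, 0.8),
    wm = smooth_ar(nt, 0.8))
  apply(conf, 2L, function(col) (col - mean(col)) / pop_sd(col))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Per-subject seeds of a cohort
#'
#' Deterministically derived from the master seed, so any subject can be
#' regenerated independently.
#'
#' @param config a [cohort_config()].
#' @return integer vector, one seed per subject.
#' @export
cohort_subject_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(2147483646L, sum(config$group_sizes))
}

#' Cohort manifest (subject table)
#'
#' Generates every subject's metadata (group, covariates, scores, GMV)
#' without generating volumes. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per subject: \code{id}, \code{group},
#'   \code{age}, \code{sex}, \code{education}, \code{MMSE}, \code{FAQ},
#'   \code{CDR}, one \code{gmv_<roi>} column per planted ROI,
#'   \code{seed}, \code{path} (\code{NA} until written).
#' @export
cohort_manifest <- function(config) {
  seeds <- cohort_subject_seeds(config)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  rows <- lapply(seq_along(groups), function(i) {
    s <- generate_subject(config, groups[i], seeds[i], metadata_only = TRUE)
    out <- data.frame(id = sprintf("sub-%03d", i), group = groups[i],
                      age = s$covariates$age, sex = s$covariates$sex,
                      education = s$covariates$education,
                      MMSE = s$scores$MMSE, FAQ = s$scores$FAQ,
                      CDR = s$scores$CDR, seed = seeds[i],
                      path = NA_character_, stringsAsFactors = FALSE)
    for (nm in names(s$gmv)) out[[paste0("gmv_", nm)]] <- s$gmv[[nm]]
    out
  })
  mf <- do.call(rbind, rows)
  mf$group <- factor(mf$group, levels = names(config$group_sizes))
  mf
}

#' Generate a cohort and write it to disk
#'
#' Writes one 4-D NIfTI and one confound CSV per subject, a manifest CSV,
#' and a YAML-style config echo. Per-subject seeds derive from the master
#' seed, so the tree is byte-reproducible.
#'
#' @param config a [cohort_config()].
#' @param dir output directory.
#' @return the manifest data frame, with \code{path} filled in.
#' @export
generate_cohort <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  mf <- cohort_manifest(config)
  for (i in seq_len(nrow(mf))) {
    sub <- generate_subject(config, as.character(mf$group[i]), mf$seed[i])
    path <- file.path(dir, paste0(mf$id[i], "_bold.nii.gz"))
    img <- RNifti::asNifti(sub$vol$data)
    img <- RNifti::`sform<-`(img, structure(sub$vol$affine, code = 2L))
    RNifti::writeNifti(img, path)
    utils::write.csv(sub$confounds,
                     file.path(dir, paste0(mf$id[i], "_confounds.csv")),
                     row.names = FALSE)
    mf$path[i] <- path
  }
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  writeLines(c("# cohort configuration",
               paste0("seed: ", config$seed),
               paste0("group_sizes: ",
                      paste(sprintf("%s=%d", names(config$group_sizes),
                                    config$group_sizes), collapse = " ")),
               paste0("dim: ", paste(config$dim, collapse = "x")),
               paste0("tr_seconds: ", config$tr_seconds),
               paste0("n_timepoints: ", config$n_timepoints),
               paste0("background_weight: ", config$background_weight),
               paste0("group_weights: ",
                      paste(sprintf("%s=%g", names(config$group_weights),
                                    config$group_weights), collapse = " ")),
               paste0("signal_model: ", config$signal_model)),
             file.path(dir, "config.yaml"))
  mf
}
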