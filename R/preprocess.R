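#' Construct a 4-D BOLD volume
#'
#' Thin container for a subject's 4-D scan: the data array indexed
#' (x, y, z, t), a 4x4 voxel-to-mm affine (0-based voxel indices), and the
#' repetition time in seconds.
#'
#' @param data 4-D numeric array.
#' @param affine 4x4 voxel-to-mm transform; by default an isotropic 3-mm
#'   grid centered on the origin.
#' @param tr_seconds repetition time (s).
#' @return an object of class \code{"bold4d"}.
#' @export
bold4d <- function(data, affine = NULL, tr_seconds = 3) {
  stopifnot(is.array(data), length(dim(data)) == 4L, dim(data)[4] >= 2L,
            all(dim(data)[1:3] >= 1L), tr_seconds > 0)
  if (is.null(affine)) affine <- grid_affine(dim(data)[1:3])
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)),
            abs(det(affine)) > 0)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Default voxel-to-mm affine for a synthetic grid
#'
#' Isotropic grid centered on the mm origin: voxel (0,0,0) maps to
#' \code{-(dim - 1) / 2 * pitch}.
#'
#' @param dim length-3 integer grid shape.
#' @param pitch_mm voxel size in mm.
#' @return 4x4 affine matrix.
#' @export
grid_affine <- function(dim, pitch_mm = 3) {
  a <- diag(c(rep(pitch_mm, 3), 1))
  a[1:3, 4] <- -(dim - 1) / 2 * pitch_mm
  a
}

#' Drop initial (dummy) volumes
#'
#' Removes the first \code{n_drop} volumes; affine and TR are unchanged.
#' The study drops the first 10 of 140 volumes, retaining 130.
#'
#' @param vol a [bold4d()] volume.
#' @param n_drop nonnegative integer, strictly less than the number of
#'   volumes.
#' @return the truncated [bold4d()].
#' @export
drop_initial_volumes <- function(vol, n_drop = 10L) {
  stopifnot(inherits(vol, "bold4d"), n_drop >= 0, n_drop == floor(n_drop))
  nt <- dim(vol$data)[4]
  if (n_drop >= nt) stop("'n_drop' must be smaller than the number of volumes")
  if (n_drop == 0L) return(vol)
  bold4d(vol$data[, , , (n_drop + 1):nt, drop = FALSE], vol$affine,
         vol$tr_seconds)
}

#' Remove the linear trend from a time series
#'
#' Residual of the OLS fit of the series on an intercept and the time
#' index; the output has mean (numerically) zero.
#'
#' @param x numeric vector, length >= 3.
#' @return detrended numeric vector.
#' @export
detrend_linear <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 3L) stop("need at least 3 samples to detrend")
  drop(residualize_mat(cbind(x), cbind(1, seq_along(x))))
}

#' Regress nuisance confounds out of a time series
#'
#' OLS residual of the series on an intercept plus the supplied confound
#' columns. The residual is orthogonal to every confound column. An empty
#' confound set reduces to demeaning.
#'
#' @param x numeric vector.
#' @param confounds numeric matrix (or data frame) with one row per
#'   sample, or \code{NULL} for intercept-only.
#' @return residual numeric vector.
#' @export
regress_confounds <- function(x, confounds = NULL) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (is.null(confounds) || NCOL(confounds) == 0L ||
      (is.matrix(confounds) && ncol(confounds) == 0L)) {
    return(x - mean(x))
  }
  cf <- as.matrix(confounds)
  if (nrow(cf) != length(x)) {
    stop("confound rows (", nrow(cf), ") must equal series length (",
         length(x), ")")
  }
  design <- cbind(`(intercept)` = 1, cf)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("degenerate confound design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  drop(residualize_mat(cbind(x), design))
}

#' Zero-phase band-pass filter a time series
#'
#' Order-2 Butterworth band-pass applied forward and backward (zero phase)
#' with odd-symmetric edge extension and steady-state initial conditions.
#' \code{f_high} must not exceed the Nyquist frequency
#' \code{1 / (2 * tr_seconds)}; at TR = 3 s Nyquist is about 0.167 Hz, so
#' the study band 0.01-0.2 Hz must be clipped by the caller (see
#' [preprocess_subject()], which clips and logs).
#'
#' @param x numeric vector.
#' @param tr_seconds sampling interval (s).
#' @param f_low,f_high band edges in Hz; \code{0 <= f_low < f_high <=}
#'   Nyquist. \code{f_low = 0} gives a low-pass.
#' @return filtered numeric vector, same length.
#' @export
bandpass_filter <- function(x, tr_seconds, f_low, f_high) {
  drop(bandpass_mat(cbind(as.numeric(x)), tr_seconds, f_low, f_high))
}

#' Standardize a time series to mean 0, SD 1
#'
#' Uses the population SD (divide by N). A zero-variance series cannot be
#' standardized and raises an error; the pipeline flags such voxels as
#' non-analyzable instead of calling this.
#'
#' @param x numeric vector.
#' @return standardized numeric vector.
#' @export
standardize <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  s <- pop_sd(x)
  if (s <= 0) stop("zero-variance series cannot be standardized")
  (x - mean(x)) / s
}

#' Full temporal preprocessing of one subject
#'
#' Applies, in order: initial-volume dropping, per-voxel linear
#' detrending, nuisance regression, zero-phase band-pass filtering, and
#' per-voxel standardization. Spatial steps (slice timing, realignment,
#' normalization) are assumed done upstream. When the requested upper band
#' edge exceeds Nyquist it is clipped to 0.99 x Nyquist and the clipping is
#' recorded in the run log. Voxels with zero variance or non-finite values
#' are flagged non-analyzable: their series are set to \code{NA} and they
#' are excluded from entropy mapping.
#'
#' @param vol a [bold4d()] volume.
#' @param confounds matrix/data frame of nuisance regressors with one row
#'   per retained volume (after dropping), or \code{NULL}.
#' @param n_drop number of initial volumes to drop (default 10).
#' @param f_low,f_high band edges in Hz (defaults 0.01 and 0.2, the study
#'   band; 0.2 is clipped to 0.99 x Nyquist at TR = 3 s).
#' @param mask optional 3-D logical analysis mask (e.g. a brain mask);
#'   voxels outside it are left as \code{NA} and flagged non-analyzable.
#' @return list with \code{vol} (preprocessed [bold4d()]), \code{mask}
#'   (3-D logical analyzability mask) and \code{log} (list: voxel counts,
#'   band actually applied, whether clipping occurred).
#' @export
preprocess_subject <- function(vol, confounds = NULL, n_drop = 10L,
                               f_low = 0.01, f_high = 0.2, mask = NULL) {
  stopifnot(inherits(vol, "bold4d"))
  d0 <- dim(vol$data)
  if (!is.null(mask) && !identical(dim(mask), d0[1:3])) {
    stop("mask grid does not match the volume grid")
  }
  if (n_drop >= d0[4]) {
    stop("'n_drop' must be smaller than the number of volumes")
  }
  nv <- prod(d0[1:3])
  flat <- matrix(as.numeric(vol$data), nrow = nv, ncol = d0[4])
  in_mask <- if (is.null(mask)) rep(TRUE, nv) else as.logical(mask)
  y <- t(flat[in_mask, , drop = FALSE])  # time x voxel, in-mask only

  pm <- preprocess_mat(y, confounds, n_drop, f_low, f_high,
                       vol$tr_seconds)
  nt <- d0[4] - n_drop
  analyzable_full <- rep(FALSE, nv)
  analyzable_full[which(in_mask)[pm$analyzable]] <- TRUE
  out <- matrix(NA_real_, nv, nt)
  out[analyzable_full, ] <- t(pm$y)
  arr <- array(out, dim = c(d0[1:3], nt))
  list(vol = bold4d(arr, vol$affine, vol$tr_seconds),
       mask = array(analyzable_full, dim = d0[1:3]),
       log = c(list(n_voxels = sum(in_mask),
                    n_non_analyzable = sum(in_mask) - sum(pm$analyzable)),
               pm$log))
}

# Matrix workhorse behind preprocess_subject: y is time x voxel over the
# FULL acquisition (dummies included). Returns the standardized series of
# the analyzable voxels plus the analyzability flags (over input columns).
preprocess_mat <- function(y, confounds, n_drop, f_low, f_high,
                           tr_seconds) {
  if (n_drop > 0) y <- y[(n_drop + 1):nrow(y), , drop = FALSE]
  nt <- nrow(y)
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    if (nrow(cf) != nt) {
      stop("confound rows (", nrow(cf), ") must equal retained volumes (",
           nt, ")")
    }
  } else {
    cf <- NULL
  }

  finite_ok <- colSums(!is.finite(y)) == 0L
  analyzable <- finite_ok
  analyzable[finite_ok] <- matrixStats_colsd(y[, finite_ok, drop = FALSE]) > 0
  ya <- y[, analyzable, drop = FALSE]

  # detrend (intercept + linear term)
  ya <- residualize_mat(ya, cbind(1, seq_len(nt)))
  # nuisance regression (intercept re-included; confounds as supplied)
  if (!is.null(cf) && ncol(cf) > 0) {
    design <- cbind(`(intercept)` = 1, cf)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
      bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
      stop("degenerate confound design; offending columns: ",
           paste(bad, collapse = ", "))
    }
    ya <- residualize_mat(ya, design)
  }
  # band-pass, clipping the upper edge to Nyquist if needed
  nyq <- 1 / (2 * tr_seconds)
  clipped <- f_high > nyq
  fh <- if (clipped) 0.99 * nyq else f_high
  ya <- bandpass_mat(ya, tr_seconds, f_low, fh)

  # standardization is last: every analyzable voxel leaves with SD exactly 1
  ok <- scale_cols_core(ya)
  if (!all(ok)) {
    analyzable[which(analyzable)[!ok]] <- FALSE
    ya <- ya[, ok, drop = FALSE]
  }
  list(y = ya, analyzable = analyzable,
       log = list(band_hz = c(f_low, fh), band_clipped = clipped))
}

# ---- internal helpers -------------------------------------------------

# Residuals of each column of y on the column span of design (via QR).
residualize_mat <- function(y, design) {
  qq <- qr.Q(qr(design))
  y - qq %*% crossprod(qq, y)
}

# Population SD of each column.
matrixStats_colsd <- function(y) {
  mu <- colMeans(y)
  sqrt(colMeans(y^2) - mu^2)
}

# Zero-phase Butterworth band-pass on a time-by-voxel matrix.
bandpass_mat <- function(y, tr_seconds, f_low, f_high) {
  stopifnot(tr_seconds > 0)
  nyq <- 1 / (2 * tr_seconds)
  if (!(f_low >= 0 && f_low < f_high)) stop("need 0 <= f_low < f_high")
  if (f_high > nyq + 1e-12) {
    stop(sprintf("f_high (%g Hz) exceeds Nyquist (%g Hz)", f_high, nyq))
  }
  w <- c(f_low, f_high) / nyq
  if (f_low <= 0) {
    flt <- signal::butter(2, min(w[2], 0.99), type = "low")
  } else {
    flt <- signal::butter(2, c(max(w[1], 1e-4), min(w[2], 0.99)),
                          type = "pass")
  }
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  zi <- lfilter_zi(b, a)
  npad <- 3L * max(length(a), length(b))
  filtfilt_core(b, a, zi, y, npad)
}

# Steady-state initial filter conditions for a unit-amplitude first sample
# (direct-form II transposed), so the forward-backward pass is free of
# start-up transients on constant segments.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  if (nf == 1L) return(numeric(0))
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[-1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  solve(diag(nf - 1) - t(comp), b[-1] - a[-1] * b[1])
}
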