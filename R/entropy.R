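#' Coarse-grain a time series
#'
#' Non-overlapping window averaging: at scale \code{l} the output has
#' \code{floor(N / l)} elements, element \code{j} being the mean of input
#' samples \code{(j-1)*l + 1} to \code{j*l}. Trailing samples that do not
#' fill a complete window are discarded. Scale 1 returns the series
#' unchanged.
#'
#' @param x numeric vector, the time series (all values finite).
#' @param scale positive integer window length.
#' @return numeric vector of length \code{floor(length(x) / scale)}.
#' @export
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)  # 1.5 3.5 5.5
coarse_grain <- function(x, scale) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1 ||
      scale != floor(scale)) {
    stop("'scale' must be a single positive integer")
  }
  scale <- as.integer(scale)
  if (scale > length(x)) stop("'scale' exceeds the series length")
  if (scale == 1L) return(x)
  n_win <- length(x) %/% scale
  colMeans(matrix(x[seq_len(n_win * scale)], nrow = scale))
}

#' Sample entropy of a time series
#'
#' Counts ordered template pairs (i, j), i != j, with templates starting at
#' i = 1 .. N - m for both the length-m and length-(m+1) counts, matching
#' under the Chebyshev (max-norm) distance with inclusive tolerance
#' \code{r_abs}. Self-matches are excluded. The entropy is
#' \code{-log(a_count / b_count)}; when either count is zero the entropy is
#' undefined and returned as \code{NA} (never coerced to 0).
#'
#' @param x numeric vector with \code{length(x) > m + 1}.
#' @param m template length (positive integer).
#' @param r_abs absolute amplitude tolerance (already scaled by the
#'   reference SD; for a unit-SD series \code{r_abs} equals the relative
#'   tolerance r).
#' @return an object of class \code{"sampen"}: list with \code{se} (the
#'   entropy, \code{NA} when undefined), \code{a_count} and \code{b_count}.
#' @export
sample_entropy <- function(x, m, r_abs) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    stop("'m' must be a single positive integer")
  }
  if (!is.numeric(r_abs) || length(r_abs) != 1L || r_abs <= 0) {
    stop("'r_abs' must be a single positive number")
  }
  if (length(x) <= m + 1) stop("series too short: need length(x) > m + 1")
  res <- sampen_core(as.numeric(x), as.integer(m), as.numeric(r_abs))
  structure(res, class = "sampen")
}

#' @export
print.sampen <- function(x, ...) {
  cat("Sample entropy:",
      if (is.na(x$se)) "undefined (zero match count)" else format(x$se),
      sprintf("  [a = %.0f, b = %.0f]\n", x$a_count, x$b_count))
  invisible(x)
}

#' MSE estimator parameters
#'
#' Bundles the template length m, the similarity radius r (as a fraction of
#' the original series' SD) and the scale list. The study default is
#' \code{m = 2, r = 0.35}, scales 1-6; the full parameter grid explored is
#' available via [mse_param_grid()].
#'
#' @param m template length, a positive integer.
#' @param r similarity radius in units of the original series' SD,
#'   in (0, 1).
#' @param scales distinct, sorted positive integer scale factors.
#' @return an object of class \code{"mse_params"}.
#' @export
mse_params <- function(m = 2L, r = 0.35, scales = 1:6) {
  stopifnot(length(m) == 1L, m >= 1, m == floor(m))
  if (!(length(r) == 1L && r > 0 && r < 1)) stop("'r' must lie in (0, 1)")
  scales <- as.integer(scales)
  if (length(scales) < 1L || any(scales < 1L) || anyDuplicated(scales) ||
      is.unsorted(scales)) {
    stop("'scales' must be distinct, sorted positive integers")
  }
  structure(list(m = as.integer(m), r = r, scales = scales),
            class = "mse_params")
}

#' The (m, r) parameter grid of the study
#'
#' Six pairs: (2, 0.15), (2, 0.25), (2, 0.30), (2, 0.35), (1, 0.25),
#' (1, 0.35); (2, 0.35) is the default pair reported throughout.
#'
#' @param scales scale factors attached to each pair.
#' @return list of [mse_params()] objects.
#' @export
mse_param_grid <- function(scales = 1:6) {
  pairs <- list(c(2, 0.15), c(2, 0.25), c(2, 0.30), c(2, 0.35),
                c(1, 0.25), c(1, 0.35))
  lapply(pairs, function(p) mse_params(m = p[1], r = p[2], scales = scales))
}

#' Multiscale entropy curve of a single series
#'
#' For each scale the series is coarse-grained and sample entropy computed
#' with the absolute tolerance \code{params$r * sd_ref}, where
#' \code{sd_ref} is the population SD of the original (scale-1) series.
#' The tolerance is fixed from the original series and NOT recomputed from
#' the coarse-grained series. Scales for which
#' \code{floor(N / l) <= m + 1} are rejected and yield \code{NA} entries.
#'
#' @param x numeric vector, the time series.
#' @param params an [mse_params()] object.
#' @return data frame with columns \code{scale}, \code{se}, \code{a_count},
#'   \code{b_count}; class \code{"mse_curve"}.
#' @export
mse_curve <- function(x, params = mse_params()) {
  stopifnot(inherits(params, "mse_params"), is.numeric(x), all(is.finite(x)))
  sd_ref <- pop_sd(x)
  if (sd_ref <= 0) stop("series has zero variance; entropy is undefined")
  r_abs <- params$r * sd_ref
  rows <- lapply(params$scales, function(l) {
    n_l <- length(x) %/% l
    if (l > length(x) || n_l <= params$m + 1) {
      return(data.frame(scale = l, se = NA_real_,
                        a_count = NA_real_, b_count = NA_real_))
    }
    y <- coarse_grain(x, l)
    r <- sampen_core(y, params$m, r_abs)
    data.frame(scale = l, se = r$se, a_count = r$a_count, b_count = r$b_count)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mse_curve", "data.frame")
  out
}

#' Sample entropy for m = 1 and m = 2 in one pass
#'
#' Identical conventions to [sample_entropy()], but both template lengths
#' are counted in a single sweep over template pairs — useful for long
#' series where a second sweep would double the cost.
#'
#' @inheritParams sample_entropy
#' @return data frame with columns \code{m}, \code{se}, \code{a_count},
#'   \code{b_count} (rows m = 1 and m = 2).
#' @export
sample_entropy_m12 <- function(x, r_abs) {
  stopifnot(is.numeric(x), all(is.finite(x)), length(x) > 3L, r_abs > 0)
  cts <- sampen_m12_core(as.numeric(x), as.numeric(r_abs))
  se <- function(a, b) if (a > 0 && b > 0) -log(a / b) else NA_real_
  data.frame(m = 1:2,
             se = c(se(cts$a1, cts$b1), se(cts$a2, cts$b2)),
             a_count = c(cts$a1, cts$a2),
             b_count = c(cts$b1, cts$b2))
}

#' Large-N sample entropy of Gaussian white noise (closed form)
#'
#' For i.i.d. Gaussian samples the per-coordinate template-match
#' probability at tolerance r (in units of the SD) is
#' \code{P(|X - Y| <= r*sigma) = erf(r / 2)} because
#' \code{X - Y ~ Normal(0, 2 sigma^2)}; coordinates are independent, so the
#' conditional probability of extending a match by one coordinate is again
#' \code{erf(r / 2)} and the sample entropy converges to
#' \code{-log(erf(r / 2))} for every m. Used as an analytic reference for
#' the estimator.
#'
#' @param r tolerance as a fraction of the SD, in (0, 1).
#' @return the limiting sample entropy.
#' @export
analytic_white_noise_se <- function(r) {
  if (!is.numeric(r) || any(r <= 0)) stop("'r' must be positive")
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  -log(erf(r / 2))
}

# Population SD (divide by N), the convention used both for the
# standardization step and the tolerance reference.
pop_sd <- function(x) {
  sqrt(sum((x - mean(x))^2) / length(x))
}
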