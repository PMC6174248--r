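#' Covariate-adjusted voxelwise ANOVA
#'
#' Per voxel, the general-linear-model partial F for the group factor:
#' the full design [intercept, covariates, group dummies] is compared to
#' the reduced design [intercept, covariates]. p-values come from the F
#' distribution with (g - 1, n - g - c) degrees of freedom. Voxels
#' missing (\code{NA}) in any subject are missing in the output maps.
#'
#' @param secohort an \code{mse_cohort} object (see [run_study_mse()]).
#' @param scale which scale's maps to analyze.
#' @param covariates character vector of manifest columns to adjust for.
#' @return an object of class \code{"mse_anova"}: F map, p map (3-D
#'   arrays), degrees of freedom, and the projection pieces needed for
#'   permutation inference.
#' @export
voxelwise_anova <- function(secohort, scale,
                            covariates = c("age", "sex", "education")) {
  stopifnot(inherits(secohort, "mse_cohort"))
  s <- match(scale, secohort$scales)
  if (is.na(s)) stop("scale ", scale, " not present in the cohort maps")
  y <- secohort$se[, , s]                       # voxels x subjects
  mf <- secohort$manifest
  group <- factor(mf$group)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop("need at least two groups with at least two subjects each")
  }
  keep <- rowSums(is.na(y)) == 0L               # complete voxels only
  yv <- t(y[keep, , drop = FALSE])              # subjects x voxels
  n <- nrow(yv)

  x_red <- cbind(`(intercept)` = rep(1, n))
  for (cv in covariates) x_red <- cbind(x_red, mf[[cv]])
  colnames(x_red) <- c("(intercept)", covariates)
  x_full <- cbind(x_red, stats::model.matrix(~group)[, -1, drop = FALSE])
  qr_full <- qr(x_full)
  if (qr_full$rank < ncol(x_full)) {
    bad <- colnames(x_full)[qr_full$pivot[(qr_full$rank + 1):ncol(x_full)]]
    stop("degenerate design; offending columns: ", paste(bad, collapse = ", "))
  }
  q_red <- qr.Q(qr(x_red))
  q_full <- qr.Q(qr_full)
  df1 <- nlevels(group) - 1L
  df2 <- n - ncol(x_full)

  r_red <- yv - q_red %*% crossprod(q_red, yv)  # reduced-model residuals
  fstat <- partial_f(r_red, q_red, q_full, df1, df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  dim3 <- dim(secohort$mask)
  fmap <- array(NA_real_, dim3)
  pmap <- array(NA_real_, dim3)
  vox <- secohort$vox_index[keep]
  fmap[vox] <- fstat
  pmap[vox] <- pval
  structure(list(fmap = fmap, pmap = pmap, df = c(df1, df2),
                 fstat = fstat, pval = pval, vox_index = vox,
                 r_red = r_red, q_red = q_red, q_full = q_full,
                 affine = secohort$affine, dim = dim3, scale = scale,
                 group = group, covariates = covariates),
            class = "mse_anova")
}

# Partial F of the group factor for each column of y (y already reduced-
# model residuals, so the reduced-model RSS is just colSums(y^2)).
partial_f <- function(y, q_red, q_full, df1, df2) {
  rss_red <- colSums(y^2) - colSums(crossprod(q_red, y)^2)
  rss_full <- colSums(y^2) - colSums(crossprod(q_full, y)^2)
  pmax(0, (rss_red - rss_full) / df1) / pmax(.Machine$double.eps,
                                             rss_full / df2)
}

#' Permutation-based cluster-level correction
#'
#' Supra-threshold voxels (p below \code{voxel_p}) are grouped into
#' face-connected (6-connectivity) clusters. The null distribution of the
#' maximum cluster size is built by Freedman-Lane residual permutation:
#' reduced-model residuals are row-permuted (covariates held fixed) and
#' the partial F recomputed for each of \code{n_perm} permutations. A
#' cluster survives when its permutation p-value
#' \code{(1 + #(null max >= size)) / (n_perm + 1)} is at most
#' \code{cluster_p}. This permutation scheme replaces Gaussian-random-
#' field theory while keeping the same voxel-threshold + cluster-threshold
#' structure.
#'
#' @param anova_res an [voxelwise_anova()] result.
#' @param voxel_p voxelwise threshold (default 0.001).
#' @param cluster_p cluster-level threshold (default 0.05).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return an object of class \code{"cluster_result"}: \code{table} (data
#'   frame: cluster id, voxel count, peak mm coordinates, peak F,
#'   corrected p), \code{labels} (3-D integer array of surviving
#'   clusters), \code{null_max_size}, and the thresholds used. Zero rows
#'   when nothing survives (a valid outcome).
#' @export
cluster_correct <- function(anova_res, voxel_p = 0.001, cluster_p = 0.05,
                            n_perm = 500L, seed = 1L) {
  stopifnot(inherits(anova_res, "mse_anova"), n_perm >= 100L)
  df1 <- anova_res$df[1]
  df2 <- anova_res$df[2]
  f_crit <- stats::qf(1 - voxel_p, df1, df2)
  dim3 <- anova_res$dim
  vox <- anova_res$vox_index

  null_max <- integer(n_perm)
  set.seed(seed)
  n <- nrow(anova_res$r_red)
  for (b in seq_len(n_perm)) {
    fp <- partial_f(anova_res$r_red[sample.int(n), , drop = FALSE],
                    anova_res$q_red, anova_res$q_full, df1, df2)
    null_max[b] <- max_cluster_size(fp > f_crit, vox, dim3)
  }

  supra <- array(FALSE, dim3)
  supra[vox] <- anova_res$fstat > f_crit
  labels <- label_clusters_core(supra, dim3)
  sizes <- tabulate(labels[labels > 0])
  out_lab <- array(0L, dim3)
  rows <- list()
  keep_id <- 0L
  for (cl in seq_along(sizes)) {
    p_corr <- (1 + sum(null_max >= sizes[cl])) / (n_perm + 1)
    if (p_corr <= cluster_p) {
      members <- which(labels == cl)
      peak <- members[which.max(anova_res$fmap[members])]
      ijk <- arrayInd(peak, dim3) - 1L
      mm <- drop(anova_res$affine %*% c(ijk, 1))[1:3]
      keep_id <- keep_id + 1L
      out_lab[members] <- keep_id
      rows[[keep_id]] <- data.frame(
        cluster = keep_id, n_voxels = sizes[cl],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_f = anova_res$fmap[peak], p_corrected = p_corr)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n_voxels = integer(0),
               peak_x = numeric(0), peak_y = numeric(0),
               peak_z = numeric(0), peak_f = numeric(0),
               p_corrected = numeric(0))
  structure(list(table = tab, labels = out_lab, null_max_size = null_max,
                 f_crit = f_crit, voxel_p = voxel_p, cluster_p = cluster_p,
                 n_perm = n_perm, seed = seed, scale = anova_res$scale),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> scale %s: %d surviving cluster(s), voxel p < %g, cluster p < %g, %d permutations\n",
              x$scale, nrow(x$table), x$voxel_p, x$cluster_p, x$n_perm))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

max_cluster_size <- function(supra_vec, vox, dim3) {
  arr <- array(FALSE, dim3)
  arr[vox] <- supra_vec
  lab <- label_clusters_core(arr, dim3)
  m <- lab[lab > 0L]
  if (length(m) == 0L) 0L else max(tabulate(m))
}

#' Group-stratified fivefold split
#'
#' Deals subjects of each group into five folds with a round-robin
#' pointer that continues across groups, so fold totals are balanced
#' (124 subjects give folds of 24/25) while every group appears in every
#' fold. Deterministic given the seed.
#'
#' @param manifest cohort manifest data frame (columns \code{id},
#'   \code{group}).
#' @param seed RNG seed.
#' @param k number of folds.
#' @return integer vector of fold assignments (1..k), one per row.
#' @export
fivefold_split <- function(manifest, seed = 1L, k = 5L) {
  stopifnot(nrow(manifest) >= 2L * k)
  group <- factor(manifest$group)
  if (any(table(group) < k)) {
    warning("a group has fewer subjects than folds; fold sizes rebalanced")
  }
  set.seed(seed)
  fold <- integer(nrow(manifest))
  ptr <- 0L
  for (g in levels(group)) {
    members <- sample(which(group == g))
    for (m in members) {
      fold[m] <- (ptr %% k) + 1L
      ptr <- ptr + 1L
    }
  }
  fold
}

#' Fivefold cross-validated ROI selection
#'
#' For each fold, ANOVA plus cluster correction is run on the other four
#' folds; the peaks of surviving clusters become 8-mm sphere ROIs, and the
#' held-out fold supplies the ROI entropy values for downstream tests.
#'
#' @param secohort an \code{mse_cohort}.
#' @param scale scale to analyze.
#' @param voxel_p,cluster_p,n_perm,seed as in [cluster_correct()].
#' @param radius_mm ROI sphere radius (default 8, the study value).
#' @param covariates manifest columns to adjust for.
#' @return list with one element per fold: \code{fold} (held-out row
#'   indices), \code{rois} (list of [roi_spec()]), \code{values} (data
#'   frame of held-out subjects x ROI means, long format), plus a pooled
#'   \code{values} table across folds as attribute \code{"pooled"}.
#' @export
fivefold_roi_selection <- function(secohort, scale, voxel_p = 0.001,
                                   cluster_p = 0.05, n_perm = 200L,
                                   seed = 1L, radius_mm = 8,
                                   covariates = c("age", "sex",
                                                  "education")) {
  stopifnot(inherits(secohort, "mse_cohort"),
            nrow(secohort$manifest) >= 10L)
  fold <- fivefold_split(secohort$manifest, seed = seed)
  res <- vector("list", 5L)
  for (f in 1:5) {
    train <- which(fold != f)
    test <- which(fold == f)
    sub <- subset_cohort(secohort, train)
    av <- voxelwise_anova(sub, scale, covariates)
    cc <- cluster_correct(av, voxel_p, cluster_p, n_perm,
                          seed = seed + f)
    rois <- list()
    vals <- NULL
    if (nrow(cc$table) > 0) {
      rois <- lapply(seq_len(nrow(cc$table)), function(i) {
        roi_spec(sprintf("fold%d_cluster%d", f, i),
                 c(cc$table$peak_x[i], cc$table$peak_y[i],
                   cc$table$peak_z[i]), radius_mm)
      })
      vals <- do.call(rbind, lapply(rois, function(roi) {
        v <- cohort_roi_means(secohort, roi, scale)[test]
        data.frame(fold = f, roi = roi$name,
                   id = secohort$manifest$id[test],
                   group = secohort$manifest$group[test], mse = v)
      }))
    }
    res[[f]] <- list(fold = test, rois = rois, values = vals)
  }
  pooled <- do.call(rbind, lapply(res, `[[`, "values"))
  attr(res, "pooled") <- pooled
  res
}

#' Bonferroni post-hoc pairwise tests on ROI values
#'
#' Two-sample pooled-variance t tests on covariate-adjusted residuals for
#' all group pairs; raw p-values are multiplied by the number of pairs
#' (6 for four groups) and capped at 1. Pairs where either group has
#' fewer than two values are skipped with a flag.
#'
#' @param values numeric vector of ROI entropy values.
#' @param group factor of group labels, same length.
#' @param covariates optional data frame / matrix of covariates to adjust
#'   out before testing.
#' @return data frame: \code{pair}, \code{mean_diff}, \code{t},
#'   \code{df}, \code{p}, \code{p_bonferroni}, \code{skipped}.
#' @export
posthoc_pairwise <- function(values, group, covariates = NULL) {
  group <- droplevels(factor(group))
  stopifnot(length(values) == length(group))
  adj <- if (is.null(covariates)) values - mean(values) else
    drop(residualize_mat(cbind(values),
                         cbind(1, as.matrix(covariates))))
  pairs <- utils::combn(levels(group), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    g1 <- adj[group == pairs[1, i]]
    g2 <- adj[group == pairs[2, i]]
    if (length(g1) < 2L || length(g2) < 2L) {
      return(data.frame(pair = paste(pairs[, i], collapse = " vs "),
                        mean_diff = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, p_bonferroni = NA_real_,
                        skipped = TRUE))
    }
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    data.frame(pair = paste(pairs[, i], collapse = " vs "),
               mean_diff = mean(g1) - mean(g2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs),
               skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of ROI entropy with a clinical score
#'
#' Spearman's rho with average ranks for ties and a two-sided p-value
#' (asymptotic, so tied scores are handled). A constant score vector has
#' undefined rho and is flagged.
#'
#' @param mse numeric vector of ROI entropy values.
#' @param score numeric vector of clinical scores, same length.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{defined}.
#' @export
spearman_clinical <- function(mse, score) {
  keep <- is.finite(mse) & is.finite(score)
  mse <- mse[keep]
  score <- score[keep]
  if (length(mse) < 5L) stop("need at least 5 paired observations")
  if (stats::sd(score) == 0 || stats::sd(mse) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(mse),
                defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(mse, score, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(mse),
       defined = TRUE)
}

#' Correlation table of ROI entropy against clinical scores
#'
#' One Spearman correlation per (ROI, score); p-values are adjusted
#' within each score's family across ROIs (Benjamini-Hochberg by default,
#' Bonferroni optionally).
#'
#' @param roi_values data frame with columns \code{roi} and \code{mse}
#'   plus one column per score named in \code{scores}, one row per
#'   (subject, ROI).
#' @param scores character vector of score column names.
#' @param method \code{"BH"} (default) or \code{"bonferroni"}.
#' @return data frame: \code{roi}, \code{score}, \code{rho}, \code{p},
#'   \code{p_adjusted}, \code{n}.
#' @export
clinical_correlations <- function(roi_values,
                                  scores = c("MMSE", "FAQ", "CDR"),
                                  method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  rows <- list()
  for (sc in scores) {
    per_roi <- lapply(split(roi_values, roi_values$roi), function(d) {
      r <- spearman_clinical(d$mse, d[[sc]])
      data.frame(roi = d$roi[1], score = sc, rho = r$rho, p = r$p,
                 n = r$n)
    })
    fam <- do.call(rbind, per_roi)
    fam$p_adjusted <- stats::p.adjust(fam$p, method = method)
    rows[[sc]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
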