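test_that("the voxelwise partial F reduces to the squared two-sample t without covariates", {
  set.seed(20)
  nv <- 12
  vals <- matrix(rnorm(nv * 20), nv, 20)
  g <- rep(c("NC", "AD"), each = 10)
  sec <- fake_secohort(vals, g)
  av <- voxelwise_anova(sec, 1, covariates = character(0))
  for (v in 1:nv) {
    tt <- t.test(vals[v, g == "NC"], vals[v, g == "AD"], var.equal = TRUE)
    expect_equal(av$fstat[v], unname(tt$statistic)^2, tolerance = 1e-8)
  }
  expect_true(all(av$fstat >= 0))
  expect_identical(av$df, c(1L, 18L))
})

test_that("the covariate-adjusted F matches lm-based partial F-tests voxel by voxel", {
  set.seed(21)
  ns <- 36
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 9))
  age <- rnorm(ns, 73, 7); sex <- rbinom(ns, 1, 0.5); edu <- rnorm(ns, 16, 2)
  vals <- matrix(rnorm(10 * ns), 10, ns)
  vals[1, ] <- vals[1, ] + 0.1 * age   # voxel with covariate structure
  sec <- fake_secohort(vals, g, age = age, sex = sex, education = edu)
  av <- voxelwise_anova(sec, 1)
  for (v in c(1, 4, 9)) {
    y <- vals[v, ]
    full <- lm(y ~ age + sex + edu + g)
    red <- lm(y ~ age + sex + edu)
    ref <- anova(red, full)
    expect_equal(av$fstat[v], ref$F[2], tolerance = 1e-8)
    expect_equal(av$pval[v], ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
  expect_identical(av$df, c(3L, as.integer(ns) - 7L))
})

test_that("null p-values are uniform and a covariate-only voxel has F near zero", {
  set.seed(22)
  ns <- 40
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 10))
  vals <- matrix(rnorm(2000 * ns), 2000, ns)
  sec <- fake_secohort(vals, g)
  av <- voxelwise_anova(sec, 1)
  ks <- ks.test(av$pval, "punif")
  expect_gt(ks$p.value, 0.01)
  # identical group means, variance fully explained by a covariate
  age <- rep(seq(60, 80, length.out = 10), 4)
  y <- 2 * age
  sec2 <- fake_secohort(rbind(y, y + 5), g, age = age)
  av2 <- voxelwise_anova(sec2, 1, covariates = "age")
  expect_lt(max(av2$fstat), 1e-2)
})

test_that("permutation cluster correction keeps planted blocks and rejects lone voxels", {
  set.seed(23)
  d3 <- c(8, 8, 8)
  nv <- prod(d3)
  ns <- 40
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 10))
  vals <- matrix(rnorm(nv * ns), nv, ns)
  block <- array(FALSE, d3); block[3:5, 3:5, 3:5] <- TRUE
  shift <- (as.integer(g) - 2.5) * 1.2
  vals[which(block), ] <- vals[which(block), ] +
    matrix(shift, sum(block), ns, byrow = TRUE)
  sec <- fake_secohort(vals, g, dim3 = d3)
  av <- voxelwise_anova(sec, 1)
  cc <- cluster_correct(av, n_perm = 200, seed = 5)
  expect_gt(nrow(cc$table), 0)
  surv <- which(cc$labels > 0)
  expect_gt(length(intersect(surv, which(block))), 0.5 * sum(block))
  # peak voxel carries the maximal F within its cluster
  top <- cc$table[which.max(cc$table$n_voxels), ]
  expect_equal(top$peak_f, max(av$fmap[cc$labels == top$cluster]))

  # a lone supra-threshold voxel should not survive cluster correction
  vals_lone <- matrix(rnorm(nv * ns), nv, ns)
  vals_lone[100, ] <- vals_lone[100, ] + shift * 2
  sec_l <- fake_secohort(vals_lone, g, dim3 = d3)
  cc_l <- cluster_correct(voxelwise_anova(sec_l, 1), n_perm = 200, seed = 6)
  expect_false(any(cc_l$table$n_voxels == 1))
  # permutation null is reproducible under a fixed seed
  cc_l2 <- cluster_correct(voxelwise_anova(sec_l, 1), n_perm = 200, seed = 6)
  expect_identical(cc_l$null_max_size, cc_l2$null_max_size)
})

test_that("stratified fivefold folds are balanced, complete and seed-stable", {
  mf <- cohort_manifest(cohort_config(seed = 2))
  f1 <- fivefold_split(mf, seed = 9)
  f2 <- fivefold_split(mf, seed = 9)
  expect_identical(f1, f2)
  sizes <- as.integer(table(f1))
  expect_true(all(sizes %in% c(24L, 25L)))
  for (k in 1:5) {
    expect_identical(sort(unique(as.character(mf$group[f1 == k]))),
                     sort(levels(mf$group)))
  }
  small <- mf[c(1:3, 31:40, 64:75, 96:110), ]
  expect_warning(fivefold_split(small, seed = 1), "rebalanced")
})

test_that("fivefold ROI selection trains on four folds and scores the fifth", {
  set.seed(24)
  d3 <- c(8, 8, 8)
  nv <- prod(d3)
  ns <- 60
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 15))
  vals <- matrix(rnorm(nv * ns), nv, ns)
  block <- array(FALSE, d3); block[3:5, 3:5, 3:5] <- TRUE
  shift <- (as.integer(g) - 2.5) * 1.5
  vals[which(block), ] <- vals[which(block), ] +
    matrix(shift, sum(block), ns, byrow = TRUE)
  sec <- fake_secohort(vals, g, dim3 = d3)
  res <- fivefold_roi_selection(sec, 1, n_perm = 120, seed = 4)
  expect_length(res, 5L)
  fold <- fivefold_split(sec$manifest, seed = 4)
  found <- FALSE
  for (f in 1:5) {
    expect_identical(res[[f]]$fold, which(fold == f))
    if (!is.null(res[[f]]$values)) {
      found <- TRUE
      expect_true(all(res[[f]]$values$id %in%
                        sec$manifest$id[fold == f]))
    }
  }
  expect_true(found)  # the planted block is selectable from training folds
  pooled <- attr(res, "pooled")
  expect_true(is.data.frame(pooled) && nrow(pooled) > 0)
})

test_that("post-hoc pairwise tests are Bonferroni-capped and detect planted order", {
  set.seed(25)
  g <- factor(rep(c("NC", "EMCI", "LMCI", "AD"), each = 12),
              levels = c("NC", "EMCI", "LMCI", "AD"))
  same <- rep(rnorm(12), 4)
  tab0 <- posthoc_pairwise(same, g)
  expect_identical(nrow(tab0), 6L)
  expect_true(all(tab0$p_bonferroni == 1))
  vals <- rnorm(48, mean = c(4, 3, 2, 1)[as.integer(g)], sd = 0.5)
  tab <- posthoc_pairwise(vals, g)
  expect_true(all(tab$p_bonferroni >= tab$p))
  nc_ad <- tab[tab$pair == "NC vs AD", ]
  expect_lt(nc_ad$p_bonferroni, 0.05)
  expect_gt(nc_ad$mean_diff, 0)
  # tiny group is skipped with a flag
  g2 <- factor(c(rep("NC", 12), "AD"), levels = c("NC", "AD"))
  tab2 <- posthoc_pairwise(c(rnorm(12), 1), g2)
  expect_true(tab2$skipped[1])
})

test_that("Spearman correlations match the hand oracle and flag degeneracy", {
  r1 <- spearman_clinical(1:10, (1:10)^3)
  expect_equal(r1$rho, 1)
  hand <- spearman_clinical(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_equal(hand$rho, 0.9)
  expect_equal(hand$rho, spearman_by_ranks(c(1, 2, 3, 4, 5),
                                           c(1, 2, 3, 5, 4)))
  const <- spearman_clinical(rnorm(10), rep(2, 10))
  expect_false(const$defined)
  expect_true(is.na(const$rho))
  expect_error(spearman_clinical(1:3, 3:1), "at least 5")
})

test_that("correlation families are adjusted monotonically within each score", {
  set.seed(26)
  n <- 30
  rois <- rep(c("r1", "r2", "r3", "r4"), each = n)
  base <- rnorm(4 * n)
  df <- data.frame(roi = rois, mse = base,
                   MMSE = base * c(1, 0.5, 0.1, 0)[as.integer(factor(rois))] +
                     rnorm(4 * n, 0, 1),
                   FAQ = rnorm(4 * n), CDR = rnorm(4 * n))
  out <- clinical_correlations(df)
  expect_true(all(out$p_adjusted >= out$p - 1e-12))
  for (sc in unique(out$score)) {
    fam <- out[out$score == sc, ]
    ord <- order(fam$p)
    expect_true(all(diff(fam$p_adjusted[ord]) >= -1e-12))
  }
  bon <- clinical_correlations(df, method = "bonferroni")
  expect_true(all(bon$p_adjusted >= out$p_adjusted - 1e-12))
})
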