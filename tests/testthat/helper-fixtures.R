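# Small cohort configuration for unit tests: default study conditions on
# a reduced subject count so single tests stay fast. The generator's
# effect sizes and couplings are the package defaults.
tiny_cohort_config <- function(per_group = 3L, seed = 1L, ...) {
  cohort_config(group_sizes = c(NC = per_group, EMCI = per_group,
                                LMCI = per_group, AD = per_group),
                seed = seed, ...)
}

# Hand-built entropy cohort for the statistics tests: values is a
# voxels x subjects matrix placed on a small grid (single scale).
fake_secohort <- function(values, group, dim3 = NULL, scale = 1L,
                          age = NULL, sex = NULL, education = NULL) {
  nv <- nrow(values)
  ns <- ncol(values)
  if (is.null(dim3)) {
    nx <- ceiling(nv^(1 / 3))
    dim3 <- c(nx, nx, ceiling(nv / nx^2))
    while (prod(dim3) < nv) dim3[3] <- dim3[3] + 1L
  }
  se <- array(NA_real_, dim = c(nv, ns, 1L))
  se[, , 1] <- values
  mask <- array(FALSE, dim3)
  mask[seq_len(nv)] <- TRUE
  mf <- data.frame(id = sprintf("s%03d", seq_len(ns)),
                   group = factor(group),
                   age = if (is.null(age)) rep(70, ns) + seq_len(ns) %% 7 else age,
                   sex = if (is.null(sex)) seq_len(ns) %% 2 else sex,
                   education = if (is.null(education)) rep(16, ns) - seq_len(ns) %% 5 else education,
                   MMSE = rep(25, ns), FAQ = rep(5, ns), CDR = rep(0.5, ns),
                   seed = seq_len(ns), path = NA_character_)
  structure(list(se = se, vox_index = which(mask), mask = mask,
                 affine = grid_affine(dim3),
                 scales = as.integer(scale),
                 params = mse_params(scales = as.integer(scale)),
                 manifest = mf,
                 n_undefined = matrix(0L, ns, 1L), config = NULL),
            class = "mse_cohort")
}
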