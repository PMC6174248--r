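make_vol <- function(dim3 = c(6, 6, 6), nt = 140, seed = 1, tr = 3) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dim3) * nt), dim = c(dim3, nt)), tr_seconds = tr)
}

test_that("initial-volume dropping truncates time only", {
  v <- make_vol(nt = 140)
  d <- drop_initial_volumes(v, 10)
  expect_identical(dim(d$data)[4], 130L)
  expect_identical(d$affine, v$affine)
  expect_identical(d$data[, , , 1], v$data[, , , 11])
  expect_identical(drop_initial_volumes(v, 0), v)
  v5 <- make_vol(nt = 5)
  expect_error(drop_initial_volumes(v5, 5), "smaller")
})

test_that("linear detrending removes exact linear signals and is idempotent in slope", {
  t <- 1:100
  expect_equal(detrend_linear(2 * t + 1), rep(0, 100), tolerance = 1e-10)
  expect_equal(detrend_linear(rep(3.7, 50)), rep(0, 50), tolerance = 1e-10)
  x <- sin(t / 5) + 0.5 * t
  r <- detrend_linear(x)
  refit <- coef(lm(r ~ t))
  expect_equal(unname(refit[2]), 0, tolerance = 1e-10)
  expect_equal(mean(r), 0, tolerance = 1e-10)
})

test_that("confound regression produces residuals orthogonal to the design", {
  set.seed(2)
  n <- 130
  cf <- cbind(drift = cumsum(rnorm(n)), card = sin(1:n / 4))
  # series equal to one confound column vanishes
  expect_equal(regress_confounds(cf[, 1], cf), rep(0, n), tolerance = 1e-8)
  # empty confound set is plain demeaning
  x <- rnorm(n)
  expect_equal(regress_confounds(x, NULL), x - mean(x))
  # constructed orthogonal confounds leave the demeaned series untouched
  xo <- x - mean(x)
  qx <- qr.Q(qr(cbind(1, xo)))
  co <- cf - qx %*% crossprod(qx, cf)
  expect_equal(regress_confounds(x, co), xo, tolerance = 1e-8)
  # general case: residual orthogonal to every column
  r <- regress_confounds(x, cf)
  expect_lt(max(abs(crossprod(scale(cf), r))) / n, 1e-8)
  # rank-deficient design names the offending column
  bad <- cbind(a = cf[, 1], b = 2 * cf[, 1])
  expect_error(regress_confounds(x, bad), "degenerate.*b")
})

test_that("band-pass keeps in-band power and suppresses out-of-band power", {
  tt <- (0:129) * 3
  pw <- function(v, f) abs(sum(v * exp(-2i * pi * f * tt)))^2
  x_in <- sin(2 * pi * 0.05 * tt)
  y_in <- bandpass_filter(x_in, 3, 0.01, 0.15)
  expect_gt(pw(y_in, 0.05) / pw(x_in, 0.05), 0.9)
  x_out <- sin(2 * pi * 0.005 * tt)
  y_out <- bandpass_filter(x_out, 3, 0.01, 0.15)
  expect_lt(pw(y_out, 0.005) / pw(x_out, 0.005), 0.1)
  expect_identical(bandpass_filter(rep(0, 130), 3, 0.01, 0.15), rep(0, 130))
  expect_error(bandpass_filter(x_in, 3, 0.01, 0.2), "Nyquist")
  expect_error(bandpass_filter(x_in, 3, 0.1, 0.05), "f_low")
})

test_that("standardization yields mean 0 / population SD 1 and rejects constants", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  expect_equal(standardize(z), z, tolerance = 1e-10)
  expect_error(standardize(rep(2, 10)), "zero-variance")
})

test_that("the preprocessing chain is deterministic, drop-invariant and unit-SD", {
  v <- make_vol(nt = 130, seed = 9)
  set.seed(10)
  conf <- matrix(rnorm(130 * 3), 130, 3,
                 dimnames = list(NULL, c("g", "m1", "m2")))
  # leak confounds into every voxel so regression has work to do
  leak <- v
  flat <- matrix(as.numeric(v$data), prod(dim(v$data)[1:3]), 130)
  set.seed(11)
  flat <- flat + t(conf %*% matrix(rnorm(3 * nrow(flat), 0, 0.4), 3,
                                   nrow(flat)))
  leak$data <- array(flat, dim = dim(v$data))

  p1 <- preprocess_subject(leak, conf, n_drop = 0)
  p2 <- preprocess_subject(leak, conf, n_drop = 0)
  expect_identical(p1$vol$data, p2$vol$data)  # byte-determinism

  # dummy volumes: prepending 10 offset volumes then dropping them is a no-op
  with_dummy <- array(0, dim = c(dim(v$data)[1:3], 140))
  with_dummy[, , , 11:140] <- leak$data
  with_dummy[, , , 1:10] <- leak$data[, , , 1:10] + 1000
  pd <- preprocess_subject(bold4d(with_dummy, leak$affine, 3), conf,
                           n_drop = 10)
  expect_equal(pd$vol$data, p1$vol$data, tolerance = 1e-12)

  # every analyzable voxel leaves with SD exactly 1
  out <- matrix(as.numeric(p1$vol$data), prod(dim(v$data)[1:3]), 130)
  sds <- apply(out[p1$mask, ], 1, function(z) sqrt(mean(z^2) - mean(z)^2))
  expect_equal(unname(sds), rep(1, sum(p1$mask)), tolerance = 1e-8)

  # band was clipped below Nyquist and logged
  expect_true(p1$log$band_clipped)
  expect_lt(p1$log$band_hz[2], 1 / 6)

  # constant voxel is excluded and counted
  vz <- leak
  vz$data[1, 1, 1, ] <- 4
  pz <- preprocess_subject(vz, conf, n_drop = 0)
  expect_false(pz$mask[1, 1, 1])
  expect_identical(pz$log$n_non_analyzable, 1L)
  expect_true(all(is.na(pz$vol$data[1, 1, 1, ])))
})

test_that("detrend-then-regress equals the joint projection (Frisch-Waugh)", {
  set.seed(4)
  n <- 120
  x <- rnorm(n)
  tt <- seq_len(n)
  conf <- cbind(a = rnorm(n), b = cumsum(rnorm(n)))
  conf_dt <- apply(conf, 2, detrend_linear)
  two_step <- regress_confounds(detrend_linear(x), conf_dt)
  joint <- residuals(lm(x ~ tt + conf))
  expect_equal(two_step, unname(joint), tolerance = 1e-8)
})
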