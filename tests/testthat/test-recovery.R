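# recovery_fit: saturation-recovery model S = M0 (1 - exp(-TR/T1)).

trs <- c(125, 250, 500, 1000, 2000)
model <- function(m0, t1, tr_ms) m0 * (1 - exp(-tr_ms / 1000 / t1))

test_that("noiseless model-consistent input is recovered near machine precision", {
  f <- fit_recovery_voxel(model(1000, 1.2, trs), trs)
  expect_true(f$ok)
  expect_equal(f$m0, 1000, tolerance = 1e-6)
  expect_equal(f$t1_s, 1.2, tolerance = 1e-6)
  expect_lt(f$rms, 1e-8 * f$m0)

  # parameterised over tissue-like and phantom-like truths
  for (tt in list(c(500, 0.9), c(80, 1.3), c(1200, 3.5), c(650, 1.6))) {
    f <- fit_recovery_voxel(model(tt[1], tt[2], trs), trs)
    expect_equal(f$m0, tt[1], tolerance = 1e-6)
    expect_equal(f$t1_s, tt[2], tolerance = 1e-6)
  }
})

test_that("fully recovered (flat) signal pins T1 at the lower bound", {
  f <- fit_recovery_voxel(rep(500, 5), trs)
  expect_equal(f$t1_s, 0.05, tolerance = 1e-4)
  expect_equal(f$m0, 500, tolerance = 0.05)
})

test_that("degenerate voxels are flagged, not fitted", {
  expect_false(fit_recovery_voxel(c(0, 0, 0, 0, 0), trs)$ok)
  expect_false(fit_recovery_voxel(c(-5, -3, -1, -2, -4), trs)$ok)
  expect_false(fit_recovery_voxel(c(1, NA, NA, NA, 2), trs)$ok)
})

test_that("scale equivariance and pair-permutation invariance", {
  set.seed(21)
  for (rep in 1:20) {
    m0 <- runif(1, 100, 2000); t1 <- runif(1, 0.3, 3)
    s <- model(m0, t1, trs)
    base <- fit_recovery_voxel(s, trs)
    k <- runif(1, 0.1, 50)
    scaled <- fit_recovery_voxel(k * s, trs)
    expect_equal(scaled$m0, k * base$m0, tolerance = 1e-9)
    expect_equal(scaled$t1_s, base$t1_s, tolerance = 1e-9)
    p <- sample(5)
    perm <- fit_recovery_voxel(s[p], trs[p])
    expect_equal(perm$m0, base$m0, tolerance = 1e-12)
    expect_equal(perm$t1_s, base$t1_s, tolerance = 1e-12)
  }
})

test_that("bounded least squares matches the exhaustive grid oracle", {
  # 20 noisy voxels here (the acceptance suite runs the full 200)
  set.seed(7)
  for (i in 1:20) {
    m0 <- runif(1, 500, 1500); t1 <- runif(1, 0.6, 2.5)
    s <- model(m0, t1, trs) * (1 + rnorm(5, sd = 0.02))
    fit <- fit_recovery_voxel(s, trs)
    oracle <- grid_fit_oracle(s, trs)
    expect_true(agrees_with_oracle(fit, oracle, s, trs))
  }
})

test_that("volume fit recovers a noiseless subject and respects the mask", {
  s <- noiseless_subject()
  masks <- s$masks
  fit_mask <- masks$brain | masks$blood | Reduce(`|`, masks$phantom)
  fit <- fit_recovery_volume(s$tr_series, fit_mask)
  truth_m0 <- s$truth$gain * s$truth$bias_field * s$truth$wc_map$values
  sel <- fit$m0$fit_mask
  expect_gt(sum(sel), 1000)
  expect_lt(max(abs(fit$m0$values[sel] - truth_m0[sel]) / truth_m0[sel]), 1e-6)
  # out-of-mask voxels are NaN
  expect_true(all(is.nan(fit$m0$values[!fit_mask])))
  expect_error(fit_recovery_volume(s$tr_series, array(FALSE, dim(fit_mask))),
               "empty mask")

  # masking out half the volume leaves that half unfitted
  half <- fit_mask
  half[1:(dim(half)[1] %/% 2), , ] <- FALSE
  fit2 <- fit_recovery_volume(s$tr_series, half)
  expect_true(all(is.nan(fit2$m0$values[fit_mask & !half])))
})

test_that("noisy volume fit error matches first-order error propagation", {
  # Independent oracle: the delta-method SD of the least-squares M0 at the
  # GM operating point.  With TR_max only ~1.5 T1_gm, extrapolating to the
  # asymptote amplifies raw-signal noise by ~1.7x, so the in-mask median
  # relative error at SNR 50 sits near 3.5%, not at the naive 2%.
  s <- noisy_subject()
  fit <- fit_recovery_volume(s$tr_series, s$masks$brain)
  truth_m0 <- s$truth$gain * s$truth$bias_field * s$truth$wc_map$values
  sel <- fit$m0$fit_mask & s$masks$gm
  relerr <- abs(fit$m0$values[sel] - truth_m0[sel]) / truth_m0[sel]

  tr_s <- s$tr_series$tr_ms / 1000
  t1 <- 1.3
  J <- cbind(1 - exp(-tr_s / t1), -exp(-tr_s / t1) * tr_s / t1^2)  # dS/dM0, dS/dT1 at M0=1
  sd_m0 <- sqrt(solve(crossprod(J))[1, 1])       # per unit signal noise, M0=1
  gm_m0 <- median(truth_m0[s$masks$gm])
  pred_median <- qnorm(0.75) * sd_m0 * s$truth$noise_sd / gm_m0
  expect_gt(median(relerr), 0.6 * pred_median)
  expect_lt(median(relerr), 1.5 * pred_median)
})
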