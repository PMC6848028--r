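# bias_field: EM estimation of multiplicative coil inhomogeneity.

make_uniform_sixmode <- function(dims = c(30L, 28L, 10L), seed = 31L,
                                 mode_sd = 0.01) {
  # spatially unstructured image whose histogram has six well-separated
  # modes: any apparent "field" would be pure overfitting
  set.seed(seed)
  n <- prod(dims)
  comp <- sample(1:6, n, replace = TRUE)
  mu <- c(50, 80, 120, 180, 260, 380)
  array(mu[comp] * exp(rnorm(n, sd = mode_sd)), dims)
}

test_that("a spatially uniform six-mode image yields a flat field", {
  # enough voxels (and narrow modes) that residual polynomial overfit of
  # the in-mode noise stays well below the 1e-3 flatness bound
  img <- make_uniform_sixmode(dims = c(44L, 40L, 14L), mode_sd = 0.003)
  mask <- array(TRUE, dim(img))
  est <- estimate_bias(img, mask)
  expect_lt(max(abs(est$bias$field - 1)), 1e-3)
  expect_equal(mean(est$bias$field[mask]), 1, tolerance = 1e-12)
  expect_true(all(est$bias$field > 0))
  expect_equal(sum(est$mixture$weights), 1, tolerance = 1e-9)
})

test_that("injected log-polynomial field is recovered in-mask", {
  # +-20% 4th-order field on the six-mode image; flattening is not needed
  # here because the intensity classes are spatially unstructured
  img <- make_uniform_sixmode(dims = c(36L, 32L, 12L), seed = 77L)
  mask <- array(TRUE, dim(img))
  set.seed(78)
  truth <- castrr:::.random_bias_field(dim(img), 0.2, mask)
  est <- estimate_bias(img * truth, mask)
  rel <- est$bias$field[mask] / truth[mask] - 1
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("voxels outside the estimation mask cannot influence the field", {
  s <- noisy_subject()
  fit <- fit_recovery_volume(s$tr_series,
                             s$masks$brain | s$masks$blood |
                               Reduce(`|`, s$masks$phantom))
  vals <- fit$m0$values
  est1 <- estimate_bias(vals, s$masks$brain)
  perturbed <- vals
  vial <- Reduce(`|`, s$masks$phantom) | s$masks$blood
  perturbed[vial] <- perturbed[vial] * 1.5
  est2 <- estimate_bias(perturbed, s$masks$brain)
  expect_lt(max(abs(est1$bias$log_coefficients - est2$bias$log_coefficients)),
            1e-9)
})

test_that("apply_bias: identity, inverse, and positivity guard", {
  s <- noiseless_subject()
  fit <- fit_recovery_volume(s$tr_series, s$masks$brain)
  ones <- array(1, dim(fit$m0$values))
  out <- apply_bias(fit$m0, ones)
  expect_identical(out$values, fit$m0$values)

  set.seed(9)
  field <- array(exp(rnorm(prod(dim(ones)), sd = 0.1)), dim(ones))
  corrected <- apply_bias(fit$m0, field)
  back <- corrected$values * field
  sel <- fit$m0$fit_mask
  expect_lt(max(abs(back[sel] - fit$m0$values[sel]) /
                  abs(fit$m0$values[sel])), 1e-12)

  bad <- field; bad[1] <- -1
  expect_error(apply_bias(fit$m0, bad), "positive")
})

test_that("correction reduces GM coefficient of variation on a biased subject", {
  s <- noisy_subject()  # bias amplitude 0.2 by default
  res <- process_subject(s)
  raw_fit <- fit_recovery_volume(s$tr_series, s$masks$brain)
  gm <- s$masks$gm & raw_fit$m0$fit_mask
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(res$m0$values[gm]), cv(raw_fit$m0$values[gm]))
})

test_that("global scale invariance and idempotence at convergence", {
  img <- make_uniform_sixmode(dims = c(30L, 26L, 10L), seed = 13L)
  mask <- array(TRUE, dim(img))
  set.seed(14)
  truth <- castrr:::.random_bias_field(dim(img), 0.15, mask)
  biased <- img * truth

  e1 <- estimate_bias(biased, mask)
  e2 <- estimate_bias(biased * 37.5, mask)
  expect_lt(sqrt(mean((e1$bias$field - e2$bias$field)^2)), 1e-6)

  corrected <- apply_bias(biased, e1$bias)
  e3 <- estimate_bias(corrected, mask)
  expect_lt(sqrt(mean((e3$bias$field[mask] - 1)^2)), 0.01)
})

test_that("estimation guards: mask size, degenerate geometry, grid mismatch", {
  img <- make_uniform_sixmode(dims = c(8L, 8L, 4L))
  expect_error(estimate_bias(img, array(TRUE, dim(img))), "mask too small")
  # a 2-slice volume cannot support a 4th-order z-polynomial
  thin <- make_uniform_sixmode(dims = c(16L, 14L, 2L))
  expect_error(estimate_bias(thin, array(TRUE, dim(thin))),
               "degenerate mask geometry")
  big <- make_uniform_sixmode()
  expect_error(estimate_bias(big, array(TRUE, c(2, 2, 2))), "match")
})
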