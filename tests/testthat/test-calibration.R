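# calibration: phantom line, cohort quadratic-error correction, Hct route.

mk_vial_world <- function(values = c(60, 70, 80, 90, 100), n_per = 20L) {
  # five constant-valued vials in a tiny volume
  dims <- c(10L, 10L, 5L)
  m0 <- array(NaN, dims)
  masks <- lapply(1:5, function(i) array(FALSE, dims))
  for (i in 1:5) {
    idx <- ((i - 1) * n_per + 1):(i * n_per)
    masks[[i]][idx] <- TRUE
    m0[idx] <- values[i]
  }
  list(m0 = m0, phantoms = phantom_set(masks))
}

test_that("phantom_means extracts exact vial means and flags failures", {
  w <- mk_vial_world()
  expect_equal(phantom_means(w$m0, w$phantoms), c(60, 70, 80, 90, 100))

  w$m0[w$phantoms$masks[[3]]] <- NaN
  expect_error(phantom_means(w$m0, w$phantoms), "vial 3")
})

test_that("noisy vials recover generative means within 1%", {
  set.seed(41)
  truth <- c(60, 70, 80, 90, 100)
  w <- mk_vial_world(truth, n_per = 60L)
  w$m0 <- w$m0 * (1 + rnorm(length(w$m0), sd = 1 / 50))
  got <- phantom_means(w$m0, w$phantoms)
  expect_true(all(abs(got / truth - 1) < 0.01))
})

test_that("fit_phantom_line: exact lines, scale, noise, and guards", {
  line <- fit_phantom_line(c(60, 70, 80, 90, 100))
  expect_equal(line$slope, 0.01, tolerance = 1e-12)
  expect_equal(line$intercept, 0, tolerance = 1e-12)
  expect_equal(line$r_squared, 1, tolerance = 1e-12)

  line2 <- fit_phantom_line(c(120, 140, 160, 180, 200))
  expect_equal(line2$slope, 0.005, tolerance = 1e-12)
  expect_equal(line2$intercept, 0, tolerance = 1e-10)

  set.seed(42)
  for (i in 1:10) {
    noisy <- c(60, 70, 80, 90, 100) * (1 + runif(5, -0.01, 0.01))
    expect_gt(fit_phantom_line(noisy)$r_squared, 0.99)
  }

  expect_error(fit_phantom_line(rep(80, 5)), "degenerate")
  expect_warning(fit_phantom_line(c(100, 90, 80, 70, 60)), "not positive")
})

test_that("ratio regression: null case, injected nonlinearity, guards", {
  # constant ratio -> beta ~ 0, all deltas ~ 0
  cohort <- data.frame(subject_id = sprintf("s%d", 1:8),
                       tissue_mean_m0 = 0.7 * seq(40, 110, by = 10),
                       phantom_mean_m0 = seq(40, 110, by = 10))
  rr <- fit_ratio_regression(cohort)
  expect_equal(rr$beta, 0, tolerance = 1e-12)
  expect_equal(unname(rr$per_subject_error), rep(0, 8), tolerance = 1e-9)

  # injected gain-dependent phantom inflation -> beta < 0
  set.seed(5)
  g <- runif(12, 25, 75)
  c_nl <- 0.002
  cohort2 <- data.frame(subject_id = sprintf("s%d", 1:12),
                        tissue_mean_m0 = 0.69 * g,
                        phantom_mean_m0 = 0.8 * g * (1 + c_nl * g))
  rr2 <- fit_ratio_regression(cohort2)
  expect_lt(rr2$beta, 0)
  expect_equal(unname(rr2$per_subject_error),
               unname(rr2$beta * cohort2$phantom_mean_m0^2), tolerance = 1e-12)

  expect_error(fit_ratio_regression(cohort2[1:2, ]), ">= 3 subjects")
})

test_that("apply_error_correction shifts brain and blood, not vials", {
  dims <- c(8L, 8L, 4L)
  m0 <- array(100, dims)
  brain <- array(FALSE, dims); brain[1:4, , ] <- TRUE
  bl <- array(FALSE, dims); bl[5, , ] <- TRUE
  vial <- array(FALSE, dims); vial[6, , ] <- TRUE
  m0[bl] <- 80; m0[vial] <- 120
  blood <- blood_sample(bl, mean_m0 = 80, hct = 0.45)

  out0 <- apply_error_correction(m0, brain, blood, 0)
  expect_identical(out0$m0, m0)

  out <- apply_error_correction(m0, brain, blood, -5)
  expect_true(all(out$m0[brain] == 105))
  expect_equal(out$blood$mean_m0, 85)
  expect_true(all(out$m0[bl] == 85))
  expect_true(all(out$m0[vial] == 120))

  expect_error(apply_error_correction(m0, brain, blood, 100),
               "non-positive")
})

test_that("hematocrit-to-blood-water formula is exact", {
  expect_identical(hct_blood_water(0), 0.912)
  expect_identical(hct_blood_water(0.45), -0.271 * 0.45 + 0.912)
  expect_equal(hct_blood_water(0.45), 0.79005, tolerance = 1e-12)
  expect_identical(hct_blood_water(1), 0.641)
  expect_warning(got <- hct_blood_water(45), "percent")
  expect_equal(got, 0.79005, tolerance = 1e-12)
  expect_error(hct_blood_water(-0.1), "out of range")
  expect_error(hct_blood_water(NA_real_), "finite")
})

test_that("normalization routes: evaluation, defining property, agreement", {
  w <- mk_vial_world()
  line <- fit_phantom_line(phantom_means(w$m0, w$phantoms))
  w$m0[1:5, , 3] <- 83
  wc <- normalize_phantom(w$m0, line)
  expect_equal(wc$values[1, 1, 3], 0.83, tolerance = 1e-12)
  # vial voxels map back to their known fractions
  expect_equal(phantom_means(wc$values, w$phantoms), seq(0.6, 1, by = 0.1),
               tolerance = 1e-9)

  # hct route: blood-ROI mean equals the formula value by construction
  dims <- c(6L, 6L, 3L)
  m0 <- array(runif(prod(dims), 50, 150), dims)
  bl <- array(FALSE, dims); bl[1:2, , ] <- TRUE
  blood <- blood_sample(bl, mean_m0 = mean(m0[bl]), hct = 0.45)
  wch <- normalize_hct(m0, blood)
  expect_equal(mean(wch$values[bl]), hct_blood_water(0.45), tolerance = 1e-12)

  # slope-only world: the two routes agree exactly
  k <- hct_blood_water(0.45) / blood$mean_m0
  line_slope_only <- structure(list(slope = k, intercept = 0, r_squared = 1),
                               class = "castrr_calibration_line")
  wcp <- normalize_phantom(m0, line_slope_only)
  expect_lt(max(abs(wcp$values - wch$values) / abs(wch$values)), 1e-9)
})
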