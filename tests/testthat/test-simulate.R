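# synthetic_cohort: generator determinism, noise models, cohort structure,
# and the closed-loop identity with the pipeline.

test_that("generation is deterministic given (config, seed)", {
  cfg <- test_cfg()
  a <- make_subject(cfg, 321L)
  b <- make_subject(cfg, 321L)
  expect_identical(a$tr_series$volumes[[1]]$data, b$tr_series$volumes[[1]]$data)
  expect_identical(a$cbf_uncorrected$values, b$cbf_uncorrected$values)
  expect_identical(a$truth$bias_field, b$truth$bias_field)
  d <- make_subject(cfg, 322L)
  expect_false(identical(a$tr_series$volumes[[1]]$data,
                         d$tr_series$volumes[[1]]$data))
})

test_that("subject anatomy is consistent with its own truth", {
  s <- noisy_subject()
  m <- s$masks
  # compartments partition the brain
  expect_true(all((m$gm | m$wm | m$csf) == m$brain))
  expect_false(any(m$gm & m$wm))
  vials <- c(m$phantom, list(m$blood))
  for (i in seq_along(vials)) {
    expect_false(any(vials[[i]] & m$brain))
    expect_gt(sum(vials[[i]]), 10)
  }
  # truth invariants
  expect_equal(s$truth$wc_blood, -0.271 * s$hct + 0.912, tolerance = 1e-12)
  bb <- s$truth$bbpc_map$values
  wc <- s$truth$wc_map$values
  expect_equal(bb[m$brain], wc[m$brain] / (s$truth$wc_blood * 1.04),
               tolerance = 1e-12)
})

test_that("add_noise: identity, gaussian calibration, Rayleigh closed form", {
  x <- array(runif(1000, 10, 20), c(10, 10, 10))
  expect_identical(add_noise(x, snr = Inf), x)

  set.seed(91)
  big <- array(1000, c(50L, 50L, 40L))     # 1e5 voxels
  g <- add_noise(big, model = "gaussian", sd = 7)
  expect_lt(abs(sd(g - big) / 7 - 1), 0.02)

  z <- array(0, c(50L, 50L, 40L))
  r <- add_noise(z, model = "rician", sd = 7)
  # |CN(0, sd^2)| is Rayleigh(sd): sd of the magnitude = sd*sqrt(2 - pi/2)
  expect_lt(abs(sd(r) / (7 * sqrt(2 - pi / 2)) - 1), 0.02)
  expect_lt(abs(mean(r) / (7 * sqrt(pi / 2)) - 1), 0.02)
})

test_that("cohort assembly: demographics, truth table, manifest round trip", {
  out_dir <- file.path(tempdir(), "castrr-sim-test")
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  cfg <- test_cfg(dims = c(24L, 22L, 8L), n_subjects = 17L, snr = Inf,
                  bias_amplitude = 0, nonlinearity_c = 0)
  co <- make_cohort(cfg, out_dir = out_dir)
  expect_length(co, 17L)
  tr <- attr(co, "truth")
  expect_identical(nrow(tr), 17L)
  expect_true(all(tr$age >= 5 & tr$age <= 8))
  expect_identical(sum(tr$sex), 4L)   # round(0.24 * 17)
  expect_true(all(tr$hct > 0.2 & tr$hct < 0.7))

  # manifest written to disk loads and points at readable volumes
  man <- load_cohort_manifest(file.path(out_dir, "cohort.yaml"))
  expect_length(man$subjects, 17L)
  m1 <- man$subjects[[1]]
  expect_equal(m1$tr_values_ms, cfg$tr_ms)
  v <- read_volume(file.path(out_dir, m1$tr_series_paths[[1]]))
  expect_identical(dim(v$data), dim(co[[1]]$tr_series$volumes[[1]]$data))
  expect_true(file.exists(file.path(out_dir, "truth.csv")))
})

test_that("generative age line is recovered from cohort truth", {
  cfg <- test_cfg(dims = c(24L, 22L, 8L), n_subjects = 17L, snr = Inf,
                  bias_amplitude = 0, nonlinearity_c = 0, seed = 9L)
  co <- make_cohort(cfg)
  gm_cbf <- vapply(co, function(s) mean(s$truth$cbf_truth$values[s$masks$gm]),
                   numeric(1))
  ages <- vapply(co, `[[`, numeric(1), "age")
  fit <- age_regression(gm_cbf, ages)
  expect_lt(abs(fit$slope + 7.5), 0.5)
})

test_that("single-subject cohorts refuse the quadratic correction downstream", {
  s <- noisy_subject()
  expect_error(quiet_cohort(list(s), quadratic_correction = TRUE,
                            erode_px = 1, center_slices = 8),
               ">= 3 subjects")
  # and run fine without it
  res <- quiet_cohort(list(s), quadratic_correction = FALSE,
                      erode_px = 1, center_slices = 8)
  expect_identical(nrow(res$report), 1L)
})

test_that("BBPC ROI-mean RMSE degrades monotonically as SNR drops", {
  rmse <- vapply(c(200, 100, 50, 25), function(snr) {
    cfg <- test_cfg(dims = c(40L, 36L, 12L), snr = snr, seed = 11L,
                    nonlinearity_c = 0)
    s <- make_subject(cfg, 500L)   # common structural seed across SNRs
    res <- quiet_cohort(list(s), quadratic_correction = FALSE,
                        erode_px = 1, center_slices = 8)
    sqrt(mean(c(res$report$bbpc_gm_hct - s$truth$bbpc_gm,
                res$report$bbpc_wm_hct - s$truth$bbpc_wm)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) >= -0.002))  # non-decreasing up to tiny jitter
})

test_that("CLI: simulate then fit runs end to end on a tiny cohort", {
  out_dir <- file.path(tempdir(), "castrr-cli-test")
  work <- file.path(tempdir(), "castrr-cli-work")
  on.exit(unlink(c(out_dir, work), recursive = TRUE), add = TRUE)
  # simulate subcommand uses package defaults except size/seed overrides;
  # build a small cohort directly to keep the test fast
  cfg <- test_cfg(dims = c(24L, 22L, 8L), n_subjects = 2L, seed = 3L)
  make_cohort(cfg, out_dir = out_dir)
  fit <- castrr_cli(c("fit", "--config", file.path(out_dir, "cohort.yaml"),
                      "--subject", "sub01", "--out-dir", work,
                      "--log-level", "quiet"))
  expect_true(file.exists(file.path(work, "sub01_m0.nii")))
  expect_true(file.exists(file.path(work, "sub01_fit_summary.csv")))
  m0 <- read_volume(file.path(work, "sub01_m0.nii"))
  expect_identical(dim(m0$data), c(24L, 22L, 8L))
})
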