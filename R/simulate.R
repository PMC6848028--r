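# Synthetic-cohort simulator.
#
# Generates subjects with known ground truth so every pipeline stage is
# testable by parameter recovery: an ellipsoidal brain (GM shell, WM core,
# CSF ventricles), five doped-phantom disks plus a blood vial above the
# head, a multi-TR saturation-recovery signal series with a multiplicative
# coil bias field and Rician noise, a gain-dependent quadratic phantom
# nonlinearity, and an uncorrected CBF map consistent with the subject's
# true BBPC under an assumed constant partition coefficient.

#' Simulation configuration
#'
#' Defaults state the acquisition and cohort this generator emulates: a
#' 96x88 matrix at 1.4x1.4 mm with 30 slices of 3 mm, TRs
#' {125,250,500,1000,2000} ms, canine cohort ages 5-8 years with 24% males,
#' true BBPC 0.83 +- 0.05 mL/g (GM) and 0.78 +- 0.04 mL/g (WM), CSF water
#' fraction 0.99, GM CBF 128 - 7.5*age and WM CBF 56 mL/100 g/min,
#' hematocrit ~ N(0.45, 0.03) truncated to (0.2, 0.7), +-20% bias-field
#' amplitude, SNR 50 (Rician). `gain_range` is the per-subject global
#' intensity scale in arbitrary units; `nonlinearity_c` (per gain unit)
#' multiplies phantom signal by `(1 + c * gain)`, the minimal mechanism for
#' the observed quadratic phantom error while tissue scales linearly.
#'
#' @param n_subjects Cohort size (default 17).
#' @param dims Grid dimensions (default `c(96, 88, 30)`).
#' @param voxel_size Voxel size in mm (default `c(1.4, 1.4, 3)`).
#' @param tr_ms Repetition times in ms.
#' @param te_ms Echo time metadata, ms.
#' @param bbpc_gm,bbpc_gm_sd,bbpc_wm,bbpc_wm_sd Cohort mean/SD of true
#'   tissue BBPC, mL/g.
#' @param csf_wc CSF water fraction.
#' @param t1_gm,t1_wm,t1_csf,t1_blood,t1_phantom True T1 values, seconds.
#' @param hct_mean,hct_sd,hct_range Hematocrit distribution (truncated
#'   normal).
#' @param cbf_gm_intercept,cbf_age_slope,cbf_wm True CBF model,
#'   mL/100 g/min (GM = intercept + slope*age).
#' @param cbf_noise_sd Voxel-wise Gaussian noise SD on the CBF map.
#' @param assumed_lambda Partition coefficient assumed by the uncorrected
#'   CBF quantification (0.9 mL/g).
#' @param age_range,male_fraction Cohort demographics.
#' @param bias_amplitude Peak log-polynomial bias amplitude (0.2 = +-20%).
#' @param nonlinearity_c Quadratic phantom-error coefficient per gain unit.
#' @param gain_range Per-subject global gain range (arbitrary units).
#' @param snr Signal-to-noise ratio at the longest TR (`Inf` = noiseless).
#' @param noise_model `"rician"` (magnitude MR) or `"gaussian"`.
#' @param d2o_fractions Phantom D2O fractions.
#' @param seed Cohort seed; all randomness flows from it via per-subject
#'   sub-seeds.
#' @return A `castrr_sim_config` list.
#' @export
sim_config <- function(n_subjects = 17L,
                       dims = c(96L, 88L, 30L),
                       voxel_size = c(1.4, 1.4, 3),
                       tr_ms = c(125, 250, 500, 1000, 2000),
                       te_ms = 1.9,
                       bbpc_gm = 0.83, bbpc_gm_sd = 0.05,
                       bbpc_wm = 0.78, bbpc_wm_sd = 0.04,
                       csf_wc = 0.99,
                       t1_gm = 1.3, t1_wm = 0.9, t1_csf = 3.5,
                       t1_blood = 1.6, t1_phantom = 1.2,
                       hct_mean = 0.45, hct_sd = 0.03, hct_range = c(0.2, 0.7),
                       cbf_gm_intercept = 128, cbf_age_slope = -7.5, cbf_wm = 56,
                       cbf_noise_sd = 15, assumed_lambda = 0.9,
                       age_range = c(5, 8), male_fraction = 0.24,
                       bias_amplitude = 0.2,
                       nonlinearity_c = 0.002,
                       gain_range = c(25, 75),
                       snr = 50, noise_model = c("rician", "gaussian"),
                       d2o_fractions = c(0.40, 0.30, 0.20, 0.10, 0.00),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), dims = as.integer(dims),
              voxel_size = voxel_size, tr_ms = tr_ms, te_ms = te_ms,
              bbpc_gm = bbpc_gm, bbpc_gm_sd = bbpc_gm_sd,
              bbpc_wm = bbpc_wm, bbpc_wm_sd = bbpc_wm_sd, csf_wc = csf_wc,
              t1_gm = t1_gm, t1_wm = t1_wm, t1_csf = t1_csf,
              t1_blood = t1_blood, t1_phantom = t1_phantom,
              hct_mean = hct_mean, hct_sd = hct_sd, hct_range = hct_range,
              cbf_gm_intercept = cbf_gm_intercept, cbf_age_slope = cbf_age_slope,
              cbf_wm = cbf_wm, cbf_noise_sd = cbf_noise_sd,
              assumed_lambda = assumed_lambda,
              age_range = age_range, male_fraction = male_fraction,
              bias_amplitude = bias_amplitude, nonlinearity_c = nonlinearity_c,
              gain_range = gain_range, snr = snr,
              noise_model = match.arg(noise_model),
              d2o_fractions = d2o_fractions, seed = as.integer(seed))
  stopifnot(length(cfg$dims) == 3L, all(cfg$dims >= 8L),
            cfg$n_subjects >= 1L, cfg$snr > 0)
  structure(cfg, class = "castrr_sim_config")
}

.subject_subseed <- function(seed, i) {
  as.integer((as.double(seed) * 10007 + 97 * i) %% 2147483647)
}

# ellipsoid mask helper
.ellipsoid <- function(dims, center, semi) {
  ex <- ((seq_len(dims[1]) - center[1]) / semi[1])^2
  ey <- ((seq_len(dims[2]) - center[2]) / semi[2])^2
  ez <- ((seq_len(dims[3]) - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

# Phantom/blood vials and brain compartments for a grid.
.subject_geometry <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  center <- c(nx / 2 + 0.5, 0.60 * ny, nz / 2 + 0.5)
  semi <- c(0.30 * nx, 0.27 * ny, 0.42 * nz)
  brain <- .ellipsoid(dims, center, semi)
  inner <- .ellipsoid(dims, center, 0.68 * semi)
  vent1 <- .ellipsoid(dims, center + c(-0.08 * nx, 0, 0),
                      c(0.045 * nx, 0.09 * ny, 0.22 * nz))
  vent2 <- .ellipsoid(dims, center + c(0.08 * nx, 0, 0),
                      c(0.045 * nx, 0.09 * ny, 0.22 * nz))
  csf <- (vent1 | vent2) & inner
  wm <- inner & !csf
  gm <- brain & !inner

  # six vials (5 phantoms + blood) on an arc resting on the top of the head
  # (low y), spanning the central 60% of slices; keeping the vials adjacent
  # to the scalp matches the acquisition layout and keeps the bias-field
  # polynomial evaluation close to its estimation support
  r <- max(1.4, 0.03 * min(nx, ny))
  margin <- r + 2
  zc <- nz / 2 + 0.5
  zr <- 0.30 * nz
  ang <- seq(-150, -30, length.out = 6) * pi / 180
  vx <- center[1] + (semi[1] + margin) * cos(ang)
  vy <- center[2] + (semi[2] + margin) * sin(ang)
  xg <- seq_len(nx); yg <- seq_len(ny); zg <- seq_len(nz)
  in_z <- abs(zg - zc) <= zr
  vials <- lapply(seq_len(6), function(i) {
    disk <- outer((xg - vx[i])^2, (yg - vy[i])^2, "+") <= r^2
    arr <- array(FALSE, dims)
    arr[, , which(in_z)] <- disk
    arr
  })
  list(brain = brain, gm = gm, wm = wm, csf = csf,
       phantom = vials[1:5], blood = vials[[6]])
}

# Random 4th-order log-polynomial bias field with given peak amplitude,
# normalized to mean 1 over the brain mask.
.random_bias_field <- function(dims, amplitude, brain_mask) {
  if (amplitude <= 0) return(array(1, dims))
  coords <- .grid_coords(dims)
  bbox <- rbind(lo = c(1, 1, 1), hi = dims)
  B <- .poly_basis(coords, 4L, bbox)
  deg <- c(0, rep(1:4, times = c(3, 6, 10, 15)))  # total degree per basis column
  coef <- stats::rnorm(ncol(B)) / (1 + deg)
  coef[1] <- 0
  lf <- as.double(B %*% coef)
  lf <- lf - mean(lf[brain_mask])
  peak <- max(abs(lf))
  if (peak > 0) lf <- lf * (log(1 + amplitude) / peak)
  field <- array(exp(lf), dims)
  field / mean(field[brain_mask])
}

#' Add acquisition noise to a volume
#'
#' Rician noise applies the magnitude of a complex Gaussian perturbation
#' (the physically correct model for magnitude MR images); Gaussian noise is
#' offered for analytic tests. The noise SD defaults to
#' `mean(nonzero signal) / snr` when not given explicitly.
#'
#' @param volume 3-D array, `castrr_volume`, or map object.
#' @param snr Signal-to-noise ratio; `Inf` returns the input unchanged.
#' @param model `"rician"` or `"gaussian"`.
#' @param sd Noise standard deviation; overrides the SNR-derived default.
#' @return Noisy array (same dimensions).
#' @export
add_noise <- function(volume, snr = Inf, model = c("rician", "gaussian"), sd = NULL) {
  model <- match.arg(model)
  x <- .vals(volume)
  if (is.null(sd)) {
    if (is.infinite(snr)) return(x)
    ref <- mean(abs(x[x != 0]))
    if (!is.finite(ref)) ref <- 0
    sd <- ref / snr
  }
  if (sd == 0) return(x)
  n <- length(x)
  if (model == "gaussian") {
    x + array(stats::rnorm(n, sd = sd), dim = dim(x))
  } else {
    re <- x + stats::rnorm(n, sd = sd)
    im <- stats::rnorm(n, sd = sd)
    array(sqrt(re^2 + im^2), dim = dim(x))
  }
}

.rtruncnorm1 <- function(mean, sd, range) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > range[1] && x < range[2]) return(x)
  }
  mean
}

#' Simulate one subject
#'
#' Deterministic given `(config, subject_seed)`. The voxel signal at
#' repetition time t is `gain * bias(v) * WC(v) * (1 - exp(-t/T1(v)))`, with
#' phantom-vial signal additionally scaled by `(1 + c * gain)`; noise is
#' added per TR volume with SD = (mean in-brain signal at the longest
#' TR) / SNR. The uncorrected CBF map equals true CBF *
#' `assumed_lambda / BBPC_true` plus Gaussian noise, so that voxel-wise BBPC
#' correction recovers the truth.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier (default derived from the seed).
#' @param age,sex,hct Optional cohort-assigned values; drawn from the
#'   subject seed when `NULL`.
#' @return A `castrr_subject`: `tr_series`, `cbf_uncorrected`, `anatomical`,
#'   `masks` (brain/blood/phantom list/gm/wm/csf), `hct`, `age`, `sex`, and
#'   `truth` (`wc_map`, `bbpc_map`, `bias_field`, `wc_blood`, `gain`,
#'   `nonlinearity_c`, `cbf_truth`, per-tissue true BBPC and T1).
#' @export
make_subject <- function(config, subject_seed, subject_id = NULL,
                         age = NULL, sex = NULL, hct = NULL) {
  stopifnot(inherits(config, "castrr_sim_config"))
  set.seed(subject_seed)
  dims <- config$dims
  geo <- .subject_geometry(dims)
  if (is.null(subject_id)) subject_id <- sprintf("sim%09d", subject_seed)
  if (is.null(age)) age <- stats::runif(1, config$age_range[1], config$age_range[2])
  if (is.null(sex)) sex <- stats::rbinom(1, 1, config$male_fraction)
  if (is.null(hct)) hct <- .rtruncnorm1(config$hct_mean, config$hct_sd, config$hct_range)

  wc_blood <- hct_blood_water(hct)
  bbpc_gm_i <- .rtruncnorm1(config$bbpc_gm, config$bbpc_gm_sd,
                            config$bbpc_gm + c(-3, 3) * config$bbpc_gm_sd)
  bbpc_wm_i <- .rtruncnorm1(config$bbpc_wm, config$bbpc_wm_sd,
                            config$bbpc_wm + c(-3, 3) * config$bbpc_wm_sd)
  gain <- stats::runif(1, config$gain_range[1], config$gain_range[2])

  # ground-truth water content and T1
  wc <- array(0, dims)
  wc[geo$gm] <- bbpc_gm_i * wc_blood * 1.04
  wc[geo$wm] <- bbpc_wm_i * wc_blood * 1.04
  wc[geo$csf] <- config$csf_wc
  wc[geo$blood] <- wc_blood
  wf <- 1 - config$d2o_fractions
  for (i in 1:5) wc[geo$phantom[[i]]] <- wf[i]

  t1 <- array(config$t1_gm, dims)  # placeholder; only voxels with signal matter
  t1[geo$gm] <- config$t1_gm
  t1[geo$wm] <- config$t1_wm
  t1[geo$csf] <- config$t1_csf
  t1[geo$blood] <- config$t1_blood
  for (i in 1:5) t1[geo$phantom[[i]]] <- config$t1_phantom

  bias <- .random_bias_field(dims, config$bias_amplitude, geo$brain)
  phantom_factor <- array(1, dims)
  phantom_factor[Reduce(`|`, geo$phantom)] <- 1 + config$nonlinearity_c * gain

  m0_clean <- gain * bias * wc * phantom_factor
  tr_s <- config$tr_ms / 1000
  noiseless_long <- m0_clean * (1 - exp(-tr_s[length(tr_s)] / t1))
  noise_sd <- if (is.infinite(config$snr)) 0 else
    mean(noiseless_long[geo$brain]) / config$snr

  volumes <- lapply(tr_s, function(t) {
    sig <- m0_clean * (1 - exp(-t / t1))
    sig <- add_noise(sig, model = config$noise_model, sd = noise_sd)
    volume_image(sig, voxel_size = config$voxel_size, units = "a.u.")
  })
  series <- tr_series(volumes, config$tr_ms, te_ms = config$te_ms)

  # true BBPC and CBF; uncorrected CBF assumes a constant lambda
  bbpc_true <- array(NaN, dims)
  inb <- geo$brain
  bbpc_true[inb] <- wc[inb] / (wc_blood * 1.04)
  cbf_true <- array(0, dims)
  cbf_true[geo$gm] <- config$cbf_gm_intercept + config$cbf_age_slope * age
  cbf_true[geo$wm] <- config$cbf_wm
  cbf_unc <- array(0, dims)
  cbf_unc[inb] <- cbf_true[inb] * config$assumed_lambda / bbpc_true[inb]
  if (config$cbf_noise_sd > 0 && !is.infinite(config$snr)) {
    noise <- stats::rnorm(sum(inb), sd = config$cbf_noise_sd)
    cbf_unc[inb] <- cbf_unc[inb] + noise
  }

  # T1-weighted anatomical (WM > GM > CSF)
  anat <- array(0, dims)
  anat[geo$gm] <- 600; anat[geo$wm] <- 900; anat[geo$csf] <- 300
  anat_sd <- if (is.infinite(config$snr)) 0 else 600 / config$snr
  anat <- add_noise(anat, model = "gaussian", sd = anat_sd)
  anat[!inb] <- 0

  structure(list(
    subject_id = subject_id,
    tr_series = series,
    cbf_uncorrected = structure(list(values = cbf_unc,
                                     assumed_lambda = config$assumed_lambda),
                                class = "castrr_cbf_map"),
    anatomical = volume_image(anat, voxel_size = config$voxel_size, units = "a.u."),
    masks = list(brain = geo$brain, blood = geo$blood, phantom = geo$phantom,
                 gm = geo$gm, wm = geo$wm, csf = geo$csf),
    hct = hct, age = age, sex = sex,
    truth = list(
      wc_map = structure(list(values = wc), class = "castrr_wc_map"),
      bbpc_map = structure(list(values = bbpc_true, density_g_per_ml = 1.04,
                                wc_blood_used = wc_blood),
                           class = "castrr_bbpc_map"),
      bias_field = bias, hct = hct, wc_blood = wc_blood, gain = gain,
      nonlinearity_c = config$nonlinearity_c,
      cbf_truth = structure(list(values = cbf_true, assumed_lambda = NA_real_),
                            class = "castrr_cbf_map"),
      age = age, sex = sex,
      bbpc_gm = bbpc_gm_i, bbpc_wm = bbpc_wm_i,
      t1_map = t1, noise_sd = noise_sd
    )
  ), class = "castrr_subject")
}

#' Simulate a cohort
#'
#' Ages are uniform over the configured range; the configured male
#' proportion is assigned as a fixed count in random order; each subject is
#' generated from a sub-seed derived from the cohort seed, so any subject is
#' reproducible in isolation. Optionally writes all volumes, masks, truth
#' maps, a YAML cohort manifest consumable by the CLI, and a truth CSV.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for NIfTI/manifest/CSV files.
#' @return List of `castrr_subject` with attributes `config` and `truth`
#'   (per-subject truth data frame).
#' @export
make_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "castrr_sim_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  n_male <- round(config$male_fraction * n)
  sexes <- sample(c(rep(1L, n_male), rep(0L, n - n_male)))
  hcts <- vapply(seq_len(n), function(i)
    .rtruncnorm1(config$hct_mean, config$hct_sd, config$hct_range), numeric(1))

  subjects <- lapply(seq_len(n), function(i) {
    make_subject(config, .subject_subseed(config$seed, i),
                 subject_id = sprintf("sub%02d", i),
                 age = ages[i], sex = sexes[i], hct = hcts[i])
  })
  truth_df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               hct = s$hct, wc_blood = s$truth$wc_blood, gain = s$truth$gain,
               bbpc_gm = s$truth$bbpc_gm, bbpc_wm = s$truth$bbpc_wm)
  }))
  attr(subjects, "config") <- config
  attr(subjects, "truth") <- truth_df
  if (!is.null(out_dir)) .write_cohort(subjects, config, truth_df, out_dir)
  subjects
}

.write_cohort <- function(subjects, config, truth_df, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, subjects = list())
  for (s in subjects) {
    sdir <- file.path(out_dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    rel <- function(...) file.path(s$subject_id, ...)
    tr_paths <- character(0)
    for (j in seq_along(s$tr_series$volumes)) {
      p <- rel(sprintf("tr%04d.nii", round(s$tr_series$tr_ms[j])))
      write_volume(s$tr_series$volumes[[j]], file.path(out_dir, p))
      tr_paths <- c(tr_paths, p)
    }
    mask_paths <- list()
    wm <- function(name, mask) {
      p <- rel(paste0(name, ".nii"))
      write_volume(volume_image(array(as.double(mask), dim(mask)),
                                voxel_size = config$voxel_size, units = "mask"),
                   file.path(out_dir, p), datatype = "uint8")
      p
    }
    mask_paths$brain <- wm("mask_brain", s$masks$brain)
    mask_paths$blood <- wm("mask_blood", s$masks$blood)
    for (i in 1:5) mask_paths[[paste0("phantom_", i)]] <-
      wm(paste0("mask_phantom_", i), s$masks$phantom[[i]])
    mask_paths$gm <- wm("mask_gm", s$masks$gm)
    mask_paths$wm <- wm("mask_wm", s$masks$wm)
    mask_paths$csf <- wm("mask_csf", s$masks$csf)
    cbf_path <- rel("cbf_uncorrected.nii")
    write_volume(volume_image(s$cbf_uncorrected$values,
                              voxel_size = config$voxel_size,
                              units = "mL/100g/min"),
                 file.path(out_dir, cbf_path))
    anat_path <- rel("anatomical.nii")
    write_volume(s$anatomical, file.path(out_dir, anat_path))
    write_volume(volume_image(s$truth$wc_map$values,
                              voxel_size = config$voxel_size,
                              units = "g/mL-fraction"),
                 file.path(out_dir, rel("truth_wc.nii")))
    write_volume(volume_image(s$truth$bias_field,
                              voxel_size = config$voxel_size),
                 file.path(out_dir, rel("truth_bias.nii")))
    manifest$subjects[[length(manifest$subjects) + 1L]] <- list(
      subject_id = s$subject_id, tr_series_paths = as.list(tr_paths),
      tr_values_ms = as.list(config$tr_ms), mask_paths = mask_paths,
      cbf_path = cbf_path, anatomical_path = anat_path,
      hct = s$hct, age_years = s$age, sex = s$sex)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "cohort.yaml"))
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(out_dir)
}
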