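# End-to-end orchestration: fit -> bias-correct -> calibrate -> BBPC ->
# CBF correction -> ROI summaries, at subject and cohort level.

#' Fit and bias-correct one subject
#'
#' Fits the recovery model over brain + blood + vial voxels, optionally
#' estimates and removes the coil bias field (estimation restricted to the
#' brain mask so the bright vials cannot attenuate the field), and collects
#' the per-subject quantities the calibration stage needs.
#'
#' @param subject A `castrr_subject` (or any list with `tr_series` and
#'   `masks` of the same shape).
#' @param bias_correct Estimate/remove the bias field (default TRUE).
#' @param K,order Bias-field mixture components and polynomial order.
#' @return List with `m0` (corrected `castrr_m0_map`), `t1`, `bias` (or
#'   NULL), `phantoms` (`castrr_phantom_set`), `phantom_means`,
#'   `phantom_mean` (grand mean of the five vial means), `blood`
#'   (`castrr_blood_sample` with `mean_m0`), `tissue_mean` (brain-mask mean
#'   M0), `fit_counts`.
#' @export
process_subject <- function(subject, bias_correct = TRUE, K = 6L, order = 4L) {
  masks <- subject$masks
  fit_mask <- masks$brain | masks$blood | Reduce(`|`, masks$phantom)
  fit <- fit_recovery_volume(subject$tr_series, fit_mask)

  bias <- NULL
  m0 <- fit$m0
  if (bias_correct) {
    # T1 is invariant to the multiplicative field, so a quick 3-class EM on
    # log T1 gives bias-free tissue labels; flattening M0 by those classes
    # keeps the polynomial field from absorbing anatomical contrast
    lt1 <- fit$t1$values
    lt1[lt1 <= 0] <- NA
    lt1 <- log(lt1)
    labels <- tryCatch(
      em_segment(lt1, masks$brain, contrast = "pd")$labels,
      error = function(e) NULL)
    est <- estimate_bias(m0, masks$brain, K = K, order = order,
                         flatten_labels = labels)
    bias <- est$bias
    m0 <- apply_bias(m0, bias)
  }

  phantoms <- phantom_set(masks$phantom)
  pm <- phantom_means(m0, phantoms)
  blood <- blood_sample(masks$blood, mean_m0 = roi_mean(m0, masks$blood),
                        hct = subject$hct)
  list(m0 = m0, t1 = fit$t1, bias = bias,
       phantoms = phantoms, phantom_means = pm, phantom_mean = mean(pm),
       blood = blood, tissue_mean = roi_mean(m0, masks$brain),
       fit_counts = list(n_fitted = fit$n_fitted, n_failed = fit$n_failed,
                         n_below_floor = fit$n_below_floor))
}

#' Analysis ROIs: eroded, center-slice-restricted tissue masks
#'
#' @param gm_mask,wm_mask Tissue masks.
#' @param brain_mask Brain mask defining the slice extent.
#' @param erode_px Per-slice erosion radius (default 2).
#' @param center_slices Number of central slices retained (default 10).
#' @param shape Structuring element for [erode_roi()].
#' @return List with eroded/restricted `gm` and `wm` masks.
#' @export
analysis_masks <- function(gm_mask, wm_mask, brain_mask, erode_px = 2L,
                           center_slices = 10L, shape = "cross") {
  keep <- select_center_slices(brain_mask, n = center_slices)
  list(gm = erode_roi(gm_mask, pixels = erode_px, shape = shape) & keep,
       wm = erode_roi(wm_mask, pixels = erode_px, shape = shape) & keep)
}

#' Run the full BBPC pipeline over a cohort
#'
#' Per subject: recovery fit, optional bias correction, then both
#' calibration routes (phantom line and hematocrit). When
#' `quadratic_correction` is on (>= 3 subjects required), the cohort ratio
#' regression estimates each subject's quadratic phantom error, which is
#' subtracted from brain and blood values before phantom normalization.
#' ROI means use per-slice-eroded, center-slice-restricted GM/WM masks; CBF
#' maps, when present, are corrected with the phantom-route BBPC map.
#'
#' @param subjects List of `castrr_subject`.
#' @param quadratic_correction Apply the cohort quadratic-error correction.
#' @param bias_correct Estimate/remove bias fields.
#' @param erode_px,center_slices,erode_shape ROI geometry parameters.
#' @param keep_maps Keep per-subject maps in the result (memory).
#' @return List with `report` (per-subject data frame: BBPC by route and
#'   tissue, CBF and CNR before/after correction), `ratio_fit` (or NULL),
#'   and `subjects` (per-subject detail; maps if `keep_maps`).
#' @export
process_cohort <- function(subjects, quadratic_correction = TRUE,
                           bias_correct = TRUE, erode_px = 2L,
                           center_slices = 10L, erode_shape = "cross",
                           keep_maps = FALSE) {
  fits <- lapply(subjects, process_subject, bias_correct = bias_correct)

  ratio_fit <- NULL
  deltas <- rep(0, length(subjects))
  if (quadratic_correction) {
    cohort_df <- data.frame(
      subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
      tissue_mean_m0 = vapply(fits, `[[`, numeric(1), "tissue_mean"),
      phantom_mean_m0 = vapply(fits, `[[`, numeric(1), "phantom_mean"))
    ratio_fit <- fit_ratio_regression(cohort_df)
    deltas <- unname(ratio_fit$per_subject_error)
  }

  detail <- vector("list", length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    f <- fits[[i]]
    # phantom route: quadratic-error correction then the calibration line;
    # hct route: pure rescaling to the hematocrit-derived blood water
    # content (the vials and their error term play no role). Both routes
    # divide by the hematocrit-derived blood water content in the BBPC
    # equation, which for the hct route equals the measured blood-ROI value
    # by construction.
    corr <- apply_error_correction(f$m0, s$masks$brain, f$blood, deltas[i])
    line <- fit_phantom_line(phantom_means(corr$m0, f$phantoms),
                             f$phantoms$water_fractions)
    wc_ph <- normalize_phantom(corr$m0, line)
    bbpc_ph <- compute_bbpc(wc_ph, f$blood$wc_blood)
    wc_hct <- normalize_hct(f$m0, f$blood)
    bbpc_hct <- compute_bbpc(wc_hct, f$blood$wc_blood)

    rois <- analysis_masks(s$masks$gm, s$masks$wm, s$masks$brain,
                           erode_px = erode_px, center_slices = center_slices,
                           shape = erode_shape)
    row <- data.frame(
      subject_id = s$subject_id, age = s$age, sex = s$sex, hct = s$hct,
      delta = deltas[i],
      tissue_mean_m0 = f$tissue_mean, phantom_mean_m0 = f$phantom_mean,
      bbpc_gm_phantom = roi_mean(bbpc_ph, rois$gm),
      bbpc_wm_phantom = roi_mean(bbpc_ph, rois$wm),
      bbpc_gm_hct = roi_mean(bbpc_hct, rois$gm),
      bbpc_wm_hct = roi_mean(bbpc_hct, rois$wm))
    if (quadratic_correction) {
      # phantom route without the quadratic-error term, for assessing how
      # much bias the correction removes
      line0 <- fit_phantom_line(phantom_means(f$m0, f$phantoms),
                                f$phantoms$water_fractions)
      bbpc0 <- compute_bbpc(suppressMessages(normalize_phantom(f$m0, line0)),
                            f$blood$wc_blood)
      row$bbpc_gm_phantom_uncorr <- roi_mean(bbpc0, rois$gm)
      row$bbpc_wm_phantom_uncorr <- roi_mean(bbpc0, rois$wm)
    }

    ccbf <- NULL
    if (!is.null(s$cbf_uncorrected)) {
      ccbf <- correct_cbf(s$cbf_uncorrected, bbpc_ph,
                          assumed_lambda = s$cbf_uncorrected$assumed_lambda)
      row$cbf_gm_uncorrected <- roi_mean(s$cbf_uncorrected, rois$gm)
      row$cbf_wm_uncorrected <- roi_mean(s$cbf_uncorrected, rois$wm)
      row$cbf_gm_corrected <- roi_mean(ccbf, rois$gm)
      row$cbf_wm_corrected <- roi_mean(ccbf, rois$wm)
      row$cnr_uncorrected <- contrast_to_noise(s$cbf_uncorrected, rois$gm, rois$wm)
      row$cnr_corrected <- contrast_to_noise(ccbf, rois$gm, rois$wm)
    }
    rows[[i]] <- row
    detail[[i]] <- c(
      list(subject_id = s$subject_id, line = line, delta = deltas[i],
           blood = corr$blood, rois = rois),
      if (keep_maps) list(m0 = corr$m0, t1 = f$t1, bias = f$bias,
                          wc_phantom = wc_ph, wc_hct = wc_hct,
                          bbpc_phantom = bbpc_ph, bbpc_hct = bbpc_hct,
                          cbf_corrected = ccbf)
    )
  }
  list(report = do.call(rbind, rows), ratio_fit = ratio_fit, subjects = detail)
}

#' Cohort summary statistics
#'
#' Cohort-level roll-up of a [process_cohort()] report: tissue means by
#' route, route agreement ([method_agreement()]) per tissue, CNR change, and
#' age regressions of CBF.
#'
#' @param report Per-subject data frame from [process_cohort()].
#' @return List of summary components.
#' @export
cohort_summary <- function(report) {
  out <- list(
    bbpc_gm_phantom_mean = mean(report$bbpc_gm_phantom),
    bbpc_wm_phantom_mean = mean(report$bbpc_wm_phantom),
    bbpc_gm_hct_mean = mean(report$bbpc_gm_hct),
    bbpc_wm_hct_mean = mean(report$bbpc_wm_hct),
    agreement_gm = method_agreement(report$bbpc_gm_phantom, report$bbpc_gm_hct),
    agreement_wm = method_agreement(report$bbpc_wm_phantom, report$bbpc_wm_hct))
  if (!is.null(report$cnr_uncorrected)) {
    out$cnr_uncorrected_mean <- mean(report$cnr_uncorrected)
    out$cnr_corrected_mean <- mean(report$cnr_corrected)
    out$age_fit_uncorrected <- age_regression(report$cbf_gm_uncorrected,
                                              report$age, report$sex)
    out$age_fit_corrected <- age_regression(report$cbf_gm_corrected,
                                            report$age, report$sex)
  }
  out
}
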