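# BBPC maps, CBF correction, and summary statistics.

#' Compute a BBPC map from a water-content map
#'
#' `BBPC = WC_brain / (WC_blood * 1.04 g/mL)` voxel-wise, in mL/g. The
#' 1.04 g/mL brain-tissue density converts per-gram tissue water to the
#' per-mL convention of the blood reference.
#'
#' @param wc_brain `castrr_wc_map` (or volume/array) of water fractions.
#' @param wc_blood Blood water content fraction in (0, 1).
#' @param density_g_per_ml Brain tissue density (default 1.04).
#' @return A `castrr_bbpc_map`: `values` (mL/g), `density_g_per_ml`,
#'   `wc_blood_used`.
#' @export
compute_bbpc <- function(wc_brain, wc_blood, density_g_per_ml = 1.04) {
  if (!is.numeric(wc_blood) || length(wc_blood) != 1L || !is.finite(wc_blood) ||
      wc_blood <= 0 || wc_blood >= 1) {
    stop("wc_blood must be a fraction in (0, 1)")
  }
  vals <- .vals(wc_brain) / (wc_blood * density_g_per_ml)
  structure(list(values = vals, density_g_per_ml = density_g_per_ml,
                 wc_blood_used = wc_blood),
            class = "castrr_bbpc_map")
}

#' Correct a CBF map for measured BBPC
#'
#' Uncorrected ASL CBF maps assume a constant partition coefficient
#' (`assumed_lambda`, conventionally 0.9 mL/g). The corrected map divides by
#' that constant and multiplies by the measured BBPC voxel-wise:
#' `cCBF = CBF / assumed_lambda * BBPC`.
#'
#' @param cbf `castrr_cbf_map`, volume, or array (mL/100 g/min).
#' @param bbpc `castrr_bbpc_map` (or array) on the same grid.
#' @param assumed_lambda BBPC assumed by the uncorrected quantification
#'   (default 0.9 mL/g).
#' @return A `castrr_cbf_map` with `values` and `assumed_lambda`.
#' @export
correct_cbf <- function(cbf, bbpc, assumed_lambda = 0.9) {
  if (!is.numeric(assumed_lambda) || assumed_lambda <= 0) {
    stop("assumed_lambda must be positive")
  }
  cv <- .vals(cbf)
  bv <- .vals(bbpc)
  if (!identical(dim(cv), dim(bv))) stop("CBF and BBPC maps must share one grid")
  structure(list(values = cv / assumed_lambda * bv,
                 assumed_lambda = assumed_lambda),
            class = "castrr_cbf_map")
}

#' Gray-white contrast-to-noise ratio
#'
#' `CNR = (mean_gray - mean_white) / pooled SD`, with the two-sample
#' Bessel-corrected pooled standard deviation
#' `sqrt(((n_g-1) s_g^2 + (n_w-1) s_w^2) / (n_g + n_w - 2))`.
#'
#' @param map 3-D array (or map object) of voxel values.
#' @param gm_mask,wm_mask Disjoint non-empty binary masks.
#' @return Signed CNR (scalar).
#' @export
contrast_to_noise <- function(map, gm_mask, wm_mask) {
  vals <- .vals(map)
  g <- vals[.as_mask(gm_mask)]
  w <- vals[.as_mask(wm_mask)]
  g <- g[is.finite(g)]; w <- w[is.finite(w)]
  if (!length(g) || !length(w)) stop("both masks must contain fitted voxels")
  if (any(.as_mask(gm_mask) & .as_mask(wm_mask))) stop("masks must be disjoint")
  ng <- length(g); nw <- length(w)
  if (ng + nw < 3L) stop("need at least 3 voxels across the two masks")
  pooled <- sqrt(((ng - 1) * stats::var(g) + (nw - 1) * stats::var(w)) /
                   (ng + nw - 2))
  (mean(g) - mean(w)) / pooled
}

#' Agreement between two calibration routes
#'
#' Pearson R-squared plus Bland-Altman statistics for paired ROI means from
#' two methods: bias = mean difference, limits of agreement = bias +-
#' 1.96 SD(differences), and a two-sided one-sample t-test of zero bias.
#'
#' @param bbpc_phantom,bbpc_hct Paired numeric vectors (n >= 3).
#' @return List with `r_squared`, `bias`, `limits` (length 2), `bias_p`.
#' @export
method_agreement <- function(bbpc_phantom, bbpc_hct) {
  x <- as.double(bbpc_phantom); y <- as.double(bbpc_hct)
  if (length(x) != length(y)) stop("paired lists must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  diffs <- y - x
  bias <- mean(diffs)
  sd_d <- stats::sd(diffs)
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)^2
  bias_p <- if (sd_d == 0) {
    if (bias == 0) 1 else 0
  } else {
    stats::t.test(diffs)$p.value
  }
  list(r_squared = r2, bias = bias,
       limits = c(bias - 1.96 * sd_d, bias + 1.96 * sd_d), bias_p = bias_p)
}

#' Linear regression of a measurement on age
#'
#' Ordinary least squares with an optional additive sex covariate; reports
#' the age slope, intercept, and two-sided slope p-value.
#'
#' @param values Numeric outcomes (one per subject).
#' @param ages Ages in years (not all equal).
#' @param covariate_sex Optional binary/factor covariate.
#' @return List with `slope`, `intercept`, `p_value`.
#' @export
age_regression <- function(values, ages, covariate_sex = NULL) {
  values <- as.double(values); ages <- as.double(ages)
  if (length(values) != length(ages) || length(values) < 3L) {
    stop("need matched values and ages (n >= 3)")
  }
  if (stats::sd(ages) == 0) stop("constant ages: slope undefined")
  if (stats::sd(values) == 0) {
    return(list(slope = 0, intercept = values[1], p_value = 1))
  }
  df <- data.frame(v = values, age = ages)
  fml <- v ~ age
  if (!is.null(covariate_sex)) {
    df$sex <- covariate_sex
    if (length(unique(df$sex)) > 1L) fml <- v ~ age + sex
  }
  fit <- stats::lm(fml, data = df)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(stats::coef(fit)["age"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       p_value = unname(sm["age", "Pr(>|t|)"]))
}

#' Mean of fitted voxels in a region of interest
#'
#' @param map Map object, volume, or array.
#' @param mask Binary ROI.
#' @return Mean of finite in-mask values (`NaN` if none).
#' @export
roi_mean <- function(map, mask) {
  v <- .vals(map)[.as_mask(mask)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NaN)
  mean(v)
}
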