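# Calibration of arbitrary-unit M0 to absolute water content.
#
# Two routes:
#  * phantom: five D2O/H2O vials (40/30/20/10/0% D2O, 0.18 mM gadobutrol)
#    span a known 60-100% water scale; OLS of known water fraction on mean
#    vial M0 gives the mapping. A cohort-level quadratic-error correction
#    handles the scanner nonlinearity that inflates bright-vial signal.
#  * hematocrit: blood water content WC_blood = -0.271*Hct + 0.912 anchors a
#    pure rescaling such that the blood-ROI mean matches WC_blood.

#' Doped-phantom description
#'
#' @param masks List of 5 disjoint binary vial masks, ordered to match
#'   `d2o_fractions`.
#' @param d2o_fractions D2O volume fractions (default `c(.40,.30,.20,.10,0)`).
#' @param gadobutrol_mM Doping concentration metadata (default 0.18).
#' @return A `castrr_phantom_set`.
#' @export
phantom_set <- function(masks, d2o_fractions = c(0.40, 0.30, 0.20, 0.10, 0.00),
                        gadobutrol_mM = 0.18) {
  if (length(masks) != length(d2o_fractions)) {
    stop("need one mask per D2O fraction")
  }
  masks <- lapply(masks, .as_mask)
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) stop("phantom masks must be disjoint")
  structure(list(masks = masks, d2o_fractions = as.double(d2o_fractions),
                 water_fractions = 1 - as.double(d2o_fractions),
                 gadobutrol_mM = gadobutrol_mM),
            class = "castrr_phantom_set")
}

#' Blood-sample description
#'
#' @param mask Binary blood-vial mask.
#' @param mean_m0 Mean fitted M0 over the mask (filled by the pipeline when
#'   `NULL`).
#' @param hct Hematocrit fraction in (0, 1).
#' @return A `castrr_blood_sample` with `wc_blood` derived via
#'   [hct_blood_water()] when `hct` is given.
#' @export
blood_sample <- function(mask, mean_m0 = NULL, hct = NULL) {
  wc <- if (!is.null(hct)) hct_blood_water(hct) else NULL
  structure(list(mask = .as_mask(mask), mean_m0 = mean_m0, hct = hct,
                 wc_blood = wc),
            class = "castrr_blood_sample")
}

#' Per-vial mean M0
#'
#' Mean of fitted (finite) M0 values in each vial mask.
#'
#' @param m0 `castrr_m0_map`, `castrr_volume`, or array.
#' @param phantoms A [phantom_set()].
#' @param min_voxels Minimum fitted voxels per vial (default 10).
#' @return Numeric vector of 5 vial means, ordered as the phantom set.
#' @export
phantom_means <- function(m0, phantoms, min_voxels = 10L) {
  stopifnot(inherits(phantoms, "castrr_phantom_set"))
  vals <- .vals(m0)
  vapply(seq_along(phantoms$masks), function(i) {
    v <- vals[phantoms$masks[[i]]]
    v <- v[is.finite(v)]
    if (length(v) < min_voxels) {
      stop(sprintf("phantom vial %d: only %d fitted voxels (need >= %d)",
                   i, length(v), min_voxels))
    }
    mean(v)
  }, numeric(1))
}

#' Fit the phantom calibration line
#'
#' Ordinary least squares of known water fraction on mean vial M0.
#'
#' @param means Per-vial mean M0 (length >= 2, not all equal).
#' @param water_fractions Known vial water fractions (same length).
#' @return A `castrr_calibration_line` with `slope` (water fraction per M0
#'   unit), `intercept`, `r_squared`.
#' @export
fit_phantom_line <- function(means, water_fractions = seq(0.6, 1.0, by = 0.1)) {
  if (length(means) != length(water_fractions) || length(means) < 2L) {
    stop("need matched means and water fractions (>= 2)")
  }
  if (stats::sd(means) == 0) stop("degenerate phantom means: all identical")
  fit <- stats::lm(water_fractions ~ means)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    warning("phantom calibration slope is not positive; check vial ordering")
  }
  pred_max <- unname(stats::coef(fit)[1] + slope * max(means))
  if (is.finite(pred_max) && pred_max > 1.2) {
    warning(sprintf("calibration predicts %.3f at the brightest vial (> 1.2 sanity bound)",
                    pred_max))
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared),
            class = "castrr_calibration_line")
}

#' Cohort ratio regression for the quadratic phantom error
#'
#' Regresses the per-subject ratio `r_i = T_i / P_i` (brain-tissue mean M0
#' over phantom mean M0) on `P_i`. Under the scanner nonlinearity the vials'
#' signal grows quadratically with overall intensity while tissue grows
#' linearly, giving a negative slope `beta`; each subject's error term is
#' `Delta_i = beta * P_i^2`, to be subtracted from tissue and blood values
#' before normalization.
#'
#' @param cohort Data frame with columns `subject_id`, `tissue_mean_m0`,
#'   `phantom_mean_m0` (>= 3 rows, positive phantom means).
#' @return A `castrr_ratio_regression` with `alpha`, `beta`,
#'   `per_subject_error` (named by subject), `r_squared`.
#' @export
fit_ratio_regression <- function(cohort) {
  req <- c("subject_id", "tissue_mean_m0", "phantom_mean_m0")
  if (!all(req %in% names(cohort))) {
    stop("cohort must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(cohort) < 3L) {
    stop("cohort quadratic-error correction needs >= 3 subjects, got ", nrow(cohort))
  }
  P <- as.double(cohort$phantom_mean_m0)
  if (any(!is.finite(P)) || any(P <= 0)) stop("phantom means must be positive")
  r <- as.double(cohort$tissue_mean_m0) / P
  fit <- stats::lm(r ~ P)
  beta <- unname(stats::coef(fit)[2])
  delta <- beta * P^2
  names(delta) <- as.character(cohort$subject_id)
  structure(list(alpha = unname(stats::coef(fit)[1]), beta = beta,
                 per_subject_error = delta,
                 r_squared = suppressWarnings(summary(fit))$r.squared),
            class = "castrr_ratio_regression")
}

#' Subtract a subject's quadratic error term
#'
#' Shifts every brain-mask and blood-mask voxel value by `-delta_i` (the
#' error term is negative when `beta < 0`, so values increase); phantom
#' voxels are untouched. The blood sample's `mean_m0` is shifted likewise.
#'
#' @param m0 `castrr_m0_map` (or volume/array).
#' @param brain_mask Binary brain mask.
#' @param blood A [blood_sample()] with `mean_m0` set.
#' @param delta_i Scalar error term for this subject.
#' @return List with corrected `m0` and `blood`.
#' @export
apply_error_correction <- function(m0, brain_mask, blood, delta_i) {
  stopifnot(inherits(blood, "castrr_blood_sample"), is.finite(delta_i))
  vals <- .vals(m0)
  brain_mask <- .as_mask(brain_mask)
  sel <- (brain_mask | blood$mask) & is.finite(vals)
  vals[sel] <- vals[sel] - delta_i
  new_blood_mean <- blood$mean_m0 - delta_i
  if (!is.null(blood$mean_m0) && new_blood_mean <= 0) {
    stop("error correction drives blood mean M0 non-positive")
  }
  blood$mean_m0 <- new_blood_mean
  if (inherits(m0, "castrr_m0_map")) m0$values <- vals
  else if (inherits(m0, "castrr_volume")) m0$data <- vals
  else m0 <- vals
  list(m0 = m0, blood = blood)
}

#' Blood water content from hematocrit
#'
#' `WC_blood = -0.271 * Hct + 0.912` (grams of water per mL of blood, as a
#' fraction). Percent-style inputs (`hct > 1`) are divided by 100 with a
#' warning.
#'
#' @param hct Hematocrit fraction in (0, 1) (or percent in (1, 100]).
#' @return Blood water content fraction.
#' @export
hct_blood_water <- function(hct) {
  if (!is.numeric(hct) || length(hct) != 1L || !is.finite(hct)) {
    stop("hct must be a single finite number")
  }
  if (hct > 1 && hct <= 100) {
    warning("hct > 1 supplied; interpreting as percent and dividing by 100")
    hct <- hct / 100
  }
  if (hct < 0 || hct > 1) stop("hct out of range (0, 1): ", hct)
  -0.271 * hct + 0.912
}

#' Water-content map via the phantom calibration line
#'
#' Evaluates `WC = slope * M0 + intercept` at every fitted voxel.
#'
#' @param m0 `castrr_m0_map` (or volume/array).
#' @param line A `castrr_calibration_line`.
#' @return A `castrr_wc_map` (`values` in water fraction).
#' @export
normalize_phantom <- function(m0, line) {
  stopifnot(inherits(line, "castrr_calibration_line"))
  vals <- .vals(m0)
  wc <- line$slope * vals + line$intercept
  n_high <- sum(wc > 1.2, na.rm = TRUE)
  if (n_high > 0) {
    message(n_high, " voxels exceed the 1.2 water-fraction sanity bound")
  }
  structure(list(values = wc, method = "phantom"), class = "castrr_wc_map")
}

#' Water-content map via hematocrit normalization
#'
#' Pure rescaling (no offset): `WC = M0 * wc_blood / mean(M0_blood)`, so the
#' blood-ROI mean water content equals the hematocrit-derived value by
#' construction.
#'
#' @param m0 `castrr_m0_map` (or volume/array).
#' @param blood A [blood_sample()] with positive `mean_m0` and `wc_blood`.
#' @return A `castrr_wc_map`.
#' @export
normalize_hct <- function(m0, blood) {
  stopifnot(inherits(blood, "castrr_blood_sample"))
  if (is.null(blood$mean_m0) || !is.finite(blood$mean_m0) || blood$mean_m0 <= 0) {
    stop("blood mean M0 must be positive")
  }
  if (is.null(blood$wc_blood)) stop("blood sample lacks wc_blood (supply hct)")
  vals <- .vals(m0)
  wc <- vals * (blood$wc_blood / blood$mean_m0)
  structure(list(values = wc, method = "hct"), class = "castrr_wc_map")
}
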