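# Saturation-recovery fitting: S(TR) = M0 * (1 - exp(-TR/T1)).
#
# With a 90-degree flip and spoiling, the multi-TR FLASH-GRE signal follows
# saturation recovery; TE is minimized at acquisition so T2* decay is
# ignored. For fixed T1 the least-squares M0 is closed-form,
#   M0*(T1) = sum(s * f) / sum(f^2),  f = 1 - exp(-TR/T1),
# so the bounded 2-parameter least-squares problem reduces to a 1-D profile
# minimization over T1, solved by a coarse log-grid bracket followed by
# golden-section refinement. This is exact for the same objective and
# vectorizes over voxels.

#' Multi-TR series container
#'
#' @param volumes List of `castrr_volume`s on a common grid, one per TR.
#' @param tr_ms Strictly increasing positive repetition times, ms; same
#'   length as `volumes` (at least 3).
#' @param te_ms Echo time metadata, ms (default 1.9).
#' @return A `castrr_tr_series` object.
#' @export
tr_series <- function(volumes, tr_ms, te_ms = 1.9) {
  tr_ms <- as.double(tr_ms)
  if (length(volumes) != length(tr_ms) || length(tr_ms) < 3L) {
    stop("need >= 3 volumes with one TR each")
  }
  if (any(tr_ms <= 0) || any(diff(tr_ms) <= 0)) {
    stop("tr_ms must be positive and strictly increasing")
  }
  d <- dim(.vals(volumes[[1]]))
  for (v in volumes) {
    if (!identical(dim(.vals(v)), d)) stop("all volumes must share one grid")
  }
  structure(list(volumes = volumes, tr_ms = tr_ms, te_ms = as.double(te_ms)),
            class = "castrr_tr_series")
}

# Vectorized profile solver. S: n x J signal matrix, tr_s: J recovery times
# in seconds. Returns list(m0, t1, rms) of length n.
.fit_recovery_matrix <- function(S, tr_s, t1_bounds = c(0.05, 5),
                                 n_coarse = 48L, tol = 1e-7, max_iter = 60L) {
  n <- nrow(S)
  J <- ncol(S)
  ss_tot <- rowSums(S^2)

  ssr_at <- function(t1) {
    # t1: length-n vector; returns SSR and keeps numerator for M0 recovery
    F <- 1 - exp(-outer(1 / t1, tr_s))        # n x J
    num <- rowSums(S * F)
    den <- rowSums(F * F)
    m0 <- num / den
    list(ssr = ss_tot - num^2 / den, m0 = m0)
  }

  # coarse bracket on a log grid (profile SSR is smooth; grid localises the
  # global minimum, golden section refines within the bracketing cell pair)
  grid <- exp(seq(log(t1_bounds[1]), log(t1_bounds[2]), length.out = n_coarse))
  F <- 1 - exp(-outer(tr_s, 1 / grid))        # J x n_coarse
  num <- S %*% F                              # n x n_coarse
  den <- colSums(F * F)
  ssr_grid <- ss_tot - sweep(num^2, 2L, den, "/")
  best <- max.col(-ssr_grid, ties.method = "first")
  lo <- grid[pmax(best - 1L, 1L)]
  hi <- grid[pmin(best + 1L, n_coarse)]

  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- ssr_at(c1)$ssr; fd <- ssr_at(d1)$ssr
  for (it in seq_len(max_iter)) {
    take_left <- fc < fd
    b <- ifelse(take_left, d1, b)
    a <- ifelse(take_left, a, c1)
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    # only one of the two interior points is new each iteration, but the
    # vectorized form recomputes both; still cheap (two n x J exp calls)
    fc <- ssr_at(c1)$ssr; fd <- ssr_at(d1)$ssr
    if (max((b - a) / pmax(a, .Machine$double.eps)) < tol) break
  }
  t1 <- (a + b) / 2
  # Newton polish on the profile stationarity condition. The SSR itself
  # loses precision to cancellation near the optimum (SSR -> 0 on
  # model-consistent data), but the stationarity function
  #   u(T1) = 2 N N' D - N^2 D',  N = sum(s f), D = sum(f^2),
  # and its derivative are cancellation-free, so a few Newton steps reach
  # ~1e-12 relative precision and make the solver scale-invariant in
  # practice (u scales uniformly with the square of the signal scale).
  for (nw in 1:3) {
    E <- exp(-outer(1 / t1, tr_s))              # n x J
    A <- matrix(tr_s, nrow = n, ncol = J, byrow = TRUE)
    f <- 1 - E
    f1 <- -E * A / t1^2
    f2 <- E * (2 * A / t1^3 - A^2 / t1^4)
    N <- rowSums(S * f);  N1 <- rowSums(S * f1); N2 <- rowSums(S * f2)
    D <- rowSums(f * f);  D1 <- 2 * rowSums(f * f1)
    D2 <- 2 * rowSums(f1 * f1 + f * f2)
    u <- 2 * N * N1 * D - N^2 * D1
    u1 <- 2 * (N1^2 + N * N2) * D - N^2 * D2
    step <- ifelse(is.finite(u / u1), u / u1, 0)
    t1 <- pmin(pmax(t1 - step, lo), hi)   # coarse bracket, not the
  }                                        # wander-limited golden interval
  t1 <- pmin(pmax(t1, t1_bounds[1]), t1_bounds[2])
  fin <- ssr_at(t1)
  m0 <- pmax(fin$m0, 0)
  ssr <- pmax(fin$ssr, 0)
  list(m0 = m0, t1 = t1, rms = sqrt(ssr / J))
}

#' Fit the recovery model at a single voxel
#'
#' Bounded least squares of `S = M0 * (1 - exp(-TR/T1))` for one signal
#' vector. The (TR, signal) pairing, not their order, determines the fit.
#'
#' @param signals Numeric signal values, one per TR.
#' @param tr_ms Repetition times in ms, same length as `signals`.
#' @param t1_bounds T1 search bounds in seconds (default `c(0.05, 5)`).
#' @return List with `m0`, `t1_s`, `rms` (root-mean-square residual) and
#'   `ok`. Degenerate input (fewer than 3 finite signals, or no positive
#'   signal) yields `ok = FALSE` with `NaN` estimates.
#' @export
fit_recovery_voxel <- function(signals, tr_ms, t1_bounds = c(0.05, 5)) {
  keep <- is.finite(signals)
  if (sum(keep) < 3L || max(signals[keep]) <= 0) {
    return(list(m0 = NaN, t1_s = NaN, rms = NaN, ok = FALSE))
  }
  fit <- .fit_recovery_matrix(matrix(signals[keep], nrow = 1L),
                              tr_ms[keep] / 1000, t1_bounds = t1_bounds)
  list(m0 = fit$m0, t1_s = fit$t1, rms = fit$rms, ok = is.finite(fit$m0))
}

#' Fit the recovery model voxel-wise over a volume series
#'
#' Every in-mask voxel is fitted independently. Voxels whose maximum signal
#' falls below `noise_floor_mult` times the background noise level are not
#' fitted; failed and unfitted voxels are `NaN` in all output maps and are
#' thereby excluded from downstream ROI means.
#'
#' @param series A [tr_series()].
#' @param mask Binary volume (array or `castrr_volume`) selecting voxels to fit.
#' @param noise_floor_mult Noise-floor multiple (default 3).
#' @param background_sd Background noise SD; when `NULL`, estimated as a
#'   robust SD of out-of-mask voxels of the longest-TR volume.
#' @param t1_bounds T1 bounds in seconds.
#' @return List with `m0` (`castrr_m0_map`: `values`, `fit_mask`,
#'   `residual_rms`), `t1` (`castrr_t1_map`), and counts `n_fitted`,
#'   `n_failed`, `n_below_floor`.
#' @export
fit_recovery_volume <- function(series, mask, noise_floor_mult = 3,
                                background_sd = NULL, t1_bounds = c(0.05, 5)) {
  stopifnot(inherits(series, "castrr_tr_series"))
  mask <- .as_mask(mask)
  d <- dim(.vals(series$volumes[[1]]))
  if (!identical(dim(mask), d)) stop("mask must be on the series grid")
  idx <- which(mask)
  if (!length(idx)) stop("empty mask: nothing to fit")

  S <- vapply(series$volumes, function(v) .vals(v)[idx], numeric(length(idx)))
  if (is.null(background_sd)) {
    bg <- .vals(series$volumes[[length(series$volumes)]])[!mask]
    bg <- bg[is.finite(bg)]
    background_sd <- if (length(bg) > 10L) stats::mad(bg, center = 0) else 0
  }
  smax <- apply(S, 1L, max)
  fit_ok <- is.finite(smax) & smax > noise_floor_mult * background_sd & smax > 0 &
    rowSums(is.finite(S)) == ncol(S)

  m0 <- t1 <- rms <- array(NaN, dim = d)
  n_failed <- 0L
  if (any(fit_ok)) {
    fit <- .fit_recovery_matrix(S[fit_ok, , drop = FALSE], series$tr_ms / 1000,
                                t1_bounds = t1_bounds)
    good <- is.finite(fit$m0) & is.finite(fit$t1)
    n_failed <- sum(!good)
    tgt <- idx[fit_ok]
    m0[tgt[good]] <- fit$m0[good]
    t1[tgt[good]] <- fit$t1[good]
    rms[tgt[good]] <- fit$rms[good]
  }
  fit_mask <- array(FALSE, dim = d)
  fit_mask[which(is.finite(m0))] <- TRUE

  list(
    m0 = structure(list(values = m0, fit_mask = fit_mask, residual_rms = rms),
                   class = "castrr_m0_map"),
    t1 = structure(list(values = t1), class = "castrr_t1_map"),
    n_fitted = sum(fit_mask),
    n_failed = n_failed,
    n_below_floor = sum(!fit_ok)
  )
}

#' @export
print.castrr_m0_map <- function(x, ...) {
  cat(sprintf("<castrr_m0_map> %s, %d fitted voxels, median M0 %.4g\n",
              paste(dim(x$values), collapse = "x"), sum(x$fit_mask),
              stats::median(x$values[x$fit_mask])))
  invisible(x)
}
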