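# EM bias-field correction.
#
# Model: within the estimation mask, log-intensity = smooth polynomial field
# + K-component Gaussian mixture. EM alternates posterior memberships
# (E-step) with closed-form mixture updates and a weighted least-squares
# polynomial fit of the field (M-step). The field is the exponential of a
# tensor Legendre polynomial of total degree <= `order` on coordinates
# rescaled to [-1, 1] over the mask bounding box (for conditioning), and is
# normalized to mean 1 over the mask, which also makes the estimate
# invariant to global intensity scaling. Phantom-vial and blood voxels are
# excluded from the mask so bright vials cannot attenuate the field; the
# correction itself is applied to the entire volume.

# Legendre polynomials P0..Pn evaluated by recurrence; x in [-1, 1]-ish.
.legendre_1d <- function(x, n) {
  P <- matrix(0, nrow = length(x), ncol = n + 1L)
  P[, 1] <- 1
  if (n >= 1L) P[, 2] <- x
  if (n >= 2L) for (k in 2:n) {
    P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
  }
  P
}

# First derivatives of P0..Pn (same recurrence differentiated).
.legendre_1d_deriv <- function(x, n) {
  P <- .legendre_1d(x, n)
  D <- matrix(0, nrow = length(x), ncol = n + 1L)
  if (n >= 1L) D[, 2] <- 1
  if (n >= 2L) for (k in 2:n) {
    D[, k + 1L] <- ((2 * k - 1) * (P[, k] + x * D[, k]) - (k - 1) * D[, k - 1L]) / k
  }
  D
}

# Tensor Legendre basis of total degree <= order on n x 3 coordinates.
.poly_basis <- function(coords, order, bbox) {
  u <- lapply(1:3, function(a) {
    lo <- bbox[1, a]; hi <- bbox[2, a]
    if (hi > lo) 2 * (coords[, a] - lo) / (hi - lo) - 1 else coords[, a] * 0
  })
  Px <- .legendre_1d(u[[1]], order)
  Py <- .legendre_1d(u[[2]], order)
  Pz <- .legendre_1d(u[[3]], order)
  combos <- .basis_combos(order)
  B <- matrix(0, nrow = nrow(coords), ncol = nrow(combos))
  for (i in seq_len(nrow(combos))) {
    B[, i] <- Px[, combos$a[i] + 1L] * Py[, combos$b[i] + 1L] * Pz[, combos$c[i] + 1L]
  }
  B
}

# Evaluate the fitted log-polynomial over arbitrary coordinates. Inside the
# estimation bounding box this is the exact tensor-Legendre expansion; with
# method "taylor", points beyond the box are continued to first order from
# the nearest box face (value + gradient), which keeps the smooth trend of
# the field without amplifying weakly-constrained high-order curvature where
# there were no data (e.g. at the phantom vials above the head).
.eval_log_field <- function(coef, coords, bbox, order,
                            method = c("taylor", "polynomial")) {
  method <- match.arg(method)
  half <- (bbox[2, ] - bbox[1, ]) / 2
  half[half == 0] <- 1
  if (method == "polynomial") {
    return(as.double(.poly_basis(coords, order, bbox) %*% coef))
  }
  cl <- coords
  for (a in 1:3) cl[, a] <- pmin(pmax(coords[, a], bbox[1, a]), bbox[2, a])
  u <- vapply(1:3, function(a) (cl[, a] - bbox[1, a]) / half[a] - 1,
              numeric(nrow(coords)))
  du <- vapply(1:3, function(a) (coords[, a] - cl[, a]) / half[a],
               numeric(nrow(coords)))
  P <- lapply(1:3, function(a) .legendre_1d(u[, a], order))
  D <- lapply(1:3, function(a) .legendre_1d_deriv(u[, a], order))
  combos <- .basis_combos(order)
  val <- numeric(nrow(coords))
  for (i in seq_len(nrow(combos))) {
    a <- combos$a[i] + 1L; b <- combos$b[i] + 1L; cc <- combos$c[i] + 1L
    base <- P[[1]][, a] * P[[2]][, b] * P[[3]][, cc]
    grad <- D[[1]][, a] * P[[2]][, b] * P[[3]][, cc] * du[, 1] +
            P[[1]][, a] * D[[2]][, b] * P[[3]][, cc] * du[, 2] +
            P[[1]][, a] * P[[2]][, b] * D[[3]][, cc] * du[, 3]
    val <- val + coef[i] * (base + grad)
  }
  val
}

.basis_combos <- function(order) {
  combos <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  combos <- combos[rowSums(combos) <= order, , drop = FALSE]
  combos[order(rowSums(combos), combos$a, combos$b, combos$c), , drop = FALSE]
}

.grid_coords <- function(d, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(prod(d))
  k <- (subset - 1L) %/% (d[1] * d[2])
  r <- (subset - 1L) %% (d[1] * d[2])
  cbind(x = r %% d[1] + 1L, y = r %/% d[1] + 1L, z = k + 1L)
}

#' Estimate a multiplicative bias field from an M0 map
#'
#' EM estimation of smooth receive-coil inhomogeneity: a 4th-order
#' log-polynomial field plus a `K`-component Gaussian mixture of residual
#' log-intensities. Only voxels in `estimation_mask` (which must exclude the
#' phantom vials and blood sample) influence the field.
#'
#' @param m0 `castrr_m0_map`, `castrr_volume`, or 3-D array of positive
#'   intensities.
#' @param estimation_mask Binary volume of voxels driving the estimate.
#' @param K Mixture components (default 6).
#' @param order Total polynomial degree (default 4; 35 basis terms).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param flatten_labels Optional integer label volume (e.g. T1-derived
#'   tissue classes). When given, in-mask intensities are divided by their
#'   class means before the EM, removing anatomical contrast that a flexible
#'   polynomial could otherwise absorb; the returned field still applies to
#'   the original intensities. Because the T1 map is invariant to
#'   multiplicative bias, T1-derived classes are a bias-free source of
#'   anatomy for this purpose.
#' @param extrapolation Field evaluation beyond the estimation bounding box:
#'   `"taylor"` (default) continues the log-polynomial to first order from
#'   the nearest box face, avoiding amplification of weakly-constrained
#'   curvature where there were no data; `"polynomial"` evaluates the raw
#'   polynomial everywhere.
#' @return List with `bias` (`castrr_bias_field`: `log_coefficients`, `field`
#'   array over the whole grid normalized to in-mask mean 1,
#'   `estimation_mask`, `bbox`, `order`) and `mixture` (`castrr_mixture`).
#' @export
estimate_bias <- function(m0, estimation_mask, K = 6L, order = 4L,
                          tol = 1e-5, max_iter = 100L, flatten_labels = NULL,
                          extrapolation = c("taylor", "polynomial")) {
  extrapolation <- match.arg(extrapolation)
  vals <- .vals(m0)
  if (!is.null(flatten_labels)) {
    lab <- .vals(flatten_labels)
    if (!identical(dim(lab), dim(vals))) stop("flatten_labels must match the M0 grid")
    emask <- .as_mask(estimation_mask)
    vals_f <- vals
    for (cl in setdiff(sort(unique(lab[emask])), 0)) {
      sel <- lab == cl & emask & is.finite(vals) & vals > 0
      if (sum(sel) >= 20L) vals_f[sel] <- vals[sel] / mean(vals[sel])
    }
    vals <- vals_f
  }
  mask <- .as_mask(estimation_mask)
  if (!identical(dim(mask), dim(vals))) stop("mask must match the M0 grid")
  idx <- which(mask & is.finite(vals) & vals > 0)
  n_coef <- choose(order + 3L, 3L)
  if (length(idx) < 10L * n_coef) {
    stop("estimation mask too small: need >= ", 10L * n_coef,
         " usable voxels, got ", length(idx))
  }
  d <- dim(vals)
  coords <- .grid_coords(d, idx)
  bbox <- rbind(lo = apply(coords, 2L, min), hi = apply(coords, 2L, max))
  B <- .poly_basis(coords, order, bbox)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) stop("degenerate mask geometry: singular polynomial design")

  y <- log(vals[idx])
  n <- length(y)

  # init: means at fixed in-mask quantiles, pooled SD, equal weights, flat field
  qs <- if (K == 6L) c(.10, .25, .40, .60, .75, .90) else seq(0.05, 0.95, length.out = K)
  mu <- as.double(stats::quantile(y, qs))
  sg <- rep(stats::sd(y), K)
  w <- rep(1 / K, K)
  var_floor <- 1e-4 * stats::var(y)
  f <- rep(0, n)
  coef <- rep(0, ncol(B))
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    r <- y - f
    # E-step
    dens <- vapply(seq_len(K), function(k) {
      w[k] * stats::dnorm(r, mu[k], sg[k])
    }, numeric(n))
    rowsum_d <- rowSums(dens) + .Machine$double.xmin
    gamma <- dens / rowsum_d
    ll <- sum(log(rowsum_d))

    # M-step: mixture
    nk <- colSums(gamma)
    w <- nk / n
    mu <- colSums(gamma * r) / nk
    sg2 <- colSums(gamma * (r - rep(mu, each = n))^2) / nk
    sg <- sqrt(pmax(sg2, var_floor))

    # M-step: field by precision-weighted least squares
    prec <- gamma %*% (1 / sg^2)               # n x 1 total precision
    target <- (gamma %*% (mu / sg^2)) / prec   # posterior-expected mean
    resid <- y - target
    wts <- as.double(prec)
    bad <- !is.finite(resid) | !is.finite(wts)
    if (any(bad)) { resid[bad] <- 0; wts[bad] <- 0 }
    coef <- qr.coef(qr(B * sqrt(wts)), resid * sqrt(wts))
    f <- as.double(B %*% coef)
    # identifiability: keep the field mean-zero in log domain, absorb the
    # shift into the mixture means
    shift <- mean(f)
    f <- f - shift
    coef[1] <- coef[1] - shift
    mu <- mu + shift

    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  log_field <- array(.eval_log_field(coef, .grid_coords(d), bbox, order,
                                     method = extrapolation), dim = d)
  field <- exp(log_field)
  norm <- mean(field[idx])
  field <- field / norm
  coef[1] <- coef[1] - log(norm)

  bias <- structure(
    list(log_coefficients = as.double(coef), field = field,
         estimation_mask = mask, bbox = bbox, order = as.integer(order)),
    class = "castrr_bias_field"
  )
  mixture <- structure(
    list(K = as.integer(K), means = mu, sds = sg, weights = w,
         loglik = ll_old, n_iter = it, converged = converged),
    class = "castrr_mixture"
  )
  list(bias = bias, mixture = mixture)
}

#' Remove a bias field from an M0 map
#'
#' Divides voxel values by the multiplicative field everywhere on the grid,
#' including vial and blood voxels that were excluded from estimation.
#'
#' @param m0 `castrr_m0_map`, `castrr_volume`, or 3-D array.
#' @param bias `castrr_bias_field` (or bare field array) on the same grid.
#' @return Object of the same kind as `m0` with corrected values.
#' @export
apply_bias <- function(m0, bias) {
  field <- if (inherits(bias, "castrr_bias_field")) bias$field else .vals(bias)
  vals <- .vals(m0)
  if (!identical(dim(field), dim(vals))) stop("field must match the M0 grid")
  if (any(field <= 0)) stop("bias field must be strictly positive")
  out_vals <- vals / field
  if (inherits(m0, "castrr_m0_map")) {
    m0$values <- out_vals
    m0
  } else if (inherits(m0, "castrr_volume")) {
    m0$data <- out_vals
    m0
  } else {
    out_vals
  }
}

#' @export
print.castrr_bias_field <- function(x, ...) {
  rng <- range(x$field)
  cat(sprintf("<castrr_bias_field> order %d (%d terms), field range [%.3f, %.3f]\n",
              x$order, length(x$log_coefficients), rng[1], rng[2]))
  invisible(x)
}
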