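# EM tissue segmentation and ROI geometry.

#' EM Gaussian-mixture tissue segmentation
#'
#' Fits an `n_classes`-component 1-D Gaussian mixture to in-mask intensities
#' and assigns tissue labels by mean-intensity rank under a contrast
#' convention: on T1-weighted images WM > GM > CSF; on proton-density /
#' water-content images CSF > GM > WM.
#'
#' @param intensity `castrr_volume` or 3-D array.
#' @param brain_mask Binary brain mask.
#' @param n_classes Number of classes (default 3: GM, WM, CSF).
#' @param contrast `"t1w"` or `"pd"` intensity ordering convention.
#' @param tol Relative log-likelihood tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param init_means Optional initial component means (any order; the final
#'   tissue assignment depends only on the converged mean ranks).
#' @return A `castrr_tissue_labels`: `labels` (0 background, 1 GM, 2 WM,
#'   3 CSF) and `posteriors` (list of per-class arrays, in-mask rows sum
#'   to 1).
#' @export
em_segment <- function(intensity, brain_mask, n_classes = 3L,
                       contrast = c("t1w", "pd"), tol = 1e-6, max_iter = 500L,
                       init_means = NULL) {
  contrast <- match.arg(contrast)
  vals <- .vals(intensity)
  mask <- .as_mask(brain_mask)
  if (!identical(dim(mask), dim(vals))) stop("mask must match the intensity grid")
  idx <- which(mask & is.finite(vals))
  if (!length(idx)) stop("empty brain mask")
  y <- vals[idx]
  n <- length(y)
  K <- as.integer(n_classes)
  if (n < 10L * (3L * K)) stop("too few in-mask voxels for ", K, " classes")
  if (stats::sd(y) == 0) {
    stop("class collapse: single-intensity image; use fewer classes")
  }

  mu <- if (is.null(init_means)) {
    as.double(stats::quantile(y, (seq_len(K) - 0.5) / K))
  } else {
    stopifnot(length(init_means) == K)
    as.double(init_means)
  }
  sg <- rep(stats::sd(y), K)
  w <- rep(1 / K, K)
  var_floor <- 1e-4 * stats::var(y)
  ll_old <- -Inf
  gamma <- NULL

  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] * stats::dnorm(y, mu[k], sg[k]),
                   numeric(n))
    rs <- rowSums(dens) + .Machine$double.xmin
    gamma <- dens / rs
    ll <- sum(log(rs))
    nk <- colSums(gamma)
    w <- nk / n
    if (any(w < 1e-4)) {
      stop("class collapse during EM (component weight < 1e-4); try fewer classes")
    }
    mu <- colSums(gamma * y) / nk
    sg <- sqrt(pmax(colSums(gamma * (y - rep(mu, each = n))^2) / nk, var_floor))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }

  # map components to tissue codes by ascending mean intensity
  ord <- order(mu)                      # ord[r] = component with rank r
  code_by_rank <- if (contrast == "t1w") c(3L, 1L, 2L) else c(2L, 1L, 3L)
  if (K != 3L) code_by_rank <- seq_len(K)  # generic: label = intensity rank
  comp_code <- integer(K)
  comp_code[ord] <- code_by_rank

  hard <- comp_code[max.col(gamma, ties.method = "first")]
  labels <- array(0L, dim = dim(vals))
  labels[idx] <- hard
  posteriors <- lapply(sort(unique(comp_code)), function(code) {
    p <- array(0, dim = dim(vals))
    p[idx] <- rowSums(gamma[, which(comp_code == code), drop = FALSE])
    p
  })
  names(posteriors) <- if (K == 3L) c("gm", "wm", "csf")[sort(unique(comp_code))] else
    paste0("class", sort(unique(comp_code)))

  structure(list(labels = labels, posteriors = posteriors,
                 means = mu, sds = sg, weights = w, contrast = contrast),
            class = "castrr_tissue_labels")
}

.shift2d <- function(m, dx, dy) {
  # logical 2-D shift with FALSE padding
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  xs <- seq_len(nr) - dx
  ys <- seq_len(nc) - dy
  okx <- xs >= 1 & xs <= nr
  oky <- ys >= 1 & ys <= nc
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Per-slice morphological erosion of a mask
#'
#' Erodes each axial (z) slice in 2-D. The default structuring element is the
#' 3x3 cross (4-connected), applied `pixels` times; `shape = "disk"` instead
#' applies one erosion with a Euclidean disk of radius `pixels`. Erosion
#' never grows a mask and may empty it (with a warning).
#'
#' @param mask Binary volume.
#' @param pixels Erosion radius in pixels (default 2).
#' @param shape `"cross"` (iterated 4-connected) or `"disk"`.
#' @return Eroded logical array.
#' @export
erode_roi <- function(mask, pixels = 2L, shape = c("cross", "disk")) {
  shape <- match.arg(shape)
  m <- .as_mask(mask)
  d <- dim(m)
  offsets <- if (shape == "cross") {
    list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    g <- expand.grid(dx = -pixels:pixels, dy = -pixels:pixels)
    g <- g[g$dx^2 + g$dy^2 <= pixels^2, ]
    lapply(seq_len(nrow(g)), function(i) c(g$dx[i], g$dy[i]))
  }
  n_pass <- if (shape == "cross") pixels else 1L
  out <- m
  for (z in seq_len(d[3])) {
    sl <- out[, , z]
    for (p in seq_len(n_pass)) {
      acc <- sl
      for (off in offsets) {
        acc <- acc & .shift2d(sl, off[1], off[2])
      }
      sl <- acc
    }
    out[, , z] <- sl
  }
  if (any(m) && !any(out)) warning("erosion emptied the mask")
  out
}

#' Restrict a mask to its centermost slices
#'
#' Keeps the `n` slices centered on the midpoint of the mask's slice extent
#' (midpoint = floor of the extent mean; ties resolve toward the lower
#' slice), zeroing all others. Matches the analysis convention of using only
#' the centermost slices where segmentation is reliable.
#'
#' @param brain_mask Binary volume spanning at least `n` slices.
#' @param n Number of slices to keep (default 10).
#' @return Logical array restricted to the selected slices.
#' @export
select_center_slices <- function(brain_mask, n = 10L) {
  m <- .as_mask(brain_mask)
  present <- which(apply(m, 3L, any))
  if (!length(present)) stop("empty brain mask")
  lo <- min(present); hi <- max(present)
  span <- hi - lo + 1L
  if (span < n) {
    stop("brain mask spans ", span, " slices; cannot select ", n, " central slices")
  }
  mid <- floor((lo + hi) / 2)
  start <- mid - floor(n / 2) + 1L
  keep <- start:(start + n - 1L)
  out <- m
  out[, , setdiff(seq_len(dim(m)[3]), keep)] <- FALSE
  out
}
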