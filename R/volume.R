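# VolumeImage container and grid operations.

#' Construct a volume image
#'
#' The basic in-memory container: a 3-D scalar array plus voxel geometry.
#' Axis order is (x, y, z) with z the slice axis; all per-slice operations in
#' the package act along the third dimension.
#'
#' @param data 3-D numeric array.
#' @param voxel_size Positive length-3 numeric, voxel edge lengths in mm.
#' @param orientation Three-letter axis-order code (default `"RAS"`).
#' @param units Free-text unit tag; `"labels"`/`"mask"` marks discrete volumes
#'   so that [resample_to()] can refuse intensity interpolation on them.
#' @return A `castrr_volume` list with fields `data`, `voxel_size`,
#'   `orientation`, `units`.
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), orientation = "RAS", units = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3-D array")
  }
  if (any(dim(data) < 1L)) stop("volume dimensions must all be >= 1")
  voxel_size <- as.double(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive numbers")
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         orientation = as.character(orientation), units = as.character(units)),
    class = "castrr_volume"
  )
}

#' @export
print.castrr_volume <- function(x, ...) {
  cat(sprintf("<castrr_volume> %s, voxels %.3gx%.3gx%.3g mm, orientation %s%s\n",
              paste(dim(x$data), collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$orientation,
              if (nzchar(x$units)) paste0(", units ", x$units) else ""))
  invisible(x)
}

#' @export
dim.castrr_volume <- function(x) dim(x$data)

# Accept either a castrr_volume, a map object with $values, or a bare array.
.vals <- function(x) {
  if (inherits(x, "castrr_volume")) return(x$data)
  if (is.list(x) && !is.null(x$values)) return(x$values)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a 3-D array, castrr_volume, or map object with $values")
}

.as_mask <- function(x) {
  v <- .vals(x)
  m <- v != 0 & !is.na(v)
  dim(m) <- dim(v)
  m
}

.same_grid <- function(a, b) identical(dim(.vals(a)), dim(.vals(b)))

.is_label_volume <- function(vol) {
  inherits(vol, "castrr_volume") && vol$units %in% c("labels", "mask")
}

#' Resample a volume onto a reference grid
#'
#' Axis-aligned resampling under the shared-origin convention: voxel centre
#' `i` (1-based) along axis `a` lies at world coordinate `(i - 0.5) *
#' voxel_size[a]`. Intended for matched acquisitions that differ only in
#' sampling density (e.g. anatomical volumes resampled to the multi-TR slice
#' grid); full registration is out of scope.
#'
#' @param reference `castrr_volume` defining the output grid.
#' @param moving `castrr_volume` to resample.
#' @param mode `"linear"` (trilinear, intensities) or `"nearest"` (labels).
#' @return A `castrr_volume` on the reference grid carrying the moving
#'   volume's units.
#' @export
resample_to <- function(reference, moving, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "castrr_volume"), inherits(moving, "castrr_volume"))
  if (mode == "linear" && .is_label_volume(moving)) {
    stop("labels require nearest-neighbour resampling")
  }
  rd <- dim(reference$data)
  md <- dim(moving$data)

  # continuous (1-based, voxel-centre) index of each reference centre in the
  # moving grid, per axis
  idx <- lapply(1:3, function(a) {
    world <- (seq_len(rd[a]) - 0.5) * reference$voxel_size[a]
    i <- world / moving$voxel_size[a] + 0.5
    pmin(pmax(i, 1), md[a])
  })

  out <- if (mode == "nearest") {
    near <- lapply(1:3, function(a) as.integer(round(idx[[a]])))
    moving$data[as.matrix(expand.grid(near[[1]], near[[2]], near[[3]]))]
  } else {
    lo <- lapply(1:3, function(a) pmin(floor(idx[[a]]), md[a] - ifelse(md[a] > 1, 1, 0)))
    fr <- lapply(1:3, function(a) idx[[a]] - lo[[a]])
    g <- expand.grid(i = seq_len(rd[1]), j = seq_len(rd[2]), k = seq_len(rd[3]))
    acc <- numeric(nrow(g))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- pmin(lo[[1]][g$i] + dx, md[1])
      jj <- pmin(lo[[2]][g$j] + dy, md[2])
      kk <- pmin(lo[[3]][g$k] + dz, md[3])
      w <- (if (dx == 1) fr[[1]][g$i] else 1 - fr[[1]][g$i]) *
           (if (dy == 1) fr[[2]][g$j] else 1 - fr[[2]][g$j]) *
           (if (dz == 1) fr[[3]][g$k] else 1 - fr[[3]][g$k])
      acc <- acc + w * moving$data[cbind(ii, jj, kk)]
    }
    acc
  }
  volume_image(array(out, dim = rd), voxel_size = reference$voxel_size,
               orientation = reference$orientation, units = moving$units)
}
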