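#' 3D scalar volume with physical geometry
#'
#' The basic image/mask carrier of the package: a 3D array of intensities
#' (dimensionless after [normalize_intensity()]) together with the voxel
#' spacing (mm per voxel, per axis), the world origin (mm) and a mask flag.
#' Axis order is (x, y, z) with x the fastest-varying (R column-major) index;
#' voxel coordinates are 0-based throughout the package.
#'
#' @param data 3D numeric array, every dimension at least 2.
#' @param spacing numeric length-3, strictly positive, in mm.
#' @param origin numeric length-3 world offset in mm.
#' @param is_mask logical; if `TRUE`, values must be 0/1 (they are validated,
#'   not coerced; use [read_volume()] with `kind = "mask"` to binarize).
#' @return an object of class `lw_volume`.
#' @examples
#' v <- lw_volume(array(runif(4^3), c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' dim(v)
#' @export
lw_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      is_mask = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("every volume dimension must be >= 2", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  storage.mode(data) <- "double"
  if (isTRUE(is_mask) && !all(data %in% c(0, 1)))
    stop("mask volumes must contain only 0/1 values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 is_mask = isTRUE(is_mask)),
            class = "lw_volume")
}

#' @export
dim.lw_volume <- function(x) dim(x$data)

#' @export
as.array.lw_volume <- function(x, ...) x$data

#' @export
print.lw_volume <- function(x, ...) {
  cat(sprintf("<lw_volume%s> %s voxels, spacing %s mm, origin %s mm, range [%.4g, %.4g]\n",
              if (x$is_mask) " mask" else "",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

# accept either an lw_volume or a bare 3D array; return the array
vol_data <- function(v) {
  if (inherits(v, "lw_volume")) v$data
  else if (is.array(v) && length(dim(v)) == 3L) v
  else stop("expected an lw_volume or a 3D array", call. = FALSE)
}

# rebuild a volume with new data, keeping geometry
vol_like <- function(data, template, is_mask = NULL) {
  if (inherits(template, "lw_volume"))
    lw_volume(data, template$spacing, template$origin,
              is_mask %||% template$is_mask)
  else data
}

#' Set of corresponding anatomical landmarks
#'
#' N continuous voxel-index triples (0-based) on either the fixed- or the
#' moving-image grid. Landmark files on disk default to the 1-based
#' convention used by DIR-Lab-style distributions; see [read_landmarks()].
#'
#' @param points numeric N x 3 matrix of 0-based voxel coordinates.
#' @param frame `"fixed"` or `"moving"`: which grid the indices refer to.
#' @return an object of class `lw_landmarks`.
#' @export
lw_landmarks <- function(points, frame = c("fixed", "moving")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 3L || !is.numeric(points) || any(!is.finite(points)))
    stop("landmarks must be a finite numeric N x 3 matrix", call. = FALSE)
  dimnames(points) <- NULL
  structure(list(points = points, frame = frame), class = "lw_landmarks")
}

#' @export
print.lw_landmarks <- function(x, ...) {
  cat(sprintf("<lw_landmarks> %d points on the %s grid\n",
              nrow(x$points), x$frame))
  invisible(x)
}

# all coordinates inside [0, dim-1] of the given grid
check_landmarks_in_grid <- function(lms, shape) {
  p <- lms$points
  ok <- p[, 1] >= 0 & p[, 1] <= shape[1] - 1 &
        p[, 2] >= 0 & p[, 2] <= shape[2] - 1 &
        p[, 3] >= 0 & p[, 3] <= shape[3] - 1
  if (!all(ok))
    stop(sprintf("%d landmark(s) outside the [0, dim-1] grid", sum(!ok)),
         call. = FALSE)
  invisible(TRUE)
}
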