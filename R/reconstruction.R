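#' 3D point cloud of shell-surface samples
#'
#' @param points N x 3 numeric matrix of world coordinates, mm.
#' @param source_slice Integer vector of per-point 0-based slice indices.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, source_slice = integer(nrow(points))) {
  points <- matrix(as.numeric(points), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(points) > 0 && !all(is.finite(points))) {
    stop("point coordinates must be finite")
  }
  if (length(source_slice) != nrow(points)) {
    stop("'source_slice' must have one entry per point")
  }
  structure(list(points = points, source_slice = as.integer(source_slice)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points from %d slice(s)\n",
              nrow(x$points), length(unique(x$source_slice))))
  invisible(x)
}

#' Map pixel indices to world coordinates
#'
#' The affine map of the package-wide convention:
#' `world = origin + (col * pixel_spacing_col, slice_index * slice_spacing,
#' row * pixel_spacing_row)`. Indices are 0-based and the map is exact.
#'
#' @param row,col 0-based pixel indices (vectorized).
#' @param slice_index 0-based slice index (vectorized or scalar).
#' @param geometry A [scan_geometry()].
#' @return N x 3 matrix of world coordinates, mm.
#' @export
pixel_to_world <- function(row, col, slice_index, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n <- max(length(row), length(col), length(slice_index))
  row <- rep_len(row, n)
  col <- rep_len(col, n)
  slice_index <- rep_len(slice_index, n)
  if (any(row < 0 | row >= geometry$image_rows) ||
      any(col < 0 | col >= geometry$image_cols) ||
      any(slice_index < 0 | slice_index >= geometry$num_slices)) {
    stop("pixel or slice index out of bounds")
  }
  cbind(x = geometry$origin[1] + col * geometry$pixel_spacing_col,
        y = geometry$origin[2] + slice_index * geometry$slice_spacing,
        z = geometry$origin[3] + row * geometry$pixel_spacing_row)
}

#' Nearest pixel indices for world coordinates
#'
#' Inverse of [pixel_to_world()] up to quantization (round to the nearest
#' pixel / slice).
#'
#' @param points N x 3 matrix of world coordinates, mm.
#' @param geometry A [scan_geometry()].
#' @return N x 3 matrix of 0-based `(row, col, slice)` indices.
#' @export
world_to_pixel <- function(points, geometry) {
  points <- matrix(as.numeric(points), ncol = 3L)
  cbind(row = round((points[, 3] - geometry$origin[3]) /
                      geometry$pixel_spacing_row),
        col = round((points[, 1] - geometry$origin[1]) /
                      geometry$pixel_spacing_col),
        slice = round((points[, 2] - geometry$origin[2]) /
                        geometry$slice_spacing))
}

#' Assemble the 3D shell point cloud from segmented slices
#'
#' Concatenates [pixel_to_world()] over the extracted shell points of every
#' slice, tagging each point with its source slice. Slices whose
#' `shell_pixels` are missing fall back to all mask pixels.
#'
#' @param masks List of [slice_mask()] objects from one stack.
#' @param geometry The stack's [scan_geometry()].
#' @return A [point_cloud()]; empty (N = 0) when all masks are empty.
#' @export
build_point_cloud <- function(masks, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  pts <- vector("list", length(masks))
  src <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    stopifnot(inherits(m, "slice_mask"))
    px <- m$shell_pixels
    if (is.null(px)) px <- extract_shell_points(m, seg_config(extraction_mode = "all"))
    if (nrow(px) == 0L) next
    pts[[i]] <- pixel_to_world(px[, 1], px[, 2], m$slice_index, geometry)
    src[[i]] <- rep.int(m$slice_index, nrow(px))
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3L)
  point_cloud(pts, unlist(src) %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statistical outlier removal for point clouds
#'
#' Drops points whose mean distance to their `k` nearest neighbours exceeds
#' the global mean by `n_sigma` standard deviations — the standard
#' statistical-outlier filter for speckle-induced false positives. The
#' threshold is floored at twice the median neighbour distance, so
#' regular but inhomogeneous sampling (grid corners, cap edges) is never
#' trimmed, and as a guard the filter removes at most 20% of the cloud (the
#' worst offenders first). Clouds with `N <= k` are returned unchanged with
#' attribute `outlier_warning` set.
#'
#' @param cloud A [point_cloud()].
#' @param k Neighbour count, at least 1.
#' @param n_sigma Threshold in standard deviations above the mean.
#' @return A filtered [point_cloud()]; attribute `removed` holds the indices
#'   of dropped points.
#' @export
remove_outliers <- function(cloud, k = 8L, n_sigma = 2.0) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 1)
  n <- nrow(cloud$points)
  if (n <= k) {
    attr(cloud, "outlier_warning") <- "cloud smaller than k; not filtered"
    return(cloud)
  }
  md <- rowMeans(cpp_knn(cloud$points, as.integer(k))$dist)
  # floor the statistical threshold at 2x the median neighbour distance so
  # regular-but-inhomogeneous sampling (grid corners, cap edges) is kept
  thr <- max(mean(md) + n_sigma * sd(md), 2 * median(md))
  drop <- which(md > thr)
  max_drop <- floor(0.2 * n)
  if (length(drop) > max_drop) {
    drop <- drop[order(md[drop], decreasing = TRUE)][seq_len(max_drop)]
  }
  if (length(drop) == 0L) {
    attr(cloud, "removed") <- integer(0)
    return(cloud)
  }
  out <- point_cloud(cloud$points[-drop, , drop = FALSE],
                     cloud$source_slice[-drop])
  attr(out, "removed") <- drop
  out
}
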