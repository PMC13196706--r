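#' Segmentation configuration
#'
#' Parameters of the per-slice shell segmentation: median denoising,
#' histogram thresholding (three-class Otsu keeping the hyperechoic class,
#' or a fixed intensity quantile), morphological closing, small-component
#' removal, a hyperechoic-contrast acceptance test, and the point-extraction
#' mode used for reconstruction.
#'
#' @param denoise_radius Median-filter half-width, pixels (0 disables).
#' @param threshold_mode `"otsu"` (three-class, upper threshold) or
#'   `"quantile"`.
#' @param quantile Intensity quantile for `threshold_mode = "quantile"`,
#'   in `(0.5, 1)`.
#' @param min_component_area Minimum connected-component area kept, pixels.
#' @param morphology_radius Closing disk radius, pixels (0 disables).
#' @param extraction_mode `"centerline"` (ridge of the distance transform;
#'   the default, which tracks the band midline and halves the thickness
#'   bias), `"outer_edge"` (boundary pixels on the convex side) or `"all"`.
#' @param min_contrast Minimum mean-intensity contrast between the candidate
#'   mask and the rest of the slice for the mask to be accepted as a
#'   hyperechoic object; slices failing it yield an empty mask.
#' @param tophat_radius Half-width (pixels) of the white top-hat window that
#'   flattens extended background before thresholding; must exceed the shell
#'   band width. 0 thresholds raw intensities, which fails whenever the thin
#'   bright band is a tiny fraction of the slice area.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(denoise_radius = 1L,
                       threshold_mode = c("otsu", "quantile"),
                       quantile = 0.95,
                       min_component_area = 10L,
                       morphology_radius = 1,
                       extraction_mode = c("centerline", "outer_edge", "all"),
                       min_contrast = 0.30,
                       tophat_radius = 5L) {
  threshold_mode <- match.arg(threshold_mode)
  extraction_mode <- match.arg(extraction_mode)
  if (quantile <= 0.5 || quantile >= 1) stop("'quantile' must lie in (0.5, 1)")
  if (denoise_radius < 0 || morphology_radius < 0) {
    stop("radii must be >= 0")
  }
  if (min_component_area < 0) stop("'min_component_area' must be >= 0")
  if (min_contrast < 0) stop("'min_contrast' must be >= 0")
  if (tophat_radius < 0) stop("'tophat_radius' must be >= 0")
  structure(
    list(denoise_radius = as.integer(denoise_radius),
         threshold_mode = threshold_mode,
         quantile = as.numeric(quantile),
         min_component_area = as.integer(min_component_area),
         morphology_radius = as.numeric(morphology_radius),
         extraction_mode = extraction_mode,
         min_contrast = as.numeric(min_contrast),
         tophat_radius = as.integer(tophat_radius)),
    class = "seg_config"
  )
}

#' Denoise a B-mode slice before thresholding
#'
#' Median filtering with the configured radius; dimensions and intensity
#' range are preserved.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param config A [seg_config()].
#' @return Filtered matrix.
#' @export
preprocess_slice <- function(image, config = seg_config()) {
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("intensities must lie in [0, 1]")
  }
  median_filter(image, config$denoise_radius)
}

#' Per-slice mask of the hyperechoic shell
#'
#' @param mask Logical matrix.
#' @param slice_index 0-based slice index within the stack.
#' @param shell_pixels Optional N x 2 matrix of 0-based `(row, col)` pixel
#'   coordinates extracted for reconstruction; must be a subset of the mask
#'   support.
#' @return An object of class `slice_mask`.
#' @export
slice_mask <- function(mask, slice_index = 0L, shell_pixels = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask, slice_index = as.integer(slice_index),
                 shell_pixels = shell_pixels),
            class = "slice_mask")
}

#' Segment the bright shell in one slice
#'
#' Flattens extended background with a white top-hat (so the histogram is
#' dominated by the flattened floor and the thin bright band, not by the
#' tissue texture), thresholds the response (three-class Otsu upper
#' threshold or a fixed quantile), closes the result morphologically, drops
#' components below the minimum area, and keeps the union of surviving
#' components. The candidate mask is accepted only if it is genuinely
#' hyperechoic in the original slice: its mean intensity must exceed the
#' background mean by `min_contrast`, otherwise the slice is declared
#' shell-free and an empty mask is returned (a valid outcome).
#'
#' @param image Numeric matrix, preprocessed, intensities in `[0, 1]`.
#' @param config A [seg_config()].
#' @param slice_index 0-based slice index recorded in the result.
#' @return A [slice_mask()] (without extracted points; see
#'   [extract_shell_points()]).
#' @export
segment_slice <- function(image, config = seg_config(), slice_index = 0L) {
  empty <- function() {
    slice_mask(matrix(FALSE, nrow(image), ncol(image)), slice_index)
  }
  if (diff(range(image)) < 1e-9) return(empty())
  feat <- if (config$tophat_radius > 0L) {
    white_tophat(image, config$tophat_radius)
  } else {
    image
  }
  if (diff(range(feat)) < 1e-9) return(empty())
  thr <- switch(config$threshold_mode,
                otsu = otsu_upper_threshold(feat),
                quantile = as.numeric(quantile(feat, config$quantile)))
  bw <- feat > thr
  if (!any(bw) || all(bw)) return(empty())
  bw <- binary_close(bw, config$morphology_radius)
  if (config$min_component_area > 1L) {
    lab <- label_components(bw)
    sizes <- tabulate(lab[lab > 0L])
    keep <- sizes >= config$min_component_area
    bw <- lab > 0L & keep[pmax(lab, 1L)]
    dim(bw) <- dim(image)
  }
  if (!any(bw) || all(bw)) return(empty())
  if (mean(image[bw]) - mean(image[!bw]) <= config$min_contrast) {
    return(empty())
  }
  slice_mask(bw, slice_index)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_matrix <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Extract shell sample pixels from a segmented slice
#'
#' Three modes: every mask pixel (`"all"`); the outer boundary — mask pixels
#' adjacent to background whose distance from the fitted in-plane circle
#' center is at least the fitted radius, i.e. the convex side of the band
#' (`"outer_edge"`); or the band centerline, the ridge of the Euclidean
#' distance transform (`"centerline"`, the default — it tracks the band
#' midline, halving the shell-thickness bias of the radius estimate).
#'
#' @param mask A [slice_mask()] or logical matrix.
#' @param config A [seg_config()]; only `extraction_mode` is used.
#' @return N x 2 matrix of 0-based `(row, col)` coordinates (0 rows when the
#'   mask is empty).
#' @export
extract_shell_points <- function(mask, config = seg_config()) {
  m <- if (inherits(mask, "slice_mask")) mask$mask else mask
  none <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("row", "col")))
  if (!any(m)) return(none)
  px <- switch(
    config$extraction_mode,
    all = which(m, arr.ind = TRUE),
    outer_edge = {
      bg <- !m
      boundary <- m & (shift_matrix(bg, 1, 0, TRUE) |
                         shift_matrix(bg, -1, 0, TRUE) |
                         shift_matrix(bg, 0, 1, TRUE) |
                         shift_matrix(bg, 0, -1, TRUE))
      idx <- which(m, arr.ind = TRUE)
      bidx <- which(boundary, arr.ind = TRUE)
      # algebraic (Kasa) circle fit to all mask pixels locates the band
      # center; a boundary pixel is on the convex (outer) side when its
      # outward radial neighbour is background
      ctr <- colMeans(idx)
      A <- cbind(2 * idx[, 1], 2 * idx[, 2], 1)
      b <- idx[, 1]^2 + idx[, 2]^2
      if (nrow(idx) >= 3 && qr(A)$rank == 3) {
        beta <- qr.solve(A, b)
        if (is.finite(beta[1]) && is.finite(beta[2])) ctr <- beta[1:2]
      }
      u <- cbind(bidx[, 1] - ctr[1], bidx[, 2] - ctr[2])
      nu <- sqrt(rowSums(u^2))
      nu[nu == 0] <- 1
      step <- round(u / nu)
      out_r <- bidx[, 1] + step[, 1]
      out_c <- bidx[, 2] + step[, 2]
      inside <- out_r >= 1 & out_r <= nrow(m) & out_c >= 1 & out_c <= ncol(m)
      keep <- !inside
      keep[inside] <- !m[cbind(out_r[inside], out_c[inside])]
      bidx[keep, , drop = FALSE]
    },
    centerline = {
      dt <- distance_transform(m)
      nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
      mx <- dt
      for (s in nb) mx <- pmax(mx, shift_matrix(dt, s[1], s[2]))
      which(m & dt >= mx - 1e-9, arr.ind = TRUE)
    }
  )
  if (nrow(px) == 0L) return(none)
  out <- cbind(row = px[, 1] - 1, col = px[, 2] - 1)
  rownames(out) <- NULL
  out
}
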