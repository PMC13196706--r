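# Thin R wrappers around the compiled image kernels, plus the pure-R
# operations (separable Gaussian blur, multi-level Otsu) that are cheap
# enough in vectorized R.

#' Median filter
#'
#' Two variants, both with the window truncated at the image border and
#' radius 0 as the identity. `"hybrid"` (the default) is the line-preserving
#' hybrid median — the median of the plus-window median, the X-window median
#' and the center pixel — which removes speckle impulses without erasing the
#' one-pixel-wide bright band a thin shell produces at the resolution limit.
#' `"square"` is the plain square-window median.
#'
#' @param image Numeric matrix.
#' @param radius Window half-width in pixels.
#' @param type `"hybrid"` or `"square"`.
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter <- function(image, radius = 1L, type = c("hybrid", "square")) {
  type <- match.arg(type)
  radius <- as.integer(radius)
  if (radius < 0L) stop("'radius' must be >= 0")
  if (radius == 0L) return(image)
  switch(type,
         hybrid = cpp_hybrid_median_filter(image, radius),
         square = cpp_median_filter(image, radius))
}

#' Separable Gaussian blur
#'
#' Kernel truncated at three sigma and renormalized row-wise, which is
#' equivalent to replicate padding in the mean. Sigmas are in pixels.
#'
#' @param image Numeric matrix.
#' @param sigma_row,sigma_col Gaussian sigma along rows / columns, pixels.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(image, sigma_row, sigma_col = sigma_row) {
  blur_mat <- function(n, sigma) {
    if (sigma <= 0) return(NULL)
    d <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-d^2 / (2 * sigma^2))
    K[abs(d) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  Br <- blur_mat(nrow(image), sigma_row)
  Bc <- blur_mat(ncol(image), sigma_col)
  if (!is.null(Br)) image <- Br %*% image
  if (!is.null(Bc)) image <- image %*% t(Bc)
  image
}

#' Multi-level Otsu threshold for a hyperechoic object
#'
#' Three-class Otsu on a 256-bin histogram. A B-mode slice has up to three
#' intensity populations (lumen, tissue, bright shell; after background
#' flattening: floor, speckle residue, shell response), so the classic
#' two-class criterion would split the two large dim populations and miss
#' the small hyperechoic class entirely. Of the two fitted thresholds the
#' function returns the one that isolates the bright object: the upper
#' threshold, unless the middle class's mean is closer to the bright class
#' than to the dim class (i.e. the bright object is itself bimodal), in
#' which case the middle class belongs to the object and the lower
#' threshold is returned.
#'
#' @param image Numeric matrix or vector with intensities in `[0, 1]`.
#' @param nbins Histogram resolution.
#' @return Threshold as an intensity in `(0, 1)`.
#' @export
otsu_upper_threshold <- function(image, nbins = 256L) {
  x <- pmin(pmax(as.numeric(image), 0), 1)
  h <- tabulate(pmin(floor(x * nbins), nbins - 1L) + 1L, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  W <- cumsum(p)
  M <- cumsum(p * mids)
  total <- M[nbins]
  best <- -Inf
  best_t1 <- 1L
  best_t2 <- nbins - 1L
  for (t1 in seq_len(nbins - 2L)) {
    w1 <- W[t1]
    m1 <- M[t1]
    t2 <- (t1 + 1L):(nbins - 1L)
    w2 <- W[t2] - w1
    m2 <- M[t2] - m1
    w3 <- 1 - W[t2]
    m3 <- total - M[t2]
    # maximizing sum_i m_i^2 / w_i is equivalent to maximizing the
    # between-class variance
    v <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    j <- which.max(v)
    if (v[j] > best) {
      best <- v[j]
      best_t1 <- t1
      best_t2 <- t2[j]
    }
  }
  w1 <- W[best_t1]
  w2 <- W[best_t2] - w1
  w3 <- 1 - W[best_t2]
  if (w2 <= 0 || w3 <= 0) return(best_t2 / nbins)
  mu1 <- if (w1 > 0) M[best_t1] / w1 else 0
  mu2 <- (M[best_t2] - M[best_t1]) / w2
  mu3 <- (total - M[best_t2]) / w3
  if ((mu3 - mu2) <= (mu2 - mu1)) best_t1 / nbins else best_t2 / nbins
}

#' Binary closing with a disk
#'
#' Dilation followed by erosion; out-of-image pixels count as foreground
#' during erosion so closing never removes original border pixels.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels; 0 is the identity.
#' @return Logical matrix.
#' @export
binary_close <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  m <- cpp_binary_erode(cpp_binary_dilate(mask, radius), radius)
  m | mask
}

#' Connected-component labels (8-connectivity)
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 is background, components are 1..n.
#' @export
label_components <- function(mask) {
  cpp_label_components(mask)
}

#' Euclidean distance transform
#'
#' Exact distance from every `TRUE` pixel to the nearest `FALSE` pixel, in
#' physical units when pixel spacings are supplied. The image border is not
#' treated as background.
#'
#' @param mask Logical matrix.
#' @param spacing_row,spacing_col Pixel pitch along rows / columns.
#' @return Numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask, spacing_row = 1, spacing_col = 1) {
  cpp_distance_transform(mask, spacing_row, spacing_col)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of equal dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' White top-hat background flattening
#'
#' Subtracts the grayscale opening (square window of half-width `radius`)
#' from the image, suppressing every structure wider than the window —
#' extended tissue, depth-dependent gain — while retaining thin bright
#' bands. Negative responses are clipped to 0.
#'
#' @param image Numeric matrix.
#' @param radius Structuring-element half-width in pixels; must exceed the
#'   width of the structures to retain.
#' @return Top-hat response matrix (same dimensions, non-negative).
#' @export
white_tophat <- function(image, radius = 5L) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be >= 1")
  opening <- cpp_gray_dilate_sq(cpp_gray_erode_sq(image, radius), radius)
  pmax(image - opening, 0)
}

#' Two-class Otsu threshold
#'
#' Classic Otsu on a 256-bin histogram: the threshold maximizing the
#' between-class variance of a two-population split. Appropriate after
#' background flattening, when the histogram is floor + response;
#' use [otsu_upper_threshold()] on raw three-population B-mode slices.
#'
#' @inheritParams otsu_upper_threshold
#' @return Threshold as an intensity in `(0, 1)`.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  x <- pmin(pmax(as.numeric(image), 0), 1)
  h <- tabulate(pmin(floor(x * nbins), nbins - 1L) + 1L, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  W <- cumsum(p)
  M <- cumsum(p * mids)
  t <- seq_len(nbins - 1L)
  w1 <- W[t]
  w2 <- 1 - w1
  v <- ifelse(w1 > 0 & w2 > 0, (M[nbins] * w1 - M[t])^2 / (w1 * w2), -Inf)
  which.max(v) / nbins
}
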