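# Classical enhancement comparators.

#' Histogram equalization
#'
#' Standard 8-bit CDF-mapping equalization: intensity `v` maps to
#' `round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`. A constant image is
#' returned unchanged. Idempotent up to integer rounding.
#'
#' @param img numeric matrix in `[0, 255]` (rounded to the integer grid
#'   internally).
#' @return equalized matrix of integer intensities in `[0, 255]`.
#' @export
#' @examples
#' x <- matrix(c(0, 255), 8, 8)
#' all(baselineHE(x) == x)  # extremes preserved
baselineHE <- function(img) {
  v <- as.integer(round(clip01(img)))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) return(matrix(as.numeric(v), nrow(img)))  # constant image
  map <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(as.numeric(map[v + 1L]), nrow(img))
}

#' Block-matching 3D filtering, hard-threshold stage
#'
#' The first stage of block-matching and 3D collaborative filtering: similar
#' 8x8 blocks are grouped by L2 patch distance within a local search window,
#' transformed with a 2D DCT per block and a 1D Haar transform across the
#' group, hard-thresholded at `lambda * noiseSigma`, inverted, and
#' aggregated with weights inversely proportional to the number of retained
#' coefficients. The Wiener second stage is intentionally omitted: this is a
#' comparator, not a contribution.
#'
#' @param img grayscale numeric matrix, at least 8x8.
#' @param noiseSigma noise standard deviation in intensity units (`> 0`).
#' @param lambda hard-threshold multiplier (default 2.7; 0 disables
#'   filtering, giving near-exact pass-through).
#' @param block block side (default 8).
#' @param step reference-block grid step (default 3).
#' @param search search-window half-size in pixels (default 12).
#' @param maxGroup maximum blocks per group (default 16).
#' @return denoised matrix clipped to `[0, 255]`.
#' @export
baselineBM3D <- function(img, noiseSigma, lambda = 2.7, block = 8L,
                         step = 3L, search = 12L, maxGroup = 16L) {
  if (!is.matrix(img)) stop("validation error: img must be a matrix")
  if (noiseSigma <= 0) stop("validation error: noiseSigma must be positive")
  if (nrow(img) < block || ncol(img) < block)
    stop("validation error: image smaller than the matching block")
  out <- bm3d_ht_cpp(img, noiseSigma, lambda, as.integer(block),
                     as.integer(step), as.integer(search),
                     as.integer(maxGroup))
  clip01(out)
}
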