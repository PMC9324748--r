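# Structural fidelity: enhancement must not complete missing chromosomal
# material or invent new material in regions that are background in the
# original (the key robustness requirement for abnormal karyograms).

#' Estimate the background/foreground decision threshold
#'
#' Pools intensity histograms over the given images and returns the midpoint
#' between the background mode (searched in `[128, 255]`) and the foreground
#' mode (searched in `[0, 127]`).
#'
#' @param images a matrix, or list of matrices / [PairTile-class] objects.
#' @return scalar threshold in `(0, 255)`.
#' @export
estimateForegroundThreshold <- function(images) {
  if (is.matrix(images)) images <- list(images)
  v <- unlist(lapply(images, function(x)
    as.vector(if (is(x, "PairTile")) x@pixels else x)))
  v <- as.integer(round(clip01(v)))
  tab <- tabulate(v + 1L, nbins = 256L)
  bg <- which.max(tab[129:256]) + 127L
  fg_tab <- tab[1:128]
  fg <- if (any(fg_tab > 0)) which.max(fg_tab) - 1L else 64L
  (bg + fg) / 2
}

#' Structural-fidelity score of an enhanced tile
#'
#' Given a mask marking a region that is background (absent chromosomal
#' material) in the original tile, the score is the fraction of masked
#' pixels that the enhanced tile keeps on the background side of the
#' foreground threshold: `1 - mean(enhanced[mask] < threshold)`. A perfect
#' enhancer that invents nothing scores 1; filling the region with
#' foreground intensity scores 0.
#'
#' @param originalTile,enhancedTile numeric matrices in `[0, 255]` of equal
#'   shape.
#' @param regionMask logical matrix of the same shape; `TRUE` marks the
#'   region that must stay background.
#' @param threshold foreground decision threshold; by default the corpus
#'   background/foreground mode midpoint estimated from the original tile
#'   (see [estimateForegroundThreshold()]).
#' @return fidelity score in `[0, 1]`.
#' @export
checkStructuralFidelity <- function(originalTile, enhancedTile, regionMask,
                                    threshold = NULL) {
  if (!all(dim(originalTile) == dim(enhancedTile)) ||
      !all(dim(originalTile) == dim(regionMask)))
    stop("validation error: shape mismatch")
  if (!any(regionMask)) stop("validation error: empty region mask")
  if (is.null(threshold)) threshold <- estimateForegroundThreshold(originalTile)
  1 - mean(enhancedTile[regionMask] < threshold)
}
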