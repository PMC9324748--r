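# Image quality metrics and the degradation-based evaluation protocol:
# generate poor images from held-out excellent ground truth with G_EU,
# enhance them back with G_UE, and measure PSNR/SSIM against the ground
# truth.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(maxValue^2 / MSE)` in decibels. Identical images have zero
#' MSE and return the `+Inf` sentinel.
#'
#' @param reference,test numeric matrices of identical shape.
#' @param maxValue intensity ceiling (255 for 8-bit images).
#' @return PSNR in dB (`+Inf` if the images are identical).
#' @export
#' @examples
#' psnr(matrix(0, 8, 8), matrix(1, 8, 8))  # 20*log10(255) ~ 48.13 dB
psnr <- function(reference, test, maxValue = 255) {
  if (!all(dim(reference) == dim(test)))
    stop("validation error: shape mismatch")
  if (maxValue <= 0) stop("validation error: maxValue must be positive")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(maxValue^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma = 1.5, truncated at
#' 3.5 sigma, reflective boundaries), stabilizers `C1 = (0.01 * maxValue)^2`
#' and `C2 = (0.03 * maxValue)^2`, population local (co)variances, and the
#' boundary ring of half a window discarded before averaging. Symmetric in
#' its arguments; 1 iff the images are identical.
#'
#' @param reference,test numeric matrices of identical shape, at least
#'   11 x 11.
#' @param maxValue intensity dynamic range (255 for 8-bit images).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, maxValue = 255) {
  if (!all(dim(reference) == dim(test)))
    stop("validation error: shape mismatch")
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)
  win <- 2L * r + 1L
  if (nrow(reference) < win || ncol(reference) < win)
    stop("validation error: image smaller than the ", win, "x", win, " window")
  f <- function(m) gaussian_filter2d(m, sigma, truncate = truncate,
                                     mode = "reflect")
  ux <- f(reference); uy <- f(test)
  vx <- f(reference^2) - ux^2
  vy <- f(test^2) - uy^2
  vxy <- f(reference * test) - ux * uy
  C1 <- (0.01 * maxValue)^2; C2 <- (0.03 * maxValue)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  core <- S[(r + 1):(nrow(S) - r), (r + 1):(ncol(S) - r)]
  mean(core)
}

#' Degradation-protocol evaluation
#'
#' For each held-out excellent tile: generate its poor counterpart with the
#' `EU` generator, enhance that back with the `UE` generator, and report
#' PSNR/SSIM of (ground truth vs generated-poor) and (ground truth vs
#' enhanced), plus averages. Infinite PSNR values (identical images) are
#' excluded from the averages and counted.
#'
#' @param bundle a trained [CycleGANBundle-class].
#' @param excellentTiles list of raw [PairTile-class] held out from training.
#' @param generatorUE,generatorEU optional plug-in functions (normalized
#'   matrix to normalized matrix) replacing the bundle's generators; use
#'   `identity` to probe the protocol itself.
#' @return an [EvalReport-class].
#' @export
evaluateEnhancement <- function(bundle, excellentTiles,
                                generatorUE = NULL, generatorEU = NULL) {
  if (length(excellentTiles) == 0L)
    stop("validation error: empty tile list")
  size <- if (!is.null(bundle)) net_image_size(bundle@netConfig)
          else nrow(excellentTiles[[1]]@pixels)
  apply_gen <- function(tl, fn, dir) {
    if (!is.null(fn)) { tl@pixels <- fn(tl@pixels); tl }
    else translateTiles(bundle, list(tl), dir)[[1]]
  }
  rows <- lapply(seq_along(excellentTiles), function(i) {
    tl <- excellentTiles[[i]]
    rn <- resizeNormalize(tl, size)
    poor_n <- apply_gen(rn, generatorEU, "EU")
    enh_n <- apply_gen(poor_n, generatorUE, "UE")
    gt <- tl@pixels
    poor8 <- unnormalizeTile(poor_n)@pixels
    enh8 <- unnormalizeTile(enh_n)@pixels
    data.frame(tile = i, label = tl@label,
               psnr_degraded = psnr(gt, poor8), ssim_degraded = ssim(gt, poor8),
               psnr_enhanced = psnr(gt, enh8), ssim_enhanced = ssim(gt, enh8))
  })
  per <- do.call(rbind, rows)
  fin_mean <- function(v) mean(v[is.finite(v)])
  avg <- c(psnr_degraded = fin_mean(per$psnr_degraded),
           ssim_degraded = mean(per$ssim_degraded),
           psnr_enhanced = fin_mean(per$psnr_enhanced),
           ssim_enhanced = mean(per$ssim_enhanced))
  n_inf <- sum(!is.finite(per$psnr_degraded)) + sum(!is.finite(per$psnr_enhanced))
  new("EvalReport", perImage = per, averages = avg,
      n = length(excellentTiles), nInfinite = as.integer(n_inf))
}

#' Compare enhancement methods on degraded tiles
#'
#' Degrades each held-out tile with `noiseParams` (per-tile noise seeds
#' derived from `noiseParams@@seed`), applies each method — `"none"`
#' (pass-through), `"he"` (histogram equalization), `"bm3d"` (hard-threshold
#' block-matching 3D filtering) and `"model"` (the trained `UE` generator) —
#' and reports PSNR/SSIM against the clean original.
#'
#' @param excellentTiles list of raw [PairTile-class] held out from training.
#' @param bundle a trained [CycleGANBundle-class] (may be `NULL` when
#'   `"model"` is not requested, or `enhancer` is given).
#' @param noiseParams a [DegradationParams-class].
#' @param methods subset of `c("none", "he", "bm3d", "model")`.
#' @param enhancer optional plug-in replacing the model generator.
#' @return `list(perTile = data.frame(method, tile, psnr, ssim),
#'   averages = data.frame(method, psnr, ssim))`; averages are means over
#'   finite per-tile values.
#' @export
compareMethods <- function(excellentTiles, bundle,
                           noiseParams = degradationParams(),
                           methods = c("none", "he", "bm3d", "model"),
                           enhancer = NULL) {
  if (length(excellentTiles) == 0L)
    stop("validation error: empty tile list")
  methods <- match.arg(methods, several.ok = TRUE)
  size <- if (!is.null(bundle)) net_image_size(bundle@netConfig)
          else nrow(excellentTiles[[1]]@pixels)
  rows <- list()
  for (i in seq_along(excellentTiles)) {
    tl <- excellentTiles[[i]]
    p <- noiseParams; p@seed <- noiseParams@seed + i
    deg <- degradeImage(tl@pixels, p)
    for (m in methods) {
      out <- switch(m,
        none = deg,
        he = baselineHE(deg),
        bm3d = baselineBM3D(deg, max(noiseParams@noiseSigma, 1)),
        model = {
          dt <- tl; dt@pixels <- deg
          rn <- resizeNormalize(dt, size)
          if (!is.null(enhancer)) rn@pixels <- enhancer(rn@pixels)
          else rn <- translateTiles(bundle, list(rn), "UE")[[1]]
          unnormalizeTile(rn)@pixels
        })
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, tile = i,
        psnr = psnr(tl@pixels, out), ssim = ssim(tl@pixels, out))
    }
  }
  per <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(split(per, per$method), function(d)
    data.frame(method = d$method[1], psnr = mean(d$psnr[is.finite(d$psnr)]),
               ssim = mean(d$ssim))))
  rownames(avg) <- NULL
  list(perTile = per, averages = avg)
}
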