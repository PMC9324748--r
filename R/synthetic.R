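# Synthetic banded-karyogram generator. The clinical karyograms behind the
# method are not publicly deposited, so this module emulates their pixel
# structure: 8-bit grayscale, light background, dark banded homolog pairs
# arranged in four rows in chromosome order. Band patterns are fixed
# pseudo-ideograms (seeded once, versioned here), not true ISCN ideograms.

BACKGROUND_INTENSITY <- 245

# Approximate relative chromosome lengths (fraction of chromosome 1) and
# centromere positions (fraction from the p-terminus); acrocentrics have
# centromeres near 0.15-0.2.
.chrom_table <- data.frame(
  label = c(as.character(1:22), "X", "Y"),
  rel = c(1.00, 0.97, 0.80, 0.77, 0.73, 0.69, 0.64, 0.59, 0.57, 0.55,
          0.54, 0.54, 0.46, 0.44, 0.41, 0.36, 0.33, 0.31, 0.24, 0.25,
          0.19, 0.20, 0.62, 0.23),
  cen = c(0.48, 0.38, 0.46, 0.28, 0.27, 0.39, 0.38, 0.34, 0.35, 0.34,
          0.40, 0.30, 0.17, 0.17, 0.18, 0.45, 0.33, 0.29, 0.46, 0.44,
          0.20, 0.21, 0.40, 0.22),
  stringsAsFactors = FALSE
)

# Versioned pseudo-ideogram: alternating dark/light bands with seeded
# boundaries. The base seed is a fixed constant so band patterns are part of
# the generator definition, not of any particular run.
.make_bands <- function(index, rel_length) {
  with_seed(19661L + index, {
    k <- max(3L, round(4 + 16 * rel_length))
    cuts <- sort(runif(k - 1L, 0.05, 0.95))
    # enforce a minimum band thickness
    cuts <- cuts[c(TRUE, diff(cuts) > 0.03)]
    k <- length(cuts) + 1L
    starts <- c(0, cuts); ends <- c(cuts, 1)
    dark <- runif(k, 60, 130); light <- runif(k, 170, 215)
    inten <- ifelse(seq_len(k) %% 2L == (index %% 2L), dark, light)
    cbind(start = starts, end = ends, intensity = round(inten))
  })
}

#' Construct a chromosome rendering specification
#'
#' @param label chromosome identity (`"1".."22"`, `"X"`, `"Y"`).
#' @param relLength length relative to chromosome 1, in `(0, 1]`.
#' @param widthPx chromatid width in pixels at the 256-pixel tile scale.
#' @param centromereFrac centromere position along the axis in `(0, 1)`.
#' @param bands matrix with columns `start`, `end`, `intensity`; ordered,
#'   contiguous segments covering `[0, 1]`.
#' @return a [ChromosomeSpec-class].
#' @export
#' @examples
#' sp <- chromosomeSpec("1", 1, 18L, 0.48,
#'                      cbind(c(0, .5), c(.5, 1), c(80, 200)))
chromosomeSpec <- function(label, relLength, widthPx, centromereFrac, bands) {
  colnames(bands) <- c("start", "end", "intensity")
  new("ChromosomeSpec", label = as.character(label),
      relLength = relLength, widthPx = as.integer(widthPx),
      centromereFrac = centromereFrac, bands = bands)
}

#' Default genome specification
#'
#' Builds the 24 chromosome specs (approximate real relative lengths and
#' centromere positions, fixed pseudo-ideogram band patterns) used by the
#' synthetic generator.
#'
#' @param sex `"XX"` or `"XY"`.
#' @return a [GenomeSpec-class].
#' @export
#' @examples
#' g <- defaultGenomeSpec("XY")
defaultGenomeSpec <- function(sex = "XY") {
  specs <- lapply(seq_len(24L), function(i) {
    row <- .chrom_table[i, ]
    chromosomeSpec(row$label, row$rel,
                   widthPx = max(8L, round(10 + 8 * row$rel)),
                   centromereFrac = row$cen,
                   bands = .make_bands(i, row$rel))
  })
  new("GenomeSpec", chromosomes = specs, sex = sex)
}

#' Construct degradation parameters
#'
#' Defaults emulate a poor-quality clinical karyogram export: 1 px of blur,
#' noise with standard deviation 15 intensity units, and contrast compressed
#' to 70 percent around mid-gray.
#'
#' @param blurSigma Gaussian blur sd in pixels (`>= 0`).
#' @param noiseSigma additive Gaussian noise sd in 8-bit units (`>= 0`).
#' @param contrastFactor contrast retention in `(0, 1]`; 1 keeps contrast.
#' @param seed integer seed for the noise.
#' @return a [DegradationParams-class].
#' @export
degradationParams <- function(blurSigma = 1.0, noiseSigma = 15,
                              contrastFactor = 0.7, seed = 0L) {
  new("DegradationParams", blurSigma = blurSigma, noiseSigma = noiseSigma,
      contrastFactor = contrastFactor, seed = as.integer(seed))
}

.genome_spec_for <- function(genome, label) {
  labs <- vapply(genome@chromosomes, function(s) s@label, character(1))
  genome@chromosomes[[match(label, labs)]]
}

# Paint two homologs side by side on a square canvas. Homologs share the band
# sequence; length (+-5%) and a slight sinusoidal bend are jittered per
# homolog. Band intensity is constant across each row of the chromosome, so
# band patterns survive rendering exactly.
.render_group <- function(specL, specR, jitterSeed, size) {
  canvas <- matrix(BACKGROUND_INTENSITY, size, size)
  scale <- size / 256
  with_seed(jitterSeed, {
    for (side in 1:2) {
      spec <- if (side == 1) specL else specR
      L <- max(8L, round(spec@relLength * 0.88 * size * (1 + runif(1, -0.05, 0.05))))
      bend_amp <- runif(1, 0, 1.5) * scale
      bend_phase <- runif(1, 0, 2 * pi)
      w <- max(3L, round(spec@widthPx * scale))
      xc0 <- size * ifelse(side == 1, 0.32, 0.68)
      y0 <- max(1L, round((size - L) / 2))

      t <- seq_len(L)
      frac <- (t - 0.5) / L
      band_idx <- findInterval(frac, spec@bands[, "start"])
      inten <- spec@bands[band_idx, "intensity"]
      hw <- (w / 2) * (1 - 0.55 * exp(-((frac - spec@centromereFrac) / 0.06)^2))
      hw <- pmax(hw, 1)
      xc <- xc0 + bend_amp * sin(2 * pi * frac + bend_phase)
      lo <- pmax(1L, round(xc - hw)); hi <- pmin(size, round(xc + hw))
      nv <- hi - lo + 1L
      rows <- rep.int(y0 + t - 1L, nv)
      cols <- sequence(nv) + rep.int(lo - 1L, nv)
      keep <- rows >= 1L & rows <= size
      canvas[cbind(rows[keep], cols[keep])] <- rep.int(inten, nv)[keep]
    }
  })
  canvas
}

#' Render one chromosome-pair tile
#'
#' Draws two homologs of the given chromosome side by side on a light
#' background. Both homologs carry the same band sequence; seeded jitter
#' perturbs length (within five percent) and adds a slight bend so the pair
#' is realistic but shape-similar. Deterministic given `jitterSeed`.
#'
#' @param spec a [ChromosomeSpec-class].
#' @param jitterSeed integer seed for the homolog jitter.
#' @param size tile side length in pixels (default 256).
#' @return numeric matrix `size` x `size` in `[0, 255]`.
#' @export
#' @examples
#' tile <- renderPairTile(defaultGenomeSpec()@chromosomes[[1]], 0)
renderPairTile <- function(spec, jitterSeed, size = 256L) {
  validObject(spec)
  .render_group(spec, spec, jitterSeed, as.integer(size))
}

#' Render a full synthetic karyogram
#'
#' Lays out the 23 pair groups (22 autosome pairs plus one sex group, XX or
#' XY according to the genome's sex) in four rows in chromosome order, one
#' square region of `tilePx` pixels per group. The layout map records each
#' region's bounding box in 0-based, half-open coordinates. Jitter seeds are
#' derived as `seed + 7919 * group_index` (group index 1..23 in chromosome
#' order), so any region can be re-rendered independently.
#'
#' @param genome a [GenomeSpec-class].
#' @param seed integer seed.
#' @param tilePx side length of each pair-group region (default 256).
#' @param canvasSize optional `c(height, width)`; must be large enough for
#'   the four-row layout, otherwise a layout error is raised.
#' @return a [KaryogramImage-class] with a 23-region layout.
#' @export
#' @examples
#' kg <- renderKaryogram(defaultGenomeSpec("XY"), seed = 1, tilePx = 64)
#' length(karyoLayout(kg))
renderKaryogram <- function(genome, seed, tilePx = 256L, canvasSize = NULL) {
  validObject(genome)
  tilePx <- as.integer(tilePx)
  rows <- list(as.character(1:5), as.character(6:12), as.character(13:18),
               c(as.character(19:22), "sex"))
  need_h <- length(rows) * tilePx
  need_w <- max(lengths(rows)) * tilePx
  if (is.null(canvasSize)) canvasSize <- c(need_h, need_w)
  if (canvasSize[1] < need_h || canvasSize[2] < need_w)
    stop("layout error: canvas ", canvasSize[1], "x", canvasSize[2],
         " too small for the ", need_h, "x", need_w, " four-row layout")
  canvas <- matrix(BACKGROUND_INTENSITY, canvasSize[1], canvasSize[2])
  layout <- list()
  k <- 0L
  for (r in seq_along(rows)) {
    for (cidx in seq_along(rows[[r]])) {
      k <- k + 1L
      lab <- rows[[r]][cidx]
      if (lab == "sex") {
        sL <- .genome_spec_for(genome, "X")
        sR <- .genome_spec_for(genome, if (genome@sex == "XY") "Y" else "X")
      } else {
        sL <- sR <- .genome_spec_for(genome, lab)
      }
      tile <- .render_group(sL, sR, jitterSeed = seed + 7919L * k, size = tilePx)
      x0 <- (cidx - 1L) * tilePx; y0 <- (r - 1L) * tilePx
      canvas[(y0 + 1L):(y0 + tilePx), (x0 + 1L):(x0 + tilePx)] <- tile
      layout[[lab]] <- as.integer(c(x0, y0, x0 + tilePx, y0 + tilePx))
    }
  }
  new("KaryogramImage", pixels = canvas, layout = layout,
      sourceId = sprintf("synthetic-%d", seed), qualityLabel = "excellent")
}

#' Degrade an image into the poor-quality domain
#'
#' Applies Gaussian blur, contrast compression towards mid-gray
#' (`128 + f * (x - 128)`), additive Gaussian noise, and clipping to
#' `[0, 255]`, in that order. With identity parameters (no blur, no noise,
#' contrast factor 1) the output is pixel-identical to the input.
#' Deterministic given the seed in `params`.
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param params a [DegradationParams-class].
#' @return degraded numeric matrix of the same size.
#' @export
#' @examples
#' x <- matrix(128, 32, 32)
#' y <- degradeImage(x, degradationParams(0, 10, 1, seed = 1))
degradeImage <- function(img, params) {
  validObject(params)
  if (!is.matrix(img)) stop("img must be a 2D grayscale matrix")
  out <- img
  if (params@blurSigma > 0)
    out <- gaussian_filter2d(out, params@blurSigma, mode = "nearest")
  if (params@contrastFactor < 1)
    out <- 128 + params@contrastFactor * (out - 128)
  if (params@noiseSigma > 0)
    out <- out + with_seed(params@seed,
      matrix(rnorm(length(out), 0, params@noiseSigma), nrow(out)))
  clip01(out)
}

#' Generate curated poor/excellent training corpora
#'
#' Renders `nPoor + nExcellent` synthetic karyograms (sex alternating between
#' XY and XX), decomposes each into its 23 pair tiles, applies the training
#' curation filter (retain chromosomes 1-12 only, to maximize shape and
#' length similarity between training tiles), and degrades the poor corpus
#' with `params`. Each poor tile gets its own noise seed derived from
#' `params@@seed` and the tile index. With 88 poor karyograms this yields the
#' 88 x 12 = 1056 poor training tiles of the original curation arithmetic.
#'
#' @param nPoor,nExcellent number of karyograms per domain (`>= 1`).
#' @param params [DegradationParams-class] for the poor domain.
#' @param seed integer seed for rendering.
#' @param tilePx tile side length in pixels.
#' @return `list(poor = , excellent = )`, each a list of [PairTile-class].
#' @export
#' @examples
#' co <- makeCorpora(1, 1, degradationParams(), seed = 1, tilePx = 64)
#' length(co$poor)  # 12
makeCorpora <- function(nPoor, nExcellent, params = degradationParams(),
                        seed = 1L, tilePx = 256L) {
  if (nPoor < 1 || nExcellent < 1)
    stop("validation error: both corpora must have at least one karyogram")
  validObject(params)
  gens <- list(XX = defaultGenomeSpec("XX"), XY = defaultGenomeSpec("XY"))
  one_domain <- function(n, offset, degrade) {
    out <- vector("list", n * 12L)
    pos <- 0L
    for (k in seq_len(n)) {
      g <- gens[[1L + (k %% 2L)]]
      kg <- renderKaryogram(g, seed = seed + offset + k, tilePx = tilePx)
      kg@qualityLabel <- if (degrade) "poor" else "excellent"
      kept <- curateTrainingTiles(decomposeKaryogram(kg))
      for (tl in kept) {
        pos <- pos + 1L
        if (degrade) {
          p <- params
          p@seed <- params@seed + 131L * (offset + k) + pos
          tl@pixels <- degradeImage(tl@pixels, p)
        }
        out[[pos]] <- tl
      }
    }
    out
  }
  list(poor = one_domain(nPoor, 0L, TRUE),
       excellent = one_domain(nExcellent, 100000L, FALSE))
}
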