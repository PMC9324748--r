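#' Chromosome rendering specification
#'
#' Describes one chromosome for the synthetic karyogram generator: its
#' identity, length relative to chromosome 1, rendered width, centromere
#' position, and a pseudo-ideogram of dark/light bands. Band segments are
#' given as rows `(start, end, intensity)` in axis fractions; they must be
#' ordered, non-overlapping and cover `[0, 1]`.
#'
#' @slot label chromosome identity, one of `"1".."22"`, `"X"`, `"Y"`.
#' @slot relLength length as a fraction of chromosome 1, in `(0, 1]`.
#' @slot widthPx rendered chromatid width in pixels (at the 256-pixel tile
#'   scale), at least 3.
#' @slot centromereFrac centromere position along the axis, in `(0, 1)`.
#' @slot bands numeric matrix with columns `start`, `end`, `intensity`
#'   (intensity in `[0, 255]`).
#' @exportClass ChromosomeSpec
setClass("ChromosomeSpec",
  representation(label = "character", relLength = "numeric",
                 widthPx = "integer", centromereFrac = "numeric",
                 bands = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!object@label %in% c(as.character(1:22), "X", "Y"))
      msg <- c(msg, "label must be one of '1'..'22', 'X', 'Y'")
    if (object@relLength <= 0 || object@relLength > 1)
      msg <- c(msg, "relLength must be in (0, 1]")
    if (object@widthPx < 3L) msg <- c(msg, "widthPx must be >= 3")
    if (object@centromereFrac <= 0 || object@centromereFrac >= 1)
      msg <- c(msg, "centromereFrac must be in (0, 1)")
    b <- object@bands
    if (ncol(b) != 3) msg <- c(msg, "bands must have 3 columns")
    else {
      if (nrow(b) < 1) msg <- c(msg, "at least one band required")
      else {
        if (abs(b[1, 1]) > 1e-9 || abs(b[nrow(b), 2] - 1) > 1e-9)
          msg <- c(msg, "bands must cover [0, 1]")
        if (nrow(b) > 1 && any(abs(b[-1, 1] - b[-nrow(b), 2]) > 1e-9))
          msg <- c(msg, "bands must be contiguous and ordered")
        if (any(b[, 2] <= b[, 1])) msg <- c(msg, "band end must exceed start")
        if (any(b[, 3] < 0 | b[, 3] > 255))
          msg <- c(msg, "band intensity must be in [0, 255]")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Genome specification for the synthetic generator
#'
#' Holds 24 [ChromosomeSpec-class] entries (autosomes 1-22 plus X and Y) and
#' the sex of the rendered karyotype, which decides whether the sex group
#' shows XX or XY.
#'
#' @slot chromosomes list of 24 `ChromosomeSpec` objects with unique labels.
#' @slot sex `"XX"` or `"XY"`.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(chromosomes = "list", sex = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@chromosomes) != 24L)
      msg <- c(msg, "exactly 24 chromosome specs required")
    labs <- vapply(object@chromosomes, function(s) s@label, character(1))
    if (anyDuplicated(labs)) msg <- c(msg, "chromosome labels must be unique")
    if (!object@sex %in% c("XX", "XY")) msg <- c(msg, "sex must be XX or XY")
    if (length(msg)) msg else TRUE
  })

#' Parametric image degradation settings
#'
#' Parameters of the operator that turns an excellent-quality image into a
#' poor-quality one: Gaussian blur, contrast compression towards mid-gray,
#' and additive Gaussian noise, followed by clipping to `[0, 255]`. With
#' `blurSigma = 0`, `noiseSigma = 0` and `contrastFactor = 1` the operator is
#' the identity map.
#'
#' @slot blurSigma blur standard deviation in pixels, `>= 0`.
#' @slot noiseSigma noise standard deviation in 8-bit intensity units, `>= 0`.
#' @slot contrastFactor contrast retention factor in `(0, 1]`.
#' @slot seed integer seed making the noise deterministic.
#' @exportClass DegradationParams
setClass("DegradationParams",
  representation(blurSigma = "numeric", noiseSigma = "numeric",
                 contrastFactor = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (object@contrastFactor <= 0 || object@contrastFactor > 1)
      msg <- c(msg, "contrastFactor must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' One grayscale karyogram with its layout map
#'
#' The central image container: an 8-bit-range grayscale pixel matrix plus a
#' layout map giving the bounding box of each of the 23 chromosome pair-group
#' regions (labels `"1".."22"` and `"sex"`). Boxes are `c(x0, y0, x1, y1)` in
#' 0-based, half-open pixel coordinates (x = column, y = row).
#'
#' @slot pixels numeric matrix in `[0, 255]`.
#' @slot layout named list of integer(4) bounding boxes.
#' @slot sourceId opaque identifier.
#' @slot qualityLabel `"poor"`, `"excellent"` or `"unknown"`.
#' @exportClass KaryogramImage
setClass("KaryogramImage",
  representation(pixels = "matrix", layout = "list", sourceId = "character",
                 qualityLabel = "character"),
  prototype(sourceId = "unknown", qualityLabel = "unknown"),
  validity = function(object) {
    msg <- character()
    if (!object@qualityLabel %in% c("poor", "excellent", "unknown"))
      msg <- c(msg, "qualityLabel must be poor/excellent/unknown")
    h <- nrow(object@pixels); w <- ncol(object@pixels)
    for (lab in names(object@layout)) {
      b <- object@layout[[lab]]
      if (length(b) != 4) { msg <- c(msg, "boxes must have 4 coordinates"); break }
      if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h || b[3] <= b[1] || b[2] >= b[4])
        msg <- c(msg, sprintf("box '%s' outside image or degenerate", lab))
    }
    if (length(msg)) msg else TRUE
  })

#' One chromosome-pair tile
#'
#' A cut-out of one pair-group region of a karyogram, optionally resized and
#' intensity-normalized for the network. Normalization statistics and the
#' original box/size are retained so the tile can be mapped back exactly
#' during reassembly.
#'
#' @slot pixels numeric matrix; `[0, 255]` raw, or `[-1, 1]` once normalized.
#' @slot label chromosome group, `"1".."22"` or `"sex"`.
#' @slot sourceId identifier of the source karyogram.
#' @slot originalBox integer(4) box in the source karyogram (or empty).
#' @slot originalSize integer(2) `(h, w)` before any resizing.
#' @slot normStats list: empty, or `list(mean, sd, clamp)` recorded by
#'   [resizeNormalize()].
#' @exportClass PairTile
setClass("PairTile",
  representation(pixels = "matrix", label = "character", sourceId = "character",
                 originalBox = "integer", originalSize = "integer",
                 normStats = "list"),
  prototype(sourceId = "unknown", originalBox = integer(),
            originalSize = integer(), normStats = list()),
  validity = function(object) {
    if (!object@label %in% c(as.character(1:22), "sex", "X", "Y"))
      "label must be a chromosome group ('1'..'22', 'sex')" else TRUE
  })

#' Ordered set of pair tiles from one karyogram
#'
#' @slot tiles list of [PairTile-class] in chromosome order
#'   (`"1".."22"`, `"sex"` for a normal karyogram).
#' @slot source the source [KaryogramImage-class].
#' @exportClass TileSet
setClass("TileSet",
  representation(tiles = "list", source = "KaryogramImage"))

#' Network architecture configuration
#'
#' @slot generatorArch `"unet_256"` (8 down/up levels for 256x256 input) or
#'   `"unet_64"` (6 levels for 64x64 input, the reduced fixture scale).
#' @slot discriminatorArch `"patchgan"` (patch-based convolutional classifier).
#' @slot inChannels,outChannels image channels; 1 for grayscale.
#' @slot norm `"batch"` or `"instance"` normalization inside the networks.
#' @slot baseWidth filters in the first layer (64 at full scale).
#' @exportClass NetConfig
setClass("NetConfig",
  representation(generatorArch = "character", discriminatorArch = "character",
                 inChannels = "integer", outChannels = "integer",
                 norm = "character", baseWidth = "integer"),
  prototype(generatorArch = "unet_256", discriminatorArch = "patchgan",
            inChannels = 1L, outChannels = 1L, norm = "batch",
            baseWidth = 64L),
  validity = function(object) {
    msg <- character()
    if (!object@generatorArch %in% c("unet_256", "unet_64"))
      msg <- c(msg, "generatorArch must be 'unet_256' or 'unet_64'")
    if (!identical(object@discriminatorArch, "patchgan"))
      msg <- c(msg, "discriminatorArch must be 'patchgan'")
    if (object@inChannels != object@outChannels)
      msg <- c(msg, "inChannels must equal outChannels")
    if (object@inChannels != 1L)
      msg <- c(msg, "grayscale networks only: channels must be 1")
    if (!object@norm %in% c("batch", "instance"))
      msg <- c(msg, "norm must be 'batch' or 'instance'")
    if (object@baseWidth < 1L) msg <- c(msg, "baseWidth must be positive")
    if (length(msg)) msg else TRUE
  })

#' Training configuration
#'
#' Defaults follow the standard unpaired cycle-consistent GAN recipe: batch
#' size 4, cycle-loss weight 10 with identity weight half of it, Adam with
#' beta1 = 0.5 and learning rate 2e-4 decaying linearly to zero over the
#' second half of training, a logistic (binary cross-entropy) adversarial
#' objective, and a 50-image history buffer for discriminator updates.
#'
#' @slot batchSize images per optimization step.
#' @slot epochs training epochs.
#' @slot lambdaCycle weight of the L1 cycle-consistency loss.
#' @slot lambdaIdentity weight of the identity loss (0 disables it).
#' @slot lr initial Adam learning rate.
#' @slot seed integer seed controlling initialization, shuffling and noise.
#' @slot adversarialMode `"logistic"` (binary cross-entropy) or `"lsgan"`.
#' @slot poolSize size of the generated-image history buffer.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", epochs = "integer",
                 lambdaCycle = "numeric", lambdaIdentity = "numeric",
                 lr = "numeric", seed = "integer", adversarialMode = "character",
                 poolSize = "integer"),
  prototype(batchSize = 4L, epochs = 200L, lambdaCycle = 10, lambdaIdentity = 5,
            lr = 2e-4, seed = 1L, adversarialMode = "logistic", poolSize = 50L),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@lambdaCycle < 0 || object@lambdaIdentity < 0)
      msg <- c(msg, "loss weights must be >= 0")
    if (object@lr <= 0) msg <- c(msg, "lr must be positive")
    if (!object@adversarialMode %in% c("logistic", "lsgan"))
      msg <- c(msg, "adversarialMode must be 'logistic' or 'lsgan'")
    if (length(msg)) msg else TRUE
  })

#' Bundle of the four cycle-GAN networks
#'
#' Holds the two generators (`G_UE`: unenhanced to enhanced, `G_EU`: enhanced
#' to unenhanced), the two discriminators (`D_E`, `D_U`), their
#' configuration, optimizer state, generated-image history buffers, and the
#' per-iteration training loss history.
#'
#' @slot gUE,gEU,dU,dE network parameter trees (internal representation).
#' @slot netConfig [NetConfig-class].
#' @slot trainConfig [TrainConfig-class].
#' @slot history data.frame of per-iteration loss records.
#' @slot optState Adam optimizer state.
#' @slot pools generated-image history buffers for the discriminators.
#' @exportClass CycleGANBundle
setClass("CycleGANBundle",
  representation(gUE = "list", gEU = "list", dE = "list", dU = "list",
                 netConfig = "NetConfig", trainConfig = "TrainConfig",
                 history = "data.frame", optState = "list", pools = "list"),
  prototype(history = data.frame(), optState = list(), pools = list()))

#' Degradation-protocol evaluation report
#'
#' Per-tile PSNR/SSIM of (ground truth vs degraded) and (ground truth vs
#' enhanced), with their averages. Infinite PSNR values (identical images)
#' are excluded from the averages and counted in `nInfinite`.
#'
#' @slot perImage data.frame with one row per tile.
#' @slot averages named numeric vector of the four column means.
#' @slot n number of tiles evaluated.
#' @slot nInfinite number of infinite PSNR values excluded from averages.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perImage = "data.frame", averages = "numeric", n = "integer",
                 nInfinite = "integer"))
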