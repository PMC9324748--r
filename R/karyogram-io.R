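# Cutting karyograms into pair tiles, curating and normalizing tiles for
# training, and reassembling enhanced tiles. Tile boundaries come from the
# layout map (generator output or a JSON sidecar next to real exports);
# automatic segmentation of arbitrary karyogram images is out of scope.

STANDARD_LABELS <- c(as.character(1:22), "sex")

.boxes_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Cut a karyogram into its pair tiles
#'
#' Crops one tile per layout region, in chromosome order. Pixels equal the
#' crop at the recorded box exactly; the box and original size are kept on
#' each tile so the karyogram can be reassembled.
#'
#' @param karyogram a [KaryogramImage-class] with a layout map.
#' @param strict if `TRUE` (default), require the 23 standard pair-group
#'   labels of a normal karyogram; `FALSE` accepts any non-empty layout
#'   (abnormal karyograms may declare other groups).
#' @return a [TileSet-class].
#' @export
#' @examples
#' kg <- renderKaryogram(defaultGenomeSpec(), seed = 1, tilePx = 64)
#' length(tiles(decomposeKaryogram(kg)))  # 23
decomposeKaryogram <- function(karyogram, strict = TRUE) {
  stopifnot(is(karyogram, "KaryogramImage"))
  lay <- karyogram@layout
  if (length(lay) == 0L) stop("layout error: no layout regions present")
  if (strict && !setequal(names(lay), STANDARD_LABELS))
    stop("layout error: expected the 23 standard pair-group regions, got ",
         length(lay))
  h <- nrow(karyogram@pixels); w <- ncol(karyogram@pixels)
  labs <- if (strict) STANDARD_LABELS else names(lay)
  boxes <- lay[labs]
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h)
      stop("bounds error: box '", labs[i], "' outside image")
    if (i > 1) for (j in seq_len(i - 1))
      if (.boxes_overlap(b, boxes[[j]]))
        stop("layout error: regions '", labs[i], "' and '", labs[j],
             "' overlap")
  }
  tl <- lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    px <- karyogram@pixels[(b[2] + 1L):b[4], (b[1] + 1L):b[3], drop = FALSE]
    new("PairTile", pixels = px, label = labs[i],
        sourceId = karyogram@sourceId, originalBox = as.integer(b),
        originalSize = dim(px))
  })
  new("TileSet", tiles = tl, source = karyogram)
}

#' Curate tiles for training
#'
#' Applies the training-set filter: only chromosomes 1-12 are retained;
#' chromosomes 13-22 and the sex group are removed to maximize shape and
#' length similarity across training tiles. Input order is preserved and the
#' filter is idempotent. A normal 23-tile karyogram yields exactly 12 tiles.
#'
#' @param tiles a [TileSet-class] or list of [PairTile-class].
#' @return list of retained [PairTile-class] objects.
#' @export
curateTrainingTiles <- function(tiles) {
  if (is(tiles, "TileSet")) tiles <- tiles@tiles
  keep <- vapply(tiles, function(t) t@label %in% as.character(1:12), logical(1))
  tiles[keep]
}

#' Resize and intensity-normalize a tile for the network
#'
#' Stretches the tile to `size` x `size` (bilinear, aspect ratio not
#' preserved), standardizes intensities per tile to zero mean and unit
#' variance (with an epsilon guard for constant tiles), and maps linearly to
#' the network range `[-1, 1]` with three standard deviations mapping to the
#' range ends. When a tile legitimately contains pixels beyond three
#' standard deviations (background-dominated tiles put chromosome pixels far
#' into the tail) the scale widens to the tile's extreme z-score instead of
#' clamping, so the map stays lossless and exactly invertible. The per-tile
#' mean/sd/scale and the original size are stored on the tile so the mapping
#' can be inverted exactly during reassembly.
#'
#' @param tile a [PairTile-class] with raw `[0, 255]` pixels.
#' @param size network input side length (default 256).
#' @return a normalized [PairTile-class] (`pixels` in `[-1, 1]`).
#' @export
resizeNormalize <- function(tile, size = 256L) {
  stopifnot(is(tile, "PairTile"))
  if (length(tile@pixels) == 0L || nrow(tile@pixels) == 0L || ncol(tile@pixels) == 0L)
    stop("validation error: zero-area tile")
  if (length(tile@originalSize) == 0L) tile@originalSize <- dim(tile@pixels)
  px <- resize_bilinear(tile@pixels, size, size)
  mu <- mean(px)
  sdv <- sd(as.vector(px))
  eps <- 1e-8
  z <- (px - mu) / max(sdv, eps)
  scale <- max(3, max(abs(z)))
  tile@pixels <- z / scale
  tile@normStats <- list(mean = mu, sd = max(sdv, eps), clamp = scale)
  tile
}

#' Invert tile normalization
#'
#' Maps a normalized tile back to 8-bit intensities using its stored
#' per-tile statistics, resizes back to the original size, rounds to the
#' integer grid and clips to `[0, 255]`.
#'
#' @param tile a [PairTile-class] produced by [resizeNormalize()] (pixels may
#'   have been replaced by a generator output of the same shape).
#' @return a [PairTile-class] with raw pixels at the original size.
#' @export
unnormalizeTile <- function(tile) {
  st <- tile@normStats
  if (length(st) == 0L)
    stop("reassembly error: tile has no stored normalization statistics")
  px <- tile@pixels * st$clamp * st$sd + st$mean
  if (length(tile@originalSize) == 2L &&
      !all(dim(px) == tile@originalSize))
    px <- resize_bilinear(px, tile@originalSize[1], tile@originalSize[2])
  tile@pixels <- clip01(round(px))
  tile@normStats <- list()
  tile
}

#' Reassemble a karyogram from (enhanced) tiles
#'
#' Pastes each tile back at its original bounding box on the source
#' karyogram. Tiles still carrying normalization statistics are inverted
#' with [unnormalizeTile()] first (including the resize back to the original
#' region size). Output dimensions and layout equal the source's.
#'
#' @param tileset a [TileSet-class] whose tiles carry `originalBox`.
#' @return a [KaryogramImage-class].
#' @export
reassembleKaryogram <- function(tileset) {
  stopifnot(is(tileset, "TileSet"))
  src <- tileset@source
  canvas <- src@pixels
  for (tl in tileset@tiles) {
    if (length(tl@originalBox) != 4L)
      stop("reassembly error: tile '", tl@label, "' lacks its original box")
    if (length(tl@normStats)) tl <- unnormalizeTile(tl)
    b <- tl@originalBox
    if (!all(dim(tl@pixels) == c(b[4] - b[2], b[3] - b[1])))
      tl@pixels <- resize_bilinear(tl@pixels, b[4] - b[2], b[3] - b[1])
    canvas[(b[2] + 1L):b[4], (b[1] + 1L):b[3]] <- tl@pixels
  }
  new("KaryogramImage", pixels = canvas, layout = src@layout,
      sourceId = src@sourceId, qualityLabel = src@qualityLabel)
}

.layout_sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".layout.json")

#' Read a karyogram image (PNG or TIFF) with its layout sidecar
#'
#' 8-bit grayscale round-trips bit-exactly. RGB input is converted to
#' luminance; 16-bit TIFF input is linearly rescaled to 8-bit with a
#' warning. The layout map is read from `<stem>.layout.json` when present.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param layoutPath optional explicit sidecar path.
#' @return a [KaryogramImage-class].
#' @export
readKaryogram <- function(path, layoutPath = NULL) {
  if (!file.exists(path)) stop("format error: cannot read '", path, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    px <- a * 255
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (max(a) > 255) {
      warning("16-bit TIFF input linearly rescaled to 8-bit")
      px <- a / 257
    } else px <- a
  } else stop("format error: unsupported extension '", ext, "'")
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      message("RGB input converted to luminance grayscale")
    } else px <- px[, , 1]
  }
  px <- round(clip01(px))
  lp <- if (is.null(layoutPath)) .layout_sidecar_path(path) else layoutPath
  layout <- list()
  if (file.exists(lp)) {
    raw <- jsonlite::read_json(lp, simplifyVector = TRUE)
    layout <- lapply(raw, as.integer)
  }
  new("KaryogramImage", pixels = px, layout = layout,
      sourceId = basename(path), qualityLabel = "unknown")
}

#' Write a karyogram image and its layout sidecar
#'
#' @param karyogram a [KaryogramImage-class].
#' @param path output file; extension selects PNG or TIFF (8-bit grayscale).
#' @return `path`, invisibly.
#' @export
writeKaryogram <- function(karyogram, path) {
  stopifnot(is(karyogram, "KaryogramImage"))
  px <- round(clip01(karyogram@pixels)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(px, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(px, path, bits.per.sample = 8L)
  else stop("format error: unsupported extension '", ext, "'")
  if (length(karyogram@layout))
    jsonlite::write_json(karyogram@layout, .layout_sidecar_path(path))
  invisible(path)
}
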