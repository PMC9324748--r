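# Decomposition, curation, normalization, reassembly and file round trips.

test_that("decomposition returns one crop-faithful tile per region", {
  kg <- renderKaryogram(fixture_genome(), seed = 1, tilePx = 64)
  ts <- decomposeKaryogram(kg)
  expect_s4_class(ts, "TileSet")
  expect_length(tiles(ts), 23)
  expect_identical(vapply(tiles(ts), tileLabel, character(1)),
                   c(as.character(1:22), "sex"))

  # crop fidelity probe: replace the chr-9 region with a marker value
  marked <- kg
  b <- karyoLayout(kg)[["9"]]
  px <- pixels(marked)
  px[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- 111
  pixels(marked) <- px
  t9 <- tiles(decomposeKaryogram(marked))[[9]]
  expect_true(all(pixels(t9) == 111))
  expect_identical(t9@originalBox, b)
  expect_identical(t9@originalSize, c(64L, 64L))
})

test_that("invalid layouts raise layout/bounds errors", {
  kg <- renderKaryogram(fixture_genome(), seed = 1, tilePx = 64)
  short <- kg
  short@layout <- kg@layout[1:22]
  expect_error(decomposeKaryogram(short), "layout error")

  shifted <- kg
  shifted@layout[["1"]] <- shifted@layout[["2"]]  # duplicate -> overlap
  expect_error(decomposeKaryogram(shifted), "overlap")
})

test_that("curation keeps chromosomes 1-12, preserves order, is idempotent", {
  kg <- renderKaryogram(fixture_genome(), seed = 4, tilePx = 64)
  kept <- curateTrainingTiles(decomposeKaryogram(kg))
  expect_length(kept, 12)
  expect_identical(vapply(kept, tileLabel, character(1)), as.character(1:12))
  again <- curateTrainingTiles(kept)
  expect_identical(vapply(again, tileLabel, character(1)),
                   vapply(kept, tileLabel, character(1)))
  expect_lte(length(curateTrainingTiles(kept)), length(kept))
})

test_that("resize-normalize standardizes and is exactly invertible", {
  # arbitrary rectangular tile -> square network size
  tl <- new("PairTile", pixels = matrix(runif(300 * 200, 0, 255), 300, 200),
            label = "3")
  rn <- resizeNormalize(tl, 256)
  expect_identical(dim(pixels(rn)), c(256L, 256L))
  expect_true(all(abs(pixels(rn)) <= 1))

  # moments before the range mapping (recomputed from stored stats)
  z <- pixels(rn) * rn@normStats$clamp
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(as.vector(z)) - 1), 1e-6)

  # constant tile: epsilon guard, all-zero output
  ct <- new("PairTile", pixels = matrix(42, 32, 32), label = "1")
  rc <- resizeNormalize(ct, 64)
  expect_true(all(pixels(rc) == 0))

  # zero-area tile rejected
  expect_error(resizeNormalize(new("PairTile",
                                   pixels = matrix(numeric(0), 0, 0),
                                   label = "1")),
               "zero-area")

  # inverse recovers seeded synthetic tiles within interpolation error
  for (s in 1:5) {
    tile <- fixture_tile(s, size = 100L)
    tile@originalSize <- dim(pixels(tile))
    back <- unnormalizeTile(resizeNormalize(tile, 256))
    mae <- mean(abs(pixels(back) - pixels(tile)))
    expect_lt(mae, 2.0)
  }
})

test_that("decompose-reassemble with untouched tiles is pixel-exact", {
  kg <- renderKaryogram(fixture_genome("XX"), seed = 6, tilePx = 64)
  out <- reassembleKaryogram(decomposeKaryogram(kg))
  expect_identical(pixels(out), pixels(kg))
  expect_identical(karyoLayout(out), karyoLayout(kg))
})

test_that("normalize-translate-reassemble round trip is exact at native size", {
  kg <- renderKaryogram(fixture_genome(), seed = 7, tilePx = 64)
  ts <- decomposeKaryogram(kg)
  ts@tiles <- lapply(tiles(ts), resizeNormalize, size = 64)
  out <- reassembleKaryogram(ts)
  expect_identical(pixels(out), pixels(kg))
})

test_that("reassembly requires tile provenance", {
  kg <- renderKaryogram(fixture_genome(), seed = 7, tilePx = 64)
  ts <- decomposeKaryogram(kg)
  ts@tiles[[3]]@originalBox <- integer()
  expect_error(reassembleKaryogram(ts), "reassembly error")
})

test_that("coordinates are 0-based half-open: a unit box crops one pixel", {
  px <- matrix(seq_len(100), 10, 10)
  kg <- new("KaryogramImage", pixels = px,
            layout = list("1" = c(3L, 4L, 4L, 5L)))
  tl <- tiles(decomposeKaryogram(kg, strict = FALSE))[[1]]
  expect_identical(dim(pixels(tl)), c(1L, 1L))
  expect_identical(as.vector(pixels(tl)), px[5, 4])
})

test_that("PNG and TIFF round trips are bit-exact with layout sidecars", {
  kg <- renderKaryogram(fixture_genome(), seed = 8, tilePx = 64)
  for (ext in c("png", "tif")) {
    path <- file.path(tempdir(), paste0("kg_roundtrip.", ext))
    writeKaryogram(kg, path)
    back <- readKaryogram(path)
    expect_identical(pixels(back), pixels(kg))
    expect_identical(karyoLayout(back), karyoLayout(kg))
  }
})

test_that("16-bit TIFF and RGB PNG inputs are coerced with notice", {
  p16 <- file.path(tempdir(), "deep.tif")
  tiff::writeTIFF(matrix(runif(64^2), 64), p16, bits.per.sample = 16L)
  expect_warning(k <- readKaryogram(p16), "16-bit")
  expect_lte(max(pixels(k)), 255)

  prgb <- file.path(tempdir(), "rgb.png")
  png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), prgb)
  expect_message(k2 <- readKaryogram(prgb), "luminance")
  expect_true(is.matrix(pixels(k2)))

  expect_error(readKaryogram(file.path(tempdir(), "nope.png")),
               "format error")
})
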