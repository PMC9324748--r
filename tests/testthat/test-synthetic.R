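# Synthetic karyogram generator: rendering, layout, degradation, corpora.

test_that("pair-tile rendering is deterministic and respects band structure", {
  sp <- fixture_genome()@chromosomes[[1]]
  t1 <- renderPairTile(sp, jitterSeed = 0)
  t2 <- renderPairTile(sp, jitterSeed = 0)
  expect_identical(t1, t2)
  expect_false(identical(t1, renderPairTile(sp, jitterSeed = 1)))

  # background light, chromosomes darker
  expect_gte(min(t1[1, ]), 230)
  expect_true(any(t1 < 230))

  # a single all-dark band: every foreground pixel carries that intensity
  dark <- chromosomeSpec("5", 0.7, 12L, 0.4,
                         cbind(0, 1, 77))
  td <- renderPairTile(dark, jitterSeed = 3)
  fg <- td[td < 230]
  expect_true(length(fg) > 0)
  expect_true(all(fg == 77))
})

test_that("alternating bands yield k-1 intensity transitions per homolog", {
  for (k in c(3L, 6L, 9L)) {
    cuts <- seq(0, 1, length.out = k + 1)
    bands <- cbind(cuts[-(k + 1)], cuts[-1],
                   rep(c(60, 200), length.out = k))
    sp <- chromosomeSpec("4", 0.8, 14L, 0.35, bands)
    tile <- renderPairTile(sp, jitterSeed = 11, size = 128)
    # scan each homolog: per-row foreground intensity along the medial axis
    for (xr in list(1:64, 65:128)) {
      sub <- tile[, xr]
      prof <- apply(sub, 1, function(row) {
        f <- row[row < 230]
        if (length(f)) f[[1]] else NA_real_
      })
      prof <- prof[!is.na(prof)]
      transitions <- sum(diff(prof) != 0)
      expect_equal(transitions, k - 1)
    }
  }
})

test_that("invalid band coverage is rejected", {
  expect_error(chromosomeSpec("1", 1, 12L, 0.5,
                              cbind(c(0, 0.6), c(0.5, 1), c(80, 200))),
               "contiguous")
  expect_error(chromosomeSpec("1", 1, 12L, 0.5, cbind(0.1, 1, 80)), "cover")
})

test_that("karyogram rendering produces a 23-region deterministic layout", {
  g <- fixture_genome("XY")
  kg <- renderKaryogram(g, seed = 5, tilePx = 64)
  expect_s4_class(kg, "KaryogramImage")
  expect_length(karyoLayout(kg), 23)
  expect_setequal(names(karyoLayout(kg)), c(as.character(1:22), "sex"))
  kg2 <- renderKaryogram(g, seed = 5, tilePx = 64)
  expect_identical(pixels(kg), pixels(kg2))

  # regions are disjoint and within the image
  boxes <- karyoLayout(kg)
  for (b in boxes) {
    expect_true(b[1] >= 0 && b[2] >= 0)
    expect_true(b[3] <= ncol(pixels(kg)) && b[4] <= nrow(pixels(kg)))
  }

  # crop of the chr-7 region equals an independent tile render with the
  # documented derived jitter seed (group index 7)
  b <- boxes[["7"]]
  crop <- pixels(kg)[(b[2] + 1):b[4], (b[1] + 1):b[3]]
  sp7 <- g@chromosomes[[7]]
  expect_identical(crop, renderPairTile(sp7, jitterSeed = 5 + 7919L * 7L,
                                        size = 64))
})

test_that("a too-small canvas raises a layout error", {
  expect_error(renderKaryogram(fixture_genome(), seed = 1, tilePx = 64,
                               canvasSize = c(100, 100)),
               "layout error")
})

test_that("degradation with identity parameters is pixel-exact identity", {
  kg <- renderKaryogram(fixture_genome(), seed = 2, tilePx = 64)
  out <- degradeImage(pixels(kg), degradationParams(0, 0, 1, seed = 9))
  expect_identical(out, pixels(kg))
})

test_that("blur leaves a constant image unchanged", {
  x <- matrix(101.5, 40, 40)
  out <- degradeImage(x, degradationParams(2.0, 0, 1, seed = 1))
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("noise-only degradation has the prescribed per-pixel MSE", {
  x <- matrix(128, 128, 128)  # 16384 pixels
  out <- degradeImage(x, degradationParams(0, 10, 1, seed = 4))
  mse <- mean((out - x)^2)
  expect_lt(abs(mse - 100) / 100, 0.05)
  # deterministic given the seed
  expect_identical(out, degradeImage(x, degradationParams(0, 10, 1, seed = 4)))
})

test_that("negative degradation parameters are rejected", {
  expect_error(degradationParams(-1, 0, 1), "blurSigma")
  expect_error(degradationParams(0, -1, 1), "noiseSigma")
  expect_error(degradationParams(0, 0, 0), "contrastFactor")
})

test_that("PSNR separation from ground truth grows with noise level", {
  tile <- fixture_tile(7)
  levels <- c(5, 15, 30)
  ps <- vapply(levels, function(ns) {
    d <- degradeImage(pixels(tile), degradationParams(1, ns, 0.9, seed = 2L))
    psnr(pixels(tile), d)
  }, numeric(1))
  expect_true(all(is.finite(ps)))
  expect_true(all(diff(ps) < 0))
})

test_that("corpus generation applies the 12-of-23 curation rule", {
  co <- makeCorpora(1, 1, degradationParams(), seed = 3, tilePx = 64)
  expect_length(co$poor, 12)
  expect_length(co$excellent, 12)
  expect_setequal(unique(vapply(co$poor, tileLabel, character(1))),
                  as.character(1:12))
  # poor tiles are actually degraded
  expect_false(identical(pixels(co$poor[[1]]),
                         pixels(co$excellent[[1]])))
})

test_that("empty corpora are rejected", {
  expect_error(makeCorpora(0, 1, degradationParams(), seed = 1),
               "validation error")
})
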