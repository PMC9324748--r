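# PSNR/SSIM fidelity: closed forms, symmetry, monotonicity, and agreement
# with an independent reference implementation (scikit-image values computed
# once on deterministically generated pairs and frozen here).

test_that("PSNR matches its closed forms", {
  a <- matrix(100, 16, 16)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1), 20 * log10(255), tolerance = 1e-12)  # 48.131 dB
  expect_equal(psnr(matrix(0, 8, 8), matrix(255, 8, 8)), 0, tolerance = 1e-12)
  expect_error(psnr(a, matrix(0, 4, 4)), "shape mismatch")
  expect_error(psnr(a, a, maxValue = 0), "maxValue")
})

test_that("PSNR decreases strictly with per-pixel MSE", {
  kc <- asNamespace("karyoCycle")
  ref <- kc$with_seed(5, matrix(runif(64^2, 0, 255), 64))
  ps <- vapply(c(2, 5, 10, 20, 40), function(s) {
    noisy <- kc$with_seed(6, pmin(pmax(ref + rnorm(length(ref), 0, s), 0), 255))
    psnr(ref, noisy)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("SSIM satisfies identity, symmetry and range", {
  kc <- asNamespace("karyoCycle")
  a <- kc$with_seed(7, matrix(runif(64^2, 0, 255), 64))
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  b <- kc$with_seed(8, pmin(pmax(a + rnorm(length(a), 0, 30), 0), 255))
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_true(ssim(a, b) >= -1 && ssim(a, b) <= 1)
  expect_error(ssim(a, matrix(0, 64, 32)), "shape mismatch")
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "smaller than")
})

test_that("PSNR and SSIM agree with the reference implementation", {
  # Oracle: skimage.metrics (structural_similarity with gaussian_weights,
  # sigma 1.5, use_sample_covariance=False, data_range 255;
  # peak_signal_noise_ratio with data_range 255) evaluated on the pairs
  # below, regenerated here from the same seeds.
  kc <- asNamespace("karyoCycle")
  oracle <- list(
    list(seed = 1, ssim = 0.9667970745, psnr = 22.3830014368),
    list(seed = 2, ssim = 0.9676808205, psnr = 22.6308115632),
    list(seed = 3, ssim = 0.9647912634, psnr = 22.4228056071))
  for (o in oracle) {
    p <- kc$with_seed(o$seed, {
      a <- matrix(runif(64 * 64, 0, 255), 64)
      b <- pmin(pmax(a + matrix(rnorm(64 * 64, 0, 20), 64), 0), 255)
      list(a = a, b = b)
    })
    expect_equal(ssim(p$a, p$b), o$ssim, tolerance = 1e-6)
    expect_equal(psnr(p$a, p$b), o$psnr, tolerance = 1e-6)
  }
})

test_that("degradation-protocol report: identity generators and bookkeeping", {
  tiles <- lapply(1:5, fixture_tile)
  rep0 <- evaluateEnhancement(NULL, tiles,
                              generatorUE = identity, generatorEU = identity)
  expect_true(all(!is.finite(rep0@perImage$psnr_degraded)))
  expect_true(all(!is.finite(rep0@perImage$psnr_enhanced)))
  expect_equal(rep0@perImage$ssim_degraded, rep(1, 5), tolerance = 1e-9)
  expect_equal(rep0@perImage$ssim_enhanced, rep(1, 5), tolerance = 1e-9)
  expect_equal(rep0@nInfinite, 10L)

  # with a non-trivial plug-in, averages equal the means of per-image values
  blur <- function(m) m * 0.9
  rep1 <- evaluateEnhancement(NULL, tiles, generatorUE = blur,
                              generatorEU = blur)
  expect_equal(nrow(rep1@perImage), 5)
  expect_equal(unname(rep1@averages["psnr_degraded"]),
               mean(rep1@perImage$psnr_degraded))
  expect_equal(unname(rep1@averages["ssim_enhanced"]),
               mean(rep1@perImage$ssim_enhanced))
  expect_error(evaluateEnhancement(NULL, list(), generatorUE = identity),
               "validation error")
})

test_that("method comparison table is complete, deterministic and consistent", {
  tiles <- lapply(1:4, fixture_tile)
  np <- degradationParams(seed = 9L)
  r1 <- compareMethods(tiles, NULL, np, methods = c("none", "he", "bm3d"))
  expect_equal(nrow(r1$perTile), 3 * 4)
  expect_setequal(unique(r1$perTile$method), c("none", "he", "bm3d"))
  r2 <- compareMethods(tiles, NULL, np, methods = c("none", "he", "bm3d"))
  expect_identical(r1$perTile, r2$perTile)

  # "none" rows equal direct metrics of the degraded tiles
  for (i in 1:4) {
    p <- np; p@seed <- np@seed + i
    deg <- degradeImage(pixels(tiles[[i]]), p)
    row <- r1$perTile[r1$perTile$method == "none" & r1$perTile$tile == i, ]
    expect_equal(row$psnr, psnr(pixels(tiles[[i]]), deg), tolerance = 1e-12)
    expect_equal(row$ssim, ssim(pixels(tiles[[i]]), deg), tolerance = 1e-12)
  }

  # noise-free input and identity model: all methods return the input
  clean <- compareMethods(tiles, NULL, degradationParams(0, 0, 1),
                          methods = c("none", "model"), enhancer = identity)
  expect_true(all(!is.finite(clean$perTile$psnr)))
})
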