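# Loss functions, model construction, the optimization step and translation.

test_that("logistic adversarial loss matches its closed form", {
  # zero logits: -ln(0.5) regardless of target
  expect_equal(adversarialLoss(matrix(0, 4, 4), TRUE), log(2), tolerance = 1e-12)
  expect_equal(adversarialLoss(matrix(0, 4, 4), FALSE), log(2), tolerance = 1e-12)
  # single logit, target real: -ln(sigmoid(x))
  expect_equal(adversarialLoss(matrix(2), TRUE), -log(1 / (1 + exp(-2))),
               tolerance = 1e-12)
  # saturating logits with matching target drive the loss to zero
  expect_lt(adversarialLoss(matrix(50, 2, 2), TRUE), 1e-12)
  # brute-force scalar evaluation on random grids
  set.seed(21)
  for (t in c(TRUE, FALSE)) {
    x <- matrix(rnorm(30, 0, 3), 5)
    brute <- mean(vapply(as.vector(x), function(xi) {
      s <- 1 / (1 + exp(-xi))
      -(as.numeric(t) * log(s) + (1 - as.numeric(t)) * log(1 - s))
    }, numeric(1)))
    expect_equal(adversarialLoss(x, t), brute, tolerance = 1e-9)
  }
  expect_error(adversarialLoss(matrix(c(1, NA), 1), TRUE), "numeric error")
  expect_error(adversarialLoss(matrix(0, 2, 2), TRUE, mode = "hinge"),
               "config error")
})

test_that("cycle loss is a symmetric nonnegative L1 mean, zero iff equal", {
  a <- array(runif(64), c(4, 4, 1, 4))
  expect_equal(cycleLoss(a, a), 0)
  expect_equal(cycleLoss(a + 0.5, a), 0.5, tolerance = 1e-12)
  b <- array(runif(64), c(4, 4, 1, 4))
  expect_equal(cycleLoss(a, b), cycleLoss(b, a))
  expect_gte(cycleLoss(a, b), 0)
  expect_error(cycleLoss(a, array(0, c(2, 2, 1, 4))), "shape mismatch")
})

test_that("model construction is seeded-deterministic with contract shapes", {
  cfg <- netConfig("unet_64", baseWidth = 4L)
  b1 <- buildModel(cfg, seed = 31)
  b2 <- buildModel(cfg, seed = 31)
  kc <- asNamespace("karyoCycle")
  expect_identical(kc$net_params(b1@gUE), kc$net_params(b2@gUE))
  expect_identical(kc$net_params(b1@dE), kc$net_params(b2@dE))
  expect_false(identical(kc$net_params(b1@gUE),
                         kc$net_params(buildModel(cfg, seed = 32)@gUE)))

  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  y <- kc$net_fw(b1@gUE, x, FALSE)$y
  expect_identical(dim(y), dim(x))
  logits <- kc$net_fw(b1@dE, x, FALSE)$y
  expect_identical(dim(logits)[3:4], c(1L, 1L))
  expect_gt(prod(dim(logits)[1:2]), 1)  # a grid of patch logits

  # full-scale architecture maps 256 -> 256 (small width to keep it light)
  big <- buildModel(netConfig("unet_256", baseWidth = 2L), seed = 1)
  xb <- array(runif(256 * 256, -1, 1), c(256, 256, 1, 1))
  expect_identical(dim(kc$net_fw(big@gUE, xb, FALSE)$y), dim(xb))

  expect_error(netConfig("resnet_9"), "generatorArch")
})

test_that("one training step yields finite decomposable losses, reproducibly", {
  cfg <- netConfig("unet_64", baseWidth = 4L)
  tc <- trainConfig(batchSize = 2L, epochs = 2L, seed = 5L)
  b <- buildModel(cfg, seed = 5)
  kc <- asNamespace("karyoCycle")
  U <- kc$with_seed(1, array(runif(64 * 64 * 2, -1, 1), c(64, 64, 1, 2)))
  E <- kc$with_seed(2, array(runif(64 * 64 * 2, -1, 1), c(64, 64, 1, 2)))

  r1 <- kc$with_seed(9, trainStep(b, U, E, tc))
  rec <- r1$record
  expect_true(all(is.finite(unlist(rec))))
  expect_gte(rec$loss_cycle, 0)
  # loss decomposition: total equals the sum of logged components
  expect_equal(rec$loss_G_total,
               rec$loss_adv_UE + rec$loss_adv_EU +
                 tc@lambdaCycle * rec$loss_cycle +
                 tc@lambdaIdentity * rec$loss_identity,
               tolerance = 1e-6)

  # identical seed and data -> identical records and identical parameters
  r2 <- kc$with_seed(9, trainStep(b, U, E, tc))
  expect_equal(r1$record, r2$record, tolerance = 1e-12)
  expect_identical(kc$net_params(r1$bundle@gUE), kc$net_params(r2$bundle@gUE))

  # with cycle and identity terms off, the generator loss is purely
  # adversarial, matching separately computed adversarialLoss values
  tc0 <- trainConfig(batchSize = 2L, lambdaCycle = 0, lambdaIdentity = 0,
                     seed = 5L)
  fE <- kc$net_fw(b@gUE, U, TRUE)
  fU <- kc$net_fw(b@gEU, E, TRUE)
  advUE <- adversarialLoss(kc$net_fw(b@dE, fE$y, TRUE)$y, TRUE)
  advEU <- adversarialLoss(kc$net_fw(b@dU, fU$y, TRUE)$y, TRUE)
  r0 <- kc$with_seed(9, trainStep(b, U, E, tc0))
  expect_equal(r0$record$loss_G_total, advUE + advEU, tolerance = 1e-9)
  expect_equal(r0$record$loss_G_total,
               r0$record$loss_adv_UE + r0$record$loss_adv_EU,
               tolerance = 1e-12)
})

test_that("training handles unpaired corpora of unequal sizes", {
  cfg <- netConfig("unet_64", baseWidth = 2L)
  tc <- trainConfig(batchSize = 2L, epochs = 1L, seed = 3L)
  U <- lapply(1:5, function(s) fixture_degrade(fixture_tile(s), s))
  E <- lapply(6:8, fixture_tile)
  b <- trainCycleGAN(U, E, cfg, tc)
  expect_s4_class(b, "CycleGANBundle")
  # epoch length follows the larger corpus
  expect_equal(nrow(lossHistory(b)), ceiling(5 / 2))
  expect_error(trainCycleGAN(U, list(), cfg, tc), "validation error")

  # end-to-end seeded reproducibility: identical seeds and data give
  # identical loss curves and checkpoints
  b2 <- trainCycleGAN(U, E, cfg, tc)
  expect_equal(lossHistory(b)$loss_G_total, lossHistory(b2)$loss_G_total,
               tolerance = 1e-6)
  kc <- asNamespace("karyoCycle")
  expect_identical(kc$net_params(b@gUE), kc$net_params(b2@gUE))
})

test_that("translation is deterministic, shape-preserving and validated", {
  cfg <- netConfig("unet_64", baseWidth = 4L)
  b <- buildModel(cfg, seed = 8)
  tl <- resizeNormalize(fixture_tile(3), 64)
  o1 <- translateTiles(b, list(tl), "UE")
  o2 <- translateTiles(b, list(tl), "UE")
  expect_identical(pixels(o1[[1]]), pixels(o2[[1]]))
  expect_identical(dim(pixels(o1[[1]])), dim(pixels(tl)))
  expect_false(identical(pixels(o1[[1]]),
                         pixels(translateTiles(b, list(tl), "EU")[[1]])))
  expect_identical(translateTiles(b, list(), "UE"), list())
  expect_error(translateTiles(b, list(tl), "XX"), "config error")
})

test_that("checkpoints save and reload bit-compatibly", {
  b <- buildModel(netConfig("unet_64", baseWidth = 2L), seed = 44)
  p <- file.path(tempdir(), "ckpt.rds")
  saveModelBundle(b, p)
  b2 <- loadModelBundle(p)
  kc <- asNamespace("karyoCycle")
  expect_identical(kc$net_params(b@gUE), kc$net_params(b2@gUE))
  tl <- resizeNormalize(fixture_tile(1), 64)
  expect_identical(pixels(translateTiles(b, list(tl), "UE")[[1]]),
                   pixels(translateTiles(b2, list(tl), "UE")[[1]]))
  saveRDS(list(format = "other"), p)
  expect_error(loadModelBundle(p), "format error")
})
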