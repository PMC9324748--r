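# The two-generator / two-discriminator cycle-consistent adversarial model
# and its training loop. G_UE translates unenhanced -> enhanced, G_EU the
# reverse; D_E and D_U judge the two domains. The adversarial objective is
# the logistic (binary cross-entropy) loss; cycle consistency and identity
# terms use L1.

#' Network configuration constructor
#'
#' @param generatorArch `"unet_256"` (8 levels, 256x256 input) or
#'   `"unet_64"` (6 levels, 64x64 input — the reduced desk-scale fixture).
#' @param norm `"batch"` (default) or `"instance"` in-network normalization.
#' @param baseWidth filters in the first generator layer (64 full scale; 16
#'   is the fixture value).
#' @param inChannels,outChannels image channels (1: grayscale).
#' @return a [NetConfig-class].
#' @export
netConfig <- function(generatorArch = "unet_256", norm = "batch",
                      baseWidth = 64L, inChannels = 1L, outChannels = 1L) {
  new("NetConfig", generatorArch = generatorArch,
      discriminatorArch = "patchgan", inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), norm = norm,
      baseWidth = as.integer(baseWidth))
}

#' Training configuration constructor
#'
#' @param batchSize images per step (default 4).
#' @param epochs training epochs (200 full scale; 5-20 for the fixture).
#' @param lambdaCycle cycle-loss weight (default 10).
#' @param lambdaIdentity identity-loss weight (default half of
#'   `lambdaCycle`; 0 disables).
#' @param lr initial Adam learning rate (2e-4, linear decay to zero over the
#'   second half of training).
#' @param seed integer seed.
#' @param adversarialMode `"logistic"` (default) or `"lsgan"`.
#' @param poolSize discriminator history-buffer size (default 50).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 4L, epochs = 200L, lambdaCycle = 10,
                        lambdaIdentity = 0.5 * lambdaCycle, lr = 2e-4,
                        seed = 1L, adversarialMode = "logistic",
                        poolSize = 50L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), lambdaCycle = lambdaCycle,
      lambdaIdentity = lambdaIdentity, lr = lr, seed = as.integer(seed),
      adversarialMode = adversarialMode, poolSize = as.integer(poolSize))
}

net_image_size <- function(cfg) if (cfg@generatorArch == "unet_256") 256L else 64L
net_num_downs <- function(cfg) if (cfg@generatorArch == "unet_256") 8L else 6L

#' Build an untrained model bundle
#'
#' Constructs the four networks with seeded deterministic initialization.
#' Generators map `1 x S x S` to `1 x S x S` (S = 256 or 64 by architecture);
#' discriminators map an image to a grid of patch logits.
#'
#' @param config a [NetConfig-class].
#' @param seed integer initialization seed.
#' @return an untrained [CycleGANBundle-class].
#' @export
#' @examples
#' b <- buildModel(netConfig("unet_64", baseWidth = 4L), seed = 1)
buildModel <- function(config, seed = 1L) {
  validObject(config)
  nd <- net_num_downs(config)
  with_seed(seed, {
    gUE <- build_unet(config@inChannels, config@outChannels, nd,
                      config@baseWidth, config@norm, "gUE")
    gEU <- build_unet(config@inChannels, config@outChannels, nd,
                      config@baseWidth, config@norm, "gEU")
    dE <- build_patchgan(config@inChannels, config@baseWidth, config@norm, "dE")
    dU <- build_patchgan(config@inChannels, config@baseWidth, config@norm, "dU")
  })
  new("CycleGANBundle", gUE = gUE, gEU = gEU, dE = dE, dU = dU,
      netConfig = config, trainConfig = trainConfig(),
      history = data.frame(), optState = list(), pools = list())
}

#' Adversarial loss over a grid of discriminator logits
#'
#' Logistic mode: mean binary cross-entropy of `sigmoid(scores)` against the
#' target label (1 = real, 0 = fake), computed in a numerically stable form.
#' `"lsgan"` mode: mean squared error of the raw scores against the label.
#'
#' @param scores numeric array of patch logits.
#' @param targetIsReal logical target label.
#' @param mode `"logistic"` or `"lsgan"`.
#' @return scalar loss.
#' @export
#' @examples
#' adversarialLoss(matrix(0, 4, 4), TRUE)  # log(2)
adversarialLoss <- function(scores, targetIsReal, mode = "logistic") {
  if (any(!is.finite(scores))) stop("numeric error: non-finite logits")
  t <- as.numeric(targetIsReal)
  if (mode == "logistic")
    mean(pmax(scores, 0) - scores * t + log1p(exp(-abs(scores))))
  else if (mode == "lsgan") mean((scores - t)^2)
  else stop("config error: unknown adversarial mode '", mode, "'")
}

# gradient of adversarialLoss with respect to the logits
adv_loss_grad <- function(scores, targetIsReal, mode = "logistic") {
  t <- as.numeric(targetIsReal)
  n <- length(scores)
  if (mode == "logistic") (1 / (1 + exp(-scores)) - t) / n
  else 2 * (scores - t) / n
}

#' L1 cycle-consistency loss
#'
#' Mean absolute difference between a reconstructed batch and the original.
#' Nonnegative, symmetric, and zero iff the inputs are equal.
#'
#' @param reconstructed,original numeric arrays of identical shape.
#' @return scalar loss.
#' @export
cycleLoss <- function(reconstructed, original) {
  if (!identical(dim(reconstructed), dim(original)) ||
      length(reconstructed) != length(original))
    stop("validation error: shape mismatch in cycle loss")
  mean(abs(reconstructed - original))
}

l1_grad <- function(a, b) sign(a - b) / length(a)

# stack normalized tiles (or matrices) into an [h, w, 1, n] batch
tiles_to_batch <- function(tiles) {
  mats <- lapply(tiles, function(t) if (is(t, "PairTile")) t@pixels else t)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats), c(h, w, 1L, length(mats)))
}

# history buffer of generated images: each incoming image is stored; once the
# pool is full it is swapped with a random stored image with probability 1/2.
pool_query <- function(pool, batch, pool_size) {
  n <- dim(batch)[4]
  out <- batch
  for (i in seq_len(n)) {
    img <- batch[, , , i, drop = FALSE]
    if (length(pool) < pool_size) {
      pool[[length(pool) + 1L]] <- img
    } else if (runif(1) > 0.5) {
      j <- sample.int(length(pool), 1L)
      out[, , , i] <- pool[[j]]
      pool[[j]] <- img
    }
  }
  list(pool = pool, batch = out)
}

#' One optimization step of the cycle-GAN
#'
#' Performs one Adam step for the generators (adversarial terms in both
#' directions, cycle-consistency terms weighted by `lambdaCycle`, identity
#' terms weighted by `lambdaIdentity`) and one for each discriminator
#' (real vs generated, drawing fakes from a 50-image history buffer).
#'
#' @param bundle a [CycleGANBundle-class].
#' @param batchU,batchE batches from the unenhanced / enhanced domains:
#'   `[h, w, 1, n]` arrays in the network range `[-1, 1]`, or lists of
#'   normalized [PairTile-class].
#' @param config a [TrainConfig-class].
#' @param lr learning rate for this step (defaults to `config@@lr`).
#' @return `list(bundle, record)` where `record` is a one-row data.frame of
#'   the loss components.
#' @export
trainStep <- function(bundle, batchU, batchE, config = bundle@trainConfig,
                      lr = config@lr) {
  if (is.list(batchU)) batchU <- tiles_to_batch(batchU)
  if (is.list(batchE)) batchE <- tiles_to_batch(batchE)
  mode <- config@adversarialMode
  lc <- config@lambdaCycle; li <- config@lambdaIdentity
  gUE <- bundle@gUE; gEU <- bundle@gEU; dE <- bundle@dE; dU <- bundle@dU

  ## ---- generator forward passes
  fU <- net_fw(gUE, batchU, TRUE); fakeE <- fU$y; gUE <- fU$net
  rU <- net_fw(gEU, fakeE, TRUE); recU <- rU$y; gEU <- rU$net
  fE <- net_fw(gEU, batchE, TRUE); fakeU <- fE$y; gEU <- fE$net
  rE <- net_fw(gUE, fakeU, TRUE); recE <- rE$y; gUE <- rE$net

  sE <- net_fw(dE, fakeE, TRUE); dE <- sE$net
  sU <- net_fw(dU, fakeU, TRUE); dU <- sU$net
  loss_adv_UE <- adversarialLoss(sE$y, TRUE, mode)
  loss_adv_EU <- adversarialLoss(sU$y, TRUE, mode)
  loss_cyc_U <- cycleLoss(recU, batchU)
  loss_cyc_E <- cycleLoss(recE, batchE)

  loss_idt <- 0
  if (li > 0) {
    iE <- net_fw(gUE, batchE, TRUE); gUE <- iE$net
    iU <- net_fw(gEU, batchU, TRUE); gEU <- iU$net
    loss_idt_E <- cycleLoss(iE$y, batchE)
    loss_idt_U <- cycleLoss(iU$y, batchU)
    loss_idt <- loss_idt_E + loss_idt_U
  }
  loss_cycle <- loss_cyc_U + loss_cyc_E
  loss_G <- loss_adv_UE + loss_adv_EU + lc * loss_cycle + li * loss_idt
  if (!is.finite(loss_G))
    stop("training aborted: non-finite generator loss (adv_UE=", loss_adv_UE,
         ", adv_EU=", loss_adv_EU, ", cycle=", loss_cycle, ")")

  ## ---- generator backward
  gr_UE <- list(); gr_EU <- list()
  # cycle U: batchU -> fakeE -> recU
  b_rU <- net_bw(gEU, rU$cache, lc * l1_grad(recU, batchU))
  gr_EU <- acc_grads(gr_EU, b_rU$grads)
  b_advE <- net_bw(dE, sE$cache, adv_loss_grad(sE$y, TRUE, mode))
  b_fU <- net_bw(gUE, fU$cache, b_rU$dx + b_advE$dx)
  gr_UE <- acc_grads(gr_UE, b_fU$grads)
  # cycle E: batchE -> fakeU -> recE
  b_rE <- net_bw(gUE, rE$cache, lc * l1_grad(recE, batchE))
  gr_UE <- acc_grads(gr_UE, b_rE$grads)
  b_advU <- net_bw(dU, sU$cache, adv_loss_grad(sU$y, TRUE, mode))
  b_fE <- net_bw(gEU, fE$cache, b_rE$dx + b_advU$dx)
  gr_EU <- acc_grads(gr_EU, b_fE$grads)
  if (li > 0) {
    gr_UE <- acc_grads(gr_UE, net_bw(gUE, iE$cache, li * l1_grad(iE$y, batchE))$grads)
    gr_EU <- acc_grads(gr_EU, net_bw(gEU, iU$cache, li * l1_grad(iU$y, batchU))$grads)
  }

  st <- bundle@optState
  if (is.null(st$t)) st <- list(t = 0L, G = list(), D = list())
  st$t <- st$t + 1L
  up <- adam_update_net(gUE, gr_UE, st$G, lr, st$t); gUE <- up$net; st$G <- up$state
  up <- adam_update_net(gEU, gr_EU, st$G, lr, st$t); gEU <- up$net; st$G <- up$state

  ## ---- discriminator updates (fakes drawn from the history buffers)
  pools <- bundle@pools
  if (is.null(pools$E)) pools <- list(E = list(), U = list())
  pq <- pool_query(pools$E, fakeE, config@poolSize)
  pools$E <- pq$pool; fakeE_d <- pq$batch
  pq <- pool_query(pools$U, fakeU, config@poolSize)
  pools$U <- pq$pool; fakeU_d <- pq$batch

  upd_D <- function(dnet, real, fake) {
    oR <- net_fw(dnet, real, TRUE); dnet <- oR$net
    oF <- net_fw(dnet, fake, TRUE); dnet <- oF$net
    lossD <- 0.5 * (adversarialLoss(oR$y, TRUE, mode) +
                    adversarialLoss(oF$y, FALSE, mode))
    gr <- acc_grads(net_bw(dnet, oR$cache, 0.5 * adv_loss_grad(oR$y, TRUE, mode))$grads,
                    net_bw(dnet, oF$cache, 0.5 * adv_loss_grad(oF$y, FALSE, mode))$grads)
    list(net = dnet, grads = gr, loss = lossD)
  }
  rDE <- upd_D(dE, batchE, fakeE_d)
  rDU <- upd_D(dU, batchU, fakeU_d)
  if (!is.finite(rDE$loss) || !is.finite(rDU$loss))
    stop("training aborted: non-finite discriminator loss")
  up <- adam_update_net(rDE$net, rDE$grads, st$D, lr, st$t); dE <- up$net; st$D <- up$state
  up <- adam_update_net(rDU$net, rDU$grads, st$D, lr, st$t); dU <- up$net; st$D <- up$state

  record <- data.frame(
    iteration = st$t, loss_adv_UE = loss_adv_UE, loss_adv_EU = loss_adv_EU,
    loss_D_E = rDE$loss, loss_D_U = rDU$loss, loss_cycle = loss_cycle,
    loss_identity = loss_idt, loss_G_total = loss_G, lr = lr)

  bundle@gUE <- gUE; bundle@gEU <- gEU; bundle@dE <- dE; bundle@dU <- dU
  bundle@optState <- st; bundle@pools <- pools
  bundle@history <- rbind(bundle@history, record)
  list(bundle = bundle, record = record)
}

#' Train the cycle-GAN on unpaired corpora
#'
#' Runs `epochs` over shuffled batches. The corpora are unpaired and may have
#' different sizes: the epoch length is `ceiling(max(nU, nE) / batchSize)`
#' and the shorter corpus is resampled. Raw tiles (`[0, 255]` pixels) are
#' resized to the network size and normalized automatically. The learning
#' rate is constant over the first half of training and decays linearly to
#' zero over the second half. Fully deterministic given `config@@seed`.
#'
#' @param corpusU,corpusE lists of [PairTile-class] (raw or normalized) or
#'   grayscale matrices; the unenhanced (poor) and enhanced (excellent)
#'   domains.
#' @param config a [NetConfig-class].
#' @param train a [TrainConfig-class].
#' @param checkpointDir optional directory; the bundle is saved there after
#'   every epoch.
#' @param verbose print per-epoch median losses.
#' @return a trained [CycleGANBundle-class] with full loss history.
#' @export
trainCycleGAN <- function(corpusU, corpusE, config = netConfig(),
                          train = trainConfig(), checkpointDir = NULL,
                          verbose = FALSE) {
  if (length(corpusU) == 0L || length(corpusE) == 0L)
    stop("validation error: both training corpora must be non-empty")
  size <- net_image_size(config)
  prep <- function(tl) {
    if (is.matrix(tl)) tl <- new("PairTile", pixels = tl, label = "1")
    if (length(tl@normStats) == 0L) tl <- resizeNormalize(tl, size)
    tl@pixels
  }
  U <- lapply(corpusU, prep); E <- lapply(corpusE, prep)
  bundle <- buildModel(config, seed = train@seed)
  bundle@trainConfig <- train
  bs <- train@batchSize
  n_long <- max(length(U), length(E))
  steps <- ceiling(n_long / bs)
  half <- ceiling(train@epochs / 2)
  with_seed(train@seed + 1L, {
    for (ep in seq_len(train@epochs)) {
      lr_ep <- if (ep <= half) train@lr else
        train@lr * (train@epochs - ep + 1) / (train@epochs - half)
      draw <- function(x) {
        idx <- sample.int(length(x))
        if (length(idx) < steps * bs)
          idx <- c(idx, sample.int(length(x), steps * bs - length(idx),
                                   replace = TRUE))
        idx[seq_len(steps * bs)]
      }
      iU <- draw(U); iE <- draw(E)
      for (s in seq_len(steps)) {
        sel <- ((s - 1) * bs + 1):(s * bs)
        r <- trainStep(bundle, tiles_to_batch(U[iU[sel]]),
                       tiles_to_batch(E[iE[sel]]), train, lr = lr_ep)
        bundle <- r$bundle
      }
      if (verbose) {
        h <- utils::tail(bundle@history, steps)
        message(sprintf("epoch %d/%d: cycle %.4f, G %.4f", ep, train@epochs,
                        stats::median(h$loss_cycle), stats::median(h$loss_G_total)))
      }
      if (!is.null(checkpointDir))
        saveModelBundle(bundle, file.path(checkpointDir,
                                          sprintf("epoch_%03d.rds", ep)))
    }
  })
  bundle
}

#' Translate tiles with a generator
#'
#' Applies the selected generator image-by-image in inference mode (batch
#' statistics frozen to the running averages), so the output is deterministic
#' and independent of batch composition.
#'
#' @param bundle a [CycleGANBundle-class].
#' @param tiles list of normalized [PairTile-class] or `[-1, 1]` matrices.
#' @param direction `"UE"` (unenhanced to enhanced) or `"EU"` (the reverse,
#'   used to generate poor images from excellent ground truth).
#' @return list of the same type as the input, pixels replaced.
#' @export
translateTiles <- function(bundle, tiles, direction = c("UE", "EU")) {
  if (!is.character(direction) || !all(direction %in% c("UE", "EU")) ||
      length(direction) > 2L)
    stop("config error: direction must be 'UE' or 'EU'")
  direction <- match.arg(direction)
  net <- if (direction == "UE") bundle@gUE else bundle@gEU
  lapply(tiles, function(tl) {
    px <- if (is(tl, "PairTile")) tl@pixels else tl
    y <- net_fw(net, array(px, c(dim(px), 1L, 1L)), training = FALSE)$y
    out <- matrix(y[, , 1L, 1L], nrow(px), ncol(px))
    if (is(tl, "PairTile")) { tl@pixels <- out; tl } else out
  })
}

#' Save / load a model bundle
#'
#' The checkpoint is a single-archive serialization of the bundle with a
#' config fingerprint; reloading reproduces the networks bit-compatibly.
#'
#' @param bundle a [CycleGANBundle-class].
#' @param path checkpoint file path (`.rds`).
#' @return `saveModelBundle`: `path` invisibly; `loadModelBundle`: the bundle.
#' @export
saveModelBundle <- function(bundle, path) {
  stopifnot(is(bundle, "CycleGANBundle"))
  saveRDS(list(format = "karyoCycle-bundle-v1", bundle = bundle), path)
  invisible(path)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "karyoCycle-bundle-v1"))
    stop("format error: not a karyoCycle checkpoint")
  x$bundle
}
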