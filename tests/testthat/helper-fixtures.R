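# Shared fixtures. Everything is generated in code under fixed seeds; the
# trained reduced-scale model is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_genome <- function(sex = "XY") {
  key <- paste0("genome_", sex)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- defaultGenomeSpec(sex)
  .fixture_cache[[key]]
}

# one synthetic 64x64 pair tile (chromosomes 1-12 cycle with the seed)
fixture_tile <- function(seed, size = 64L) {
  sp <- fixture_genome()@chromosomes[[(seed %% 12) + 1]]
  px <- renderPairTile(sp, jitterSeed = seed, size = size)
  new("PairTile", pixels = px, label = sp@label,
      sourceId = paste0("fix", seed))
}

fixture_degrade <- function(tile, seed, params = degradationParams()) {
  params@seed <- as.integer(seed)
  pixels(tile) <- degradeImage(pixels(tile), params)
  tile
}

# The sanctioned reduced-scale training run: 6-level U-Net at 64x64 with
# base width 16, 40 poor + 40 excellent synthetic tiles, 20 epochs, batch 4,
# fixed seed. Trained once and reused by every test that needs a trained
# model.
fixture_trained_bundle <- function() {
  if (!is.null(.fixture_cache$bundle)) return(.fixture_cache$bundle)
  exc <- lapply(1:40, fixture_tile)
  poor <- lapply(101:140, function(s) fixture_degrade(fixture_tile(s), s))
  cfg <- netConfig("unet_64", baseWidth = 16L)
  tc <- trainConfig(batchSize = 4L, epochs = 20L, seed = 42L)
  .fixture_cache$bundle <- trainCycleGAN(poor, exc, cfg, tc)
  .fixture_cache$bundle
}

# held-out evaluation tiles (never seen in training) and their degraded
# counterparts
fixture_holdout <- function(n = 50L) {
  key <- paste0("holdout_", n)
  if (is.null(.fixture_cache[[key]])) {
    clean <- lapply(200 + seq_len(n), fixture_tile)
    degraded <- lapply(seq_len(n), function(i)
      fixture_degrade(clean[[i]], 1000L + i))
    .fixture_cache[[key]] <- list(clean = clean, degraded = degraded)
  }
  .fixture_cache[[key]]
}

# enhance degraded tiles with the bundle's UE generator, back in 8-bit space
enhance_tiles_8bit <- function(bundle, degraded_tiles, size = 64L) {
  norm <- lapply(degraded_tiles, resizeNormalize, size = size)
  enh <- translateTiles(bundle, norm, "UE")
  lapply(enh, function(tl) pixels(unnormalizeTile(tl)))
}

# synthetic rating study: nk karyograms x 2 raters x 2 conditions; the
# enhanced condition scores +1 on every scale (clipped to 5) with seeded
# jitter, and takes longer to analyze
make_ratings <- function(nk = 60L, seed = 1L, swap = FALSE) {
  kc <- asNamespace("karyoCycle")
  kc$with_seed(seed, {
    rows <- list()
    for (rater in c("specialist1", "specialist2")) {
      for (k in seq_len(nk)) {
        q <- sample(2:4, 1); s <- sample(2:4, 1)
        tm <- runif(1, 60, 240)
        jq <- sample(0:1, 1); js <- sample(0:1, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          karyogram_id = sprintf("k%02d", k), condition = "original",
          rater_id = rater, quality = q, sharpness = s,
          analysis_time_s = tm, suspected_abnormality = "")
        rows[[length(rows) + 1L]] <- data.frame(
          karyogram_id = sprintf("k%02d", k), condition = "enhanced",
          rater_id = rater, quality = min(5, q + 1 + jq),
          sharpness = min(5, s + 1 + js),
          analysis_time_s = tm + runif(1, 10, 60),
          suspected_abnormality = "")
      }
    }
    df <- do.call(rbind, rows)
    if (swap) df$condition <- ifelse(df$condition == "original",
                                     "enhanced", "original")
    df
  })
}


# a tile with a simulated terminal deletion of the right homolog: the distal
# part below the cut is blanked to background; the mask marks the removed
# foreground (with a 2-row margin at the cut line, so the score measures
# invented material rather than boundary bleed)
fixture_deletion_tile <- function(seed) {
  sp <- fixture_genome()@chromosomes[[(seed %% 12) + 1]]
  px <- renderPairTile(sp, jitterSeed = seed, size = 64)
  fg <- px < 230
  right <- 33:64
  rws <- which(apply(fg[, right], 1, any))
  cut <- rws[ceiling(length(rws) * 0.6)]
  mask <- matrix(FALSE, 64, 64)
  mask[(cut + 2):64, right] <- fg[(cut + 2):64, right]
  px[cut:64, right][fg[cut:64, right]] <- 245
  list(pixels = px, mask = mask, label = sp@label)
}
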