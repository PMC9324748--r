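# karyoCycle

Per-pair enhancement of clinical G-banded karyograms with a cycle-consistent
generative adversarial network, in R.

Bone-marrow cytogenetics often has to work with poor-quality karyograms —
blurred, noisy, low-contrast — which slows analysis and can hide cryptic
chromosomal abnormalities. `karyoCycle` implements an enhancement pipeline
that treats each of the 23 chromosome-pair tiles of a karyogram
individually: cut the karyogram along its layout map, translate every tile
from the "unenhanced" domain to the "enhanced" domain with a trained
generator, and reassemble the karyogram. Because paired poor/excellent
images of the same cell do not exist, the translator is trained *unpaired*
(CycleGAN): two generators `G_UE` / `G_EU` and two patch discriminators
`D_E` / `D_U`, with a logistic adversarial loss, an L1 cycle-consistency
loss (weight 10) and an identity loss (weight 5):

```
L = L_adv(D_E, G_UE) + L_adv(D_U, G_EU)
    + 10 * ( |G_EU(G_UE(u)) - u|_1 + |G_UE(G_EU(e)) - e|_1 )
    +  5 * ( |G_UE(e) - e|_1 + |G_EU(u) - u|_1 )
```

The generator is a `unet_256` encoder–decoder (8 levels, 256×256 grayscale);
training uses Adam (beta1 = 0.5, lr 2e-4 with linear decay over the second
half), batch size 4, and a 50-image history buffer for the discriminators.
The network engine (convolutions, batch/instance normalization, U-Net skip
connections, hand-derived backward passes) is implemented in R with
Rcpp/RcppArmadillo kernels and verified against finite differences in the
test suite.

The package also provides:

* a synthetic banded-karyogram generator (chromosome-specific relative
  lengths, centromeres, seeded pseudo-ideogram band patterns, four-row
  layout) with a parametric degradation operator (blur + contrast
  compression + noise) standing in for undeposited clinical corpora;
* tile curation for training (keep chromosomes 1–12: 88 karyograms → 1056
  tiles) and exactly invertible per-tile intensity normalization;
* PSNR/SSIM quality metrics (SSIM cross-checked against a reference
  implementation to 1e-6) and a degradation-based evaluation protocol;
* histogram-equalization and BM3D (hard-threshold stage) baselines;
* rating-study statistics (per-rater one-tailed paired t-tests for the
  quality / sharpness / analysis-time hypotheses);
* a structural-fidelity score checking that enhancement does not invent
  chromosomal material in regions that are background in the original.

## Worked example

```r
library(karyoCycle)

genome <- defaultGenomeSpec("XY")
kg <- renderKaryogram(genome, seed = 1)
kg
#> KaryogramImage 'synthetic-1' (excellent): 1024 x 1792 px, 23 layout regions

ts <- decomposeKaryogram(kg)
ts
#> TileSet: 23 tiles from karyogram 'synthetic-1'
length(curateTrainingTiles(ts))
#> [1] 12

tile <- tiles(ts)[[1]]
poor <- degradeImage(pixels(tile), degradationParams(seed = 1))
sprintf("degraded tile: PSNR %.2f dB, SSIM %.3f",
        psnr(pixels(tile), poor), ssim(pixels(tile), poor))
#> "degraded tile: PSNR 16.71 dB, SSIM 0.267"

# the pipeline with an identity enhancer is pixel-exact at native tile size
out <- enhanceKaryogram(kg, enhancer = identity, size = 256)
max(abs(pixels(out) - pixels(kg)))
#> [1] 0
```

The numbers read as follows: the synthetic karyogram carries 23 pair-group
regions of which 12 (chromosomes 1–12) survive training curation; the
default degradation drops a clean tile to about 16.7 dB PSNR and 0.27 SSIM,
which is the baseline an enhancer must beat; and the cut → normalize →
enhance → reassemble loop itself introduces no error.

Training and enhancing at the reduced verification scale (64×64 tiles,
6-level U-Net, base width 16 — minutes on a CPU):

```r
co <- makeCorpora(4, 4, degradationParams(), seed = 1, tilePx = 64)
bundle <- trainCycleGAN(co$poor, co$excellent,
                        netConfig("unet_64", baseWidth = 16L),
                        trainConfig(epochs = 20L, seed = 42L))
enhanced <- enhanceKaryogram(renderKaryogram(genome, 2, tilePx = 64), bundle)
```

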