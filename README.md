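# foveanet

Simulation toolkit for studying **intrinsic scale- and translation-invariance
in one-shot visual recognition**, for computational neuroscientists and
vision modellers. It asks: when a recognition system sees a novel glyph
exactly once, how far can the stimulus be rescaled or displaced before a
same/different judgement against a paired distractor breaks down — and which
network architecture reproduces the human-like answer (broad scale tolerance,
narrow size-dependent position tolerance, and a central/peripheral learning
asymmetry)?

## The model

Two networks share one four-layer stack (conv 11×11 stride 4 + 5×5 max-pool
stride 2, then three rounds of conv 5×5 stride 1 + 5×5 pool stride 2, then a
fully connected classifier):

* **ENN** — an *eccentricity-dependent network*. Its input is a set of
  concentric square crops of the simulated visual field with spans
  `s_k = round(225 · 1.5^(k−1))` px, k = 1..10, each anti-alias resampled to
  a common 225-px grid (at the fixed calibration of 450 px/deg the coarsest
  crop spans ≈ 19.2°). The *same* weights process every scale channel, and
  last-layer features are max-pooled element-wise over channels:
  `f = max_k φ(c_k)`. The fovea is seen at every resolution, the periphery
  only coarsely — receptive fields effectively grow with eccentricity, and
  scale invariance is built in (rescaling by 1.5 ≈ shifting one channel).
* **CNN control** — the same stack applied once to the whole field at the
  resolution of ENN channel 5 (its mid-resolution). Any invariance it shows
  must come from training data (example-based).

One-shot evaluation: a target glyph is "learned" (features stored), a test
glyph (same or its structurally similar distractor) is presented at another
size/eccentricity, and the pair counts as "same" when the Pearson
correlation of the features exceeds a per-condition, accuracy-maximising
threshold. The ENN additionally supports an **asymmetric** metric: the stored
target keeps its per-channel templates (plus its pooled vector), the test
contributes only its scale-pooled feature, and the best-correlated stored
template is selected — which makes learning order matter, as it does for
human observers. Accuracy-threshold optimisation, d′ (with log-linear edge
correction), raw correlation-vs-eccentricity tables, and interpolated
(size × eccentricity) invariance windows with threshold boundaries are all
included, as are procedural glyph generators (novel target/distractor pairs
and labelled training classes) so everything runs offline.

## Worked example

The desk profile (150 px/deg, 75-px crops, 480 augmented training images;
see the methods vignette for the scaling rationale) trains both models and
reproduces the qualitative pattern in a few minutes on one CPU:

```r
library(foveanet)
cfg    <- experiment_config("desk")
models <- train_experiment_models(cfg, seed = 1)
run_scale_experiment(cfg, models, seed = 1)
```

```
   model target_size test_size accuracy d_prime
1    enn          30        30    1.000   4.200
2    enn          30       120    0.852   2.211
3    enn         120        30    0.852   2.635
4    enn          30       300    0.852   2.635
5    enn         300        30    0.833   2.531
6    cnn          30        30    1.000   4.200
7    cnn          30       120    0.611   0.570
8    cnn         120        30    0.685   0.999
9    cnn          30       300    0.556   0.456
10   cnn         300        30    0.685   0.966
```

Reading: with bit-identical target/test images (rows 1, 6) the optimal
threshold separates every pair, so accuracy is exactly 1.0 for any
non-degenerate model. Across a 4× size change (30′ ↔ 2°, rows 2–3 vs 7–8)
and even 10× (rows 4–5 vs 9–10) the scale-channel model stays ≈ 0.85 while
the single-scale control falls toward chance (0.5) — scale invariance for
*novel* glyphs comes from the architecture, not the augmented training.

```r
tr <- run_translation_experiment(cfg, models, seed = 1, cnn_sizes = c(30, 120))
tr$windows$enn_central$boundaries
#>   size boundary_ecc censored
#> 1   30        0.450    FALSE
#> 2   60        0.753    FALSE
#> 3  120        1.080    FALSE
tr$correlation
#>   eccentricity mean_correlation
#> 1            0           1.0000
#> 2            1           0.9557
#> 3            2           0.9373
#> 4            3           0.9394
```

Reading: the eccentricity at which one-shot accuracy drops below 0.85 grows
with letter size (0.45° for 30′ letters, 1.08° for 2° letters) — the
V-shaped window of invariance — and the raw same-glyph feature correlation
declines with eccentricity, so the effect is in the representation, not an
artefact of threshold selection.

## Command line

```sh
Rscript inst/cli/foveanet.R train         --profile desk --seed 1 --out out/
Rscript inst/cli/foveanet.R scale-exp     --profile desk --seed 1 --out out/
Rscript inst/cli/foveanet.R translate-exp --profile desk --seed 1 --out out/
Rscript inst/cli/foveanet.R report        --out out/
```

Outputs are CSV/JSON stamped with the config hash and seed; window heatmaps
are written as PNG when the graphics device is available.
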