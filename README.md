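# dfameter

Fully automated measurement of the **disc-fovea angle (DFA)** in color
fundus photographs. The DFA — the angle between the line from the optic
disc center to the foveal center and the horizontal through the disc
center — is the standard objective index of ocular torsion used in the
diagnosis of rotational strabismus. Manual measurement is slow and poorly
reproducible; `dfameter` replaces it with a segmentation-based pipeline:

1. **Segmentation** — a DeepLabv3+-style network (MobileNetV2 encoder of
   17 inverted-residual bottlenecks, ASPP, decoder with a low-level skip;
   U-Net and PSPNet baselines included) labels each pixel background /
   optic disc / *virtual macular area* (a disc of radius 400 px at native
   2584 × 1985 resolution centered on the fovea, scaled with image width).
2. **Geometry** — each structure is reduced to the largest 8-connected
   component of its class; its center is the center of the **minimum
   enclosing circle** (Welzl-style algorithm; a bounding-rectangle variant
   is provided).
3. **Angle** — with disc center $(OX, OY)$ and macular center $(MX, MY)$,

   $$\mathrm{DFA} = \arctan\!\big(|OY-MY| / |OX-MX|\big)\cdot 180/\pi,$$

   defined as 90° for a vertical pair and negated when $MY > OY$
   (image y grows downward).

Evaluation follows the standard segmentation suite — per-class IoU and
pixel accuracy, their unweighted means MIoU / MPA over all three classes,
Euclidean center errors DO / DM, and min/max/average summaries — plus the
7:3 train/test and 9:1 train/validation split protocol (682 images →
477/205 → 429/48 with floor arithmetic).

Everything runs on synthetic fundus images with exact ground truth from
the built-in generator (`make_dataset()`), since clinical datasets of this
kind are private. A pure-R + Rcpp CPU training engine (im2col + BLAS
convolutions, hand-derived backprop validated against finite differences)
makes the package self-contained — no deep-learning framework required.

## Worked example

```r
library(dfameter)

# 80 synthetic fundus images with known geometry, 128 x 128
ds <- make_dataset(80, width = 128, height = 128, seed = 11)

# train a quarter-width DeepLabv3+ on 64 of them (a few CPU-minutes)
fit <- fit_segmenter(ds$images[1:64], ds$masks[1:64], "deeplabv3plus",
                     input_size = 128, width_multiplier = 0.25,
                     epochs = 20, learning_rate = 1e-2, seed = 5)
print(fit)
#> Fundus segmentation model (deeplabv3plus)
#>   input 128 x 128, width multiplier 0.25, 3 classes
#>   382267 trainable parameters
#>   trained 20 epochs; best validation loss 0.0161 at epoch 12

# measure one unseen image
measure_image(ds$images[[70]], fit, true_dfa = ds$manifest$true_dfa_deg[70])
#>     id status disc_x disc_y macula_x macula_y dfa_pred dfa_true dfa_err
#> 1 <NA>     ok     38     66    77.74    63.82    3.134    2.936  0.1987

# full held-out evaluation: IoU/PA table, DFA and center-error summaries
ev <- evaluate_model(ds$images[65:80], ds$masks[65:80], fit,
                     ds$manifest[65:80, ])
print(ev)
#> DFA measurement evaluation
#>   images: 16 measurable, 0 unmeasurable
#>
#> DFA error (deg):
#>     min     max average
#>  0.0576  1.9720  0.5799
#>
#> Segmentation (fractions; multiply by 100 for %):
#>       class    iou     pa
#>  background 0.9943 0.9949
#>        disc 0.9336 0.9984
#>      macula 0.9543 0.9965
#>     average 0.9608 0.9966
#>
#> Center errors (px):
#>        min    max average
#> DO  0.0000 1.0572  0.3710
#> DM  0.3029 1.2564  0.5762
```

The desk-scale quarter-width model localizes both centers to about a
pixel, giving a held-out mean DFA error under one degree. An image whose
prediction lacks one of the structures is reported `unmeasurable` rather
than silently dropped.

The angle stage can also be exercised without any model — the end-to-end
oracle that bounds rasterization error:

```r
s <- make_scene(512, 512, dfa = -7.13, disc_fovea_distance = 200, seed = 7)
measure_from_mask(render_labels(s), true_dfa = s$true_dfa)$dfa_err
#> [1] 0
```

Here the error is exactly zero: the stored ground-truth angle is defined
on the grid-rounded centers, and the minimum enclosing circle of a
symmetrically rasterized region recovers those centers exactly. Across
100 random scenes the suite bounds this rasterization error at 0.3°.

A command-line front end with `synth` / `split` / `train` / `measure` /
`evaluate` subcommands lives at `inst/cli/dfa-meter.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dfa-meter.R", package="dfameter"))')" \
    synth --n 20 --width 256 --height 256 --seed 1 --out-dir data/
```

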