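# hdpress

Noise-resilient hyperdimensional-computing (HDC) classification of human
activity from a 32 x 16 resistive pressure mat.

Ambient pressure sensing is an unobtrusive way to recognize what a person is
doing at home — standing, walking, jumping, shifting weight, tiptoeing — from
nothing but a time series of pressure images. The classifiers that run on
such mats must be cheap enough for an embedded board and, more importantly,
robust: the data path is noisy end to end, from the acquisition (shifted or
rotated placement, blur), through the sensors (Gaussian and white noise), to
memory and radio links (dropped packets, bit errors in stored vectors).

`hdpress` implements a prototype-based HDC classifier built on *window-based
local encoding*. Every fully contained `w x w` window of a frame (defaults
`w = 8`, step `s = 3`; 27 windows on the 32 x 16 mat) is encoded by random
projection, `sign(B %*% F)`, bound to a bipolar position-ID hypervector, and
superposed; the frames of a 7-frame activity sequence are bound to temporal
ID vectors and superposed again:

    W         = sum_i sign(B F_i) * ID_i            (one frame)
    W_dynamic = sum_t W_frame_t   * ID_frame_t      (7-frame sequence)

Class prototypes `C_l = sum_{y_j = l} H_j` accumulate training encodings;
inference is nearest-prototype by cosine similarity
`argmax_j cos(H, C_j)`; mistake-driven retraining (default 20 online epochs)
adds each misclassified encoding to its true class and subtracts it from the
wrongly predicted one. The conventional whole-sample random-projection HDC
(`method = "flat"`, `D = 10000`) is included as the comparison baseline, and
the package ships the three noise families above, a seeded synthetic
pressure-mat generator standing in for the (request-only) kind of dataset
such systems are trained on, a sweep harness, model/dataset persistence, and
a command-line interface.

## Worked example

```r
library(hdpress)

cfg <- synth_config(n_per_class = 100, seed = 42)   # 7 classes, 80-20 split
d   <- generate_dataset(cfg)

fit <- hdc(d$train, method = "window", dim = 200, epochs = 20, seed = 42)
fit
#> Hyperdimensional-computing activity classifier
#>   encoding : window-based local (D = 200, w = 8, s = 3, 27 windows)
#>   classes  : jump, lr_shift, no_press, object, stand, tiptoe, walk
#>   trained  : 560 samples, 20 retraining epoch(s)
#>   training accuracy (last pass): 1.000

hdc_accuracy(fit, d$test)
#> [1] 0.9857143

# the flat whole-sample baseline at D = 10000 on the same data
flat <- hdc(d$train, method = "flat", dim = 10000, epochs = 20, seed = 42)
hdc_accuracy(flat, d$test)
#> [1] 0.9214286

# corrupt half of every stored class prototype (memory "packet loss")
noisy <- apply_noise(fit, noise_spec("packet_loss", 0.5, target = "prototypes",
                                     seed = 9))
hdc_accuracy(noisy, d$test)
#> [1] 0.9714286
```

The window-based model reaches 98.6% on the clean synthetic test set, stays
within 1.5 points of that when half of every prototype's elements are
zeroed, and outperforms the 50x-larger flat baseline on clean data. A
noise sweep compares both encoders across an intensity grid:

```r
sw <- noise_sweep("packet_loss", c(0, 0.25, 0.5), target = "prototypes",
                  cfg = cfg, dims = c(window = 200, flat = 200),
                  n_seeds = 3, seed = 1)
summary(sw)
#>       method intensity      mean          sd
#> 1   flat_hdc      0.00 0.9071429 0.028571429
#> 3   flat_hdc      0.25 0.8880952 0.035951593
#> 5   flat_hdc      0.50 0.8547619 0.033755826
#> 2 window_hdc      0.00 0.9857143 0.007142857
#> 4 window_hdc      0.25 0.9690476 0.025084890
#> 6 window_hdc      0.50 0.9476190 0.010910895
```

Each row is the mean and seed-to-seed spread of test accuracy for one
encoder at one corruption ratio, models trained clean (D matched at 200 so
the comparison isolates the encoding, not capacity).

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hdpress.R", package = "hdpress"))')
Rscript $CLI generate --classes stand,no_press --n-per-class 20 --seed 1 -o d.rds
Rscript $CLI train --data d.rds --dim 200 --epochs 20 --seed 1 -o model.rds
Rscript $CLI evaluate --model model.rds --data d.rds
Rscript $CLI sweep --config sweep.yaml --out-dir results/
```

`sweep` reads a YAML/JSON config (noise kind, intensity grid, dataset
parameters, seeds) and writes a tidy `sweep.csv`, a `sweep_summary.csv`, and
a `manifest.json`; two runs from the same config are bit-identical.

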