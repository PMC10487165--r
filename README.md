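# calospec

Multispectral food classification and caloric estimation in R.

Foods that look identical under visible light — sugared versus sugar-free
drinks, tofu versus milk pudding — differ in water, sugar and fat content,
and those constituents absorb near-infrared (NIR) and ultraviolet light
very differently from visible light. `calospec` implements a complete
pipeline for analysing food images captured under narrow-band LED
illumination (19 center wavelengths from 385 to 1020 nm plus one white/RGB
shot, 16-bit frames):

* **Feasibility statistics.** Masked brightness histograms compared by the
  Bhattacharyya distance
  `D_B(I_n, I_m | λ) = −log Σ_y √(p(y|I_n,λ) p(y|I_m,λ))`;
  the cumulative ratio
  `F_C(T_V, T_NV) = |{pairs: D_B^(V) < T_V ∧ D_B^(NV) > T_NV}| / |{pairs: D_B^(V) < T_V}|`
  of visually similar pairs that the non-visible bands separate (band
  representatives are band maxima of `D_B`); and per-wavelength Pearson
  correlations `ρ(λ)` between `D_B(·|λ)` and the absolute relative caloric
  difference `D_C(n,m) = |c_n − c_m| / (c_n + c_m)`, with a Fisher-z
  comparison of the visible and non-visible band means.
* **A compact CNN** (conv 11×11 → pool 4×4 → conv 7×7 → pool 4×4 →
  FC 112 → FC 128 → output) on 64×64 inputs, soft-max/cross-entropy for
  food-type classification and a linear output trained with the mean
  absolute percentage error (MAPE) for caloric regression; implemented in
  R (im2col + BLAS, Adam), fully seeded and reproducible.
* **Piecewise wavelength selection**: a wrapper search (forward selection,
  backward elimination, final forward selection, iterated to the full
  set) scoring each candidate wavelength set by the validation loss of a
  CNN trained on it, with per-cardinality optima, a full audit trace and
  selection-rate summaries by band.
* **A synthetic data generator** producing 16-bit multispectral stacks
  with planted structure — visually confusable class pairs separable only
  at one designated NIR channel, composition-driven calorie labels coupled
  to NIR reflectance, illumination jitter and sensor noise — so the whole
  pipeline is testable without the original acquisition rig.

The package ships the 101-item food table of the motivating study (name,
serving weight, calories; three items with missing calorie values) as its
only real-data fixture.

## Worked example

```r
library(calospec)

## the packaged food table
table_stats()
#> items: 101 (missing calorie: 3)
#> weight  (g):    mean 141.17  sd 60.69
#> calorie (kcal): mean 139.27  sd 101.36

## a synthetic dataset: 6 classes, 8 views, two confusable pairs that
## differ only at 890 nm
spec <- generator_spec(seed = 1)
stacks <- generate_stacks(spec, wavelengths = c("RGB", "890"))

## does the planted NIR channel help? RGB alone vs RGB + 890 nm
for (sel in list("RGB", c("RGB", "890"))) {
  ds <- assemble_dataset(stacks, sel, task = "classification")
  cfg <- cnn_config("classification", ds$n_classes, dim(ds$train$x)[3],
                    epochs = 30, conv1_filters = 8, conv2_filters = 16,
                    seed = 42)
  m <- train_cnn(build_model(cfg), ds$train, ds$val)
  print(evaluate_cnn(m, ds$val$x, ds$val$y))
}
#> classification: accuracy 66.67% over 6 classes
#> classification: accuracy 100.00% over 6 classes
```

The RGB-only network is stuck near its ceiling — the four paired classes
are pixel-identical in every visible channel, so at best it guesses within
each pair — while one added NIR image resolves them completely. The same
comparison for caloric regression (`task = "regression"`, 100 epochs)
drops the validation MAPE from 34.0% to 8.4% on this dataset. A
selection run recovers the planted channel as the first wavelength added
to RGB:

```r
wls <- c("RGB", "470", "560", "890", "950")
loss_fn <- make_cnn_loss(generate_stacks(spec, wavelengths = wls),
                         "classification",
                         selection_cnn_config("classification", epochs = 20),
                         seed = 1)
res <- run_selection(wls, loss_fn, include_rgb = TRUE, max_cardinality = 2)
res$steps$forward_added[1]
#> [1] "890"
```

A thin CLI over the same functions is installed at
`system.file("exec", "calospec-cli.R", package = "calospec")` with
subcommands `generate`, `feasibility`, `experiment`, `select` and
`table-stats`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/wavelengths.R`, `R/food_table.R`, `R/image_io.R` | domain types, the packaged food table, TIFF/manifest IO |
| `R/synthetic.R` | the synthetic multispectral generator |
| `R/spectral_stats.R` | histograms, Bhattacharyya distances, `F_C`, correlation profiles |
| `R/preprocessing.R` | intensity normalization, resizing, RGB splitting, input assembly |
| `R/cnn.R` | the CNN: configuration, training, MAPE, evaluation |
| `R/selection.R` | piecewise wavelength selection and selection-rate summaries |
| `R/pipeline.R` | experiment orchestration, CSV/JSON-lines artifacts |
| `vignettes/multispectral-food-analysis.Rmd` | methods, design decisions, limitations |

See the methods vignette for the model details, the generator's scope and
every numerical convention.
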