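# holocyte

Label-free identification of circulating tumour cells is a central
goal of liquid biopsy: rare cancer cells must be told apart from the
blood cells they resemble — monocytes above all — without staining.
Holographic flow cytometry records off-axis holograms of cells in
microfluidic flow and reconstructs quantitative phase maps (QPMs),
images of the optical path delay in radians, which carry morphometric
information that intensity imaging cannot access. `holocyte` is an R
package that implements this whole measurement-and-learning chain *in
silico*, for researchers who want a reproducible, ground-truthed test
bench for holographic cell classification pipelines:

1. **Synthetic scene** — two overlapping cell populations
   (ovarian-cancer-like "OC" and monocyte-like "MONO", unbalanced
   ~6.36:1) rendered as phase phantoms and turned into realistic
   off-axis holograms `I = |P_z[e^{iφ}]·e^{iA}·s + R|²` with random
   defocus, shared polynomial aberrations, correlated speckle and
   shot noise, plus a cell-free reference hologram.
2. **Reconstruction** — apodization, +1-order demodulation,
   reference-phase aberration compensation, autofocus by minimising
   the Tamura coefficient `sqrt(sd/mean)` of the amplitude,
   angular-spectrum refocusing, congruent least-squares phase
   unwrapping, adaptive denoising, segmentation and centred 384-px
   cropping.
3. **Descriptor** — 12 features per cell: area, eccentricity,
   perimeter (morphological); GLCM homogeneity, energy, entropy plus
   skewness and kurtosis (texture); max, min, mean, sd of the phase
   (QPI).
4. **Feature analysis** — Kendall tau-b correlation with significance,
   |tau| > 0.9 pruning, ReliefF ranking, PCA and t-SNE embeddings.
5. **Classification** — stratified 97.3/2.7 holdout, eight classical
   models (fine/medium/coarse tree, LDA, QDA, linear/quadratic/cubic
   SVM) under stratified 10-fold cross-validation, a feature-group
   ablation grid, and a compact from-scratch CNN built from
   inverted-residual bottleneck blocks, trained with 5-fold CV,
   10 epochs, batch 16, Adam at 1e-4, cross-entropy — on a pure-R
   network engine with analytically verified gradients.

## Worked example

```r
library(holocyte)

cfg <- run_config(
  scene = scene_config(frame_size_px = 256, class_counts = c(44, 7),
                       defocus_range_um = c(-35, 35),
                       frames_per_cell_range = c(1, 1)),
  crop_size = 192, test_fraction = 0.1, cv_folds = 5,
  models = c("fine_tree", "linear_discriminant", "linear_svm", "cubic_svm"),
  dl_config = train_config_dl(folds = 3, epochs = 2),
  dl_max_crops = 30, seed = 7)

rep <- run_pipeline(cfg)
print(rep)
#> run_report: 51 frames (51 cells), ratio 6.29
#>   reconstruction: 51 ok, 0 skipped
#>   pruned:
#>   cubic SVM (all features): val 97.8%, test 100.0%
#>   CNN: mean val 75.8%, test 80.0%
```

Reading the output: 51 holograms (44 OC cells, 7 monocytes, ratio
6.29) were rendered and all 51 reconstructed to phase crops; on this
small run the Kendall pruning found no redundant feature pair; the
cubic SVM reaches 97.8% cross-validated accuracy and classifies the
holdout frames perfectly, while the deliberately tiny 2-epoch,
30-crop CNN run lands at 76% — the default 10-epoch protocol on the
full N = 600 bench reaches ~90% cross-validated accuracy. Per-stage functions
(`generate_dataset()`, `reconstruct_qpm()`, `extract_features()`,
`kendall_matrix()`, `relief_rank()`, `ablation_study()`,
`train_dl()`, ...) expose every intermediate; a thin command-line
front end with per-stage subcommands lives at `inst/cli/holocyte`.

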