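# spermQPM

Quantitative phase microscopy (QPM) of human sperm cells, end to end and in
silico: simulation of off-axis digital holograms of sperm-shaped phase
objects under an oxidative-stress deformation, Fourier-method phase
reconstruction, morphological and texture feature extraction from the head
phase map, and SVM classification of control versus stressed cells.

Intended users are researchers in quantitative phase imaging and
computational andrology who need a tested, reproducible reference
implementation of this analysis chain — to validate reconstruction and
morphometry code against ground truth, to prototype classifiers, or to study
how optical and algorithmic choices propagate into cell-level statistics.

## The models

**Imaging.** An off-axis hologram records
`h(x,y) = a + b·cos[2π(f_x x + f_y y) + Δφ(x,y)]`, where `Δφ` is the cell's
phase delay and `(f_x, f_y)` the fringe carrier. One Fourier sideband equals
`c = (b/2)·e^{iΔφ}`; reconstruction selects it, recentres it to DC,
inverse-transforms, takes `Δφ = arctan(Im c / Re c)`, unwraps in 2-D
(reliability-ordered) and removes a polynomial background. In reflection
geometry, optical thickness is `OT = φ·λ/4π`.

**Morphometry** of the segmented head: maximum phase, peak OT, optical
volume `V = ∬ OT dx dy`, Monge surface area
`S = ∬ √(1 + G_x² + G_y²) dx dy` plus the projected area, the ratio `S/V`,
and sphericity `Ψ = 4.84·V^{2/3}/S` (1 for a sphere, → 0 for a laminar
disk).

**Texture** of the head phase distribution: population mean, variance,
excess kurtosis and skewness, 256-bin histogram entropy, and the angular
second moment (energy) of a 16-level gray-level co-occurrence matrix.

**Classification.** The eleven predictors feed a linear SVM (z-scored with
training statistics, stratified 60/40 split); the report carries the
confusion matrix, sensitivity/specificity/accuracy and the trapezoidal-AUC
ROC.

**Synthesis.** `make_phantom()` builds a parametric sperm phase object
(flat-topped acrosomal plateau, nucleus reaching 4 rad, thin midpiece,
45 µm undulating tail) band-limited by the instrument PSF;
`stress_transform()` applies a volume-conserving flattening with membrane
blebs and vacuoles that reproduces the reported direction pattern of
oxidative stress. Two illumination models (coherent/speckled and
pseudo-thermal) are calibrated to flat-region phase sensitivities near 300
and 20 mrad respectively. See `vignette("spermQPM-methods")` for the full
account.

## Worked example

```r
library(spermQPM)
cfg <- pipeline_config(out_dir = "demo_run", n_per_class = 10L, base_seed = 7L)
res <- run_all(cfg)   # simulate -> reconstruct -> features -> classify

dplyr::select(dplyr::slice_head(res$features, n = 3),
              cell_id, label, max_phase, S, V, sphericity)
#>   cell_id   label max_phase     S     V sphericity
#> 1 cell_0001     0      3.96  24.5 0.851      0.177
#> 2 cell_0002     0      3.85  27.3 0.902      0.166
#> 3 cell_0003     0      4.25  28.6 0.969      0.166

res$report
#> <classification_report>
#>   n = 8 test cells; confusion TP=3 FP=0 TN=4 FN=1
#>   sensitivity 75.00%, specificity 100.00%, accuracy 87.50%
#>   AUC 1.0000
```

The per-class medians show the stress signature: the maximum head phase
drops from 3.97 to 3.46 rad, the Monge surface area grows from 26.6 to
33.9 µm², and sphericity falls from 0.168 to 0.129, while the optical
volume stays constant — the flattening of stressed heads. Units: phases in
rad, `S` in µm², `V` in µm³ (optical volume), OT in nm.

Each result type plots with `autoplot()` (phase maps, holograms, ROC
curves) or `plot_feature_boxes()` (whisker-box plots across stress levels),
and the classification report supports broom-style `tidy()`/`glance()`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/spermqpm.R`
(`simulate | reconstruct | features | classify | run-all`).

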