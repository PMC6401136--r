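---
title: "Quantitative phase microscopy of sperm cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase microscopy of sperm cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

spermQPM simulates and analyses off-axis digital holographic microscopy
(DHM) of human spermatozoa under oxidative stress. This vignette explains
the models behind each stage, the parameters that matter, and the design
choices made where the underlying physics or published practice leaves the
implementation open.

## The imaging model

An off-axis hologram records the interference of an object beam carrying
the specimen's phase delay with a tilted reference beam:

$$h(x,y) = a(x,y) + b(x,y)\cos[2\pi(f_x x + f_y y) + \Delta\varphi(x,y)]$$

where $a$ is the background (DC) intensity, $b$ the fringe modulation, and
$(f_x, f_y)$ the spatial carrier frequency in cycles/pixel. The cell's phase
delay $\Delta\varphi$ rides on the carrier, so a single camera frame holds
the full complex field: rewriting the cosine as conjugate exponentials, one
spectral sideband is $c(x,y) = \tfrac{b}{2} e^{i\Delta\varphi}$.

Reconstruction (`reconstruct_phase()`) is the classical Fourier method:
2-D FFT, pick the strongest bin in the upper half-plane outside a DC guard
disk (0.05 cycles/pixel by default), window the sideband, shift it to DC
(removing the sub-bin carrier residual by spatial demodulation), inverse
FFT, take the four-quadrant angle, unwrap in 2-D, and remove a polynomial
background surface. In reflection geometry the beam traverses the specimen
twice, so optical thickness is $\mathrm{OT} = \varphi\lambda/4\pi$
(`phase_to_ot()`; $\varphi\lambda/2\pi$ in transmission). The default
wavelength is the HeNe line, 632.8 nm.

### Carrier and window defaults

Published descriptions of this step usually say only "numeric band-pass
filter". The filter has to pass the *instantaneous frequency* band of
$e^{i\varphi}$, which for a 4 rad head sampled at 0.1 µm/pixel extends to
roughly 0.07 cycles/pixel. Measured on noiseless phantoms, a Gaussian
window with $1/e$ radius at one third of the DC-to-carrier distance
(a common default) attenuates that band enough to bias the reconstructed
peak low by about a radian. The package therefore defaults to a **hard
window with radius 0.6 × the carrier distance** and a carrier of
(0.22, 0.22) cycles/pixel, which reconstructs the default phantom with
RMSE ≈ 0.01 rad and peak error < 0.01 rad; the Gaussian window remains
available (`window = "gaussian"`). The DC bin is zeroed before windowing so
the background delta cannot leak through a soft window's tail.

### Unwrapping and background removal

Unwrapping uses the reliability-ordered (second-difference) algorithm:
pixel pairs are joined most-reliable-first with 2π offsets propagated by
union-find. It is total (never fails), exact on wrap-free fields, and the
output is congruent with the input modulo 2π at every pixel. The map is
anchored so the histogram mode (the empty background) sits near zero.

Background removal fits a least-squares polynomial surface (order 2 by
default) to background pixels. Because the residual carrier tilt can dwarf
the object, the object mask is estimated *iteratively* when not supplied:
fit on all pixels, threshold the absolute median-filtered residual by Otsu,
refit on the background, three times. At least 20% of pixels must remain
background.

## The sperm phantom

`make_phantom()` composes a nonnegative ground-truth phase field in
cell-local coordinates:

* **acrosomal plateau** over the whole head ellipse (semi-axes 2.25 × 1.5
  µm), height 1.2 rad with a nearly flat top (radial exponent 0.1) — a
  healthy head is optically homogeneous;
* **nucleus**, the tallest structure, a flat-topped bump (semi-axes
  1.0 × 0.75 µm) on the posterior half, normalised so the field maximum
  equals the configured peak phase (4 rad by default, matching reported
  head peaks at 632.8 nm) exactly;
* **midpiece**, a thin tapered ridge (0.3 µm wide, 0.9 → 0.3 rad);
* **tail**, a 45 µm-long undulating ribbon of 0.3 rad (the WHO principal-
  piece length); the undulation chord is solved numerically so the
  centreline arc length matches the configured value to < 1%.

The composed field is band-limited by a Gaussian PSF (σ = 0.2 µm),
representing the microscope's resolution limit; the stored ground truth is
this band-limited field, since no instrument could deliver sharper.
Closed-form ground-truth features (peak phase, head phase volume, projected
area) are stored with each phantom. The default grid is 512 × 512 at
0.1 µm/pixel, consistent with high-NA imaging onto a modern sCMOS sensor;
absolute pixel pitch is not critical because all downstream quantities are
calibrated through `dx`, `dy`.

### The oxidative-stress deformation

`stress_transform(phantom, s)` with $s \in [0,1]$ models the documented
flattening of stressed heads so that the mean head phase falls by the
reported control-to-stressed ratio at $s = 1$:

1. the peak phase scales by $(1 - 0.115\,s)$ (0.115 calibrated from the
   reported control vs 10 µM mean-phase ratio 1.102/1.245 ≈ 0.885);
2. the acrosomal plateau thins by $(1 - 0.25\,s)$;
3. membrane damage adds **positively skewed, volume-neutral, band-limited
   roughness** ("blebs": exponentiated correlated Gaussian, amplitude
   0.65 s rad, correlation 0.9 µm, clipped at 2.5 sd so a bleb can never
   rival the nucleus peak), a **fine granularity** component (0.45 s rad at
   0.3 µm correlation, near the resolution limit), and **eight vacuole
   dips** (radius 0.35–0.5 µm) whose depth grows with $s$ but never cuts
   below ~half the local height;
4. the plateau's lateral extent is rescaled isotropically, the scale factor
   solved numerically so the head's integrated phase (optical volume) is
   conserved — flattening redistributes material, it does not remove it.
   The discrete plateau sum is not smooth enough in the lateral scale for a
   10⁻⁶ tolerance (rim pixels enter the support in near-steps), so the
   scale sets the geometry to ~10⁻⁴ and a final plateau-height trim factor
   (1 ± 5·10⁻⁴, in which the volume is exactly linear) closes the budget to
   better than 10⁻⁹.

Midpiece and tail are untouched. The net effect reproduces, through the
*full* hologram → reconstruction → segmentation → feature pipeline, the
direction pattern reported for real stressed cells: maximum phase and mean
fall, projected/Monge area rises, volume is conserved, sphericity falls,
variance falls, kurtosis and skewness rise (the peak becomes relatively
more extreme against a tighter bulk), entropy rises and co-occurrence
energy falls (the head becomes more heterogeneous). A purely self-similar
flattening (amplitude + lateral scale only) provably leaves all
scale-free statistics unchanged, which is why the deformation carries the
structural terms (2)–(3). Nucleus condensation is also available
(`stress_condense`) but defaults to 0: it empties the high-value histogram
tail and reverses the entropy direction.

### Illumination and noise

Two regimes are modelled (`illumination_model()`):

* **pseudo-thermal** (laser through a rotating diffuser): speckle-free;
  i.i.d. Gaussian intensity noise, σ_I = 11.5 counts by default —
  calibrated so the reconstructed flat-region phase std is ≈ 20 mrad, the
  sensitivity reported for such sources;
* **coherent** (direct laser): the object beam is multiplied by a complex
  exponentiated correlated Gaussian speckle field (contrast 0.43,
  correlation 3 px) and a low-frequency parasitic fringe rides on the
  background; calibrated to ≈ 290–295 mrad flat-region std, near the
  reported 300 mrad. A *real* speckle factor would leave the reconstructed
  phase untouched (a positive factor does not change $\arg c$), so the
  physical complex field is essential.

Both presets are calibrations and documented as such; `illum_noiseless()`
disables all noise for fidelity checks.

## Morphometry and texture

The head is segmented by an Otsu threshold on the 3×3 median-filtered
phase. The threshold is computed on a log scale (`log(phase + 0.1)`):
the cell fills well under 1% of the field, and under that imbalance a
linear-scale Otsu drifts into the object and truncates the head. A
morphological opening (disk radius 2 px) detaches midpiece and tail, and
the largest connected component (ties broken by higher mean phase) within
plausibility bounds is kept. Against ground truth this yields
intersection-over-union ≈ 0.95.

From the OT map (nm, converted to µm for gradients) the package computes:
optical volume $V = \sum \mathrm{OT}\,dx\,dy$ (µm³), the Monge surface
area $S = \sum dx\,dy\sqrt{1 + G_x^2 + G_y^2}$ *plus* the projected area
(so a flat patch has $S = 2A$), their ratio, and sphericity
$\Psi = 4.84\,V^{2/3}/S$, which is 1.00 for a sphere and → 0 for a laminar
disk. Gradients are estimated per pixel as the larger-magnitude of the
forward and backward differences: at steep rims central differences halve
the slope and understate a discretized hemisphere's area by ~7%, while the
one-sided maximum recovers $3\pi r^2$ to well under 2%. Volume is
reported in µm³ — the only choice that makes $\Psi$ dimensionless — and is
an *optical* volume: without independent refractive-index knowledge, OT
and geometric height cannot be separated, so all "volumes" here are OT
integrals, exactly as in the quantities being emulated.

Texture statistics on the masked phase samples use the *population* (1/N)
moment definitions with excess kurtosis, Shannon entropy of a 256-bin
equal-width histogram over the sample min–max, and the angular second
moment (energy) of a 16-level symmetric normalized gray-level
co-occurrence matrix at offset (0, 1), computed on the mask's bounding box.
Level 0 is reserved for out-of-mask pixels (in-mask values quantize to
levels 1–15 over the masked min–max, so the darkest cell pixels are never
conflated with empty background), and only pixel pairs lying entirely
inside the mask are counted: background–background pairs otherwise reduce
the statistic to the bounding box's fill ratio, a property of the mask
geometry rather than of the head's texture. The co-occurrence reading of
the energy formula's double subscript is a deliberate interpretation — the
printed formula does not define $p_{ij}$ — and the level count and offset
are configurable.

## Classification

The eleven predictors (peak OT, $S$, $V$, $S/V$, $\Psi$, mean, variance,
entropy, kurtosis, skewness, energy) feed a support vector machine:
stratified 60/40 split, predictors z-scored with training statistics only,
linear kernel with cost 1 by default (the smallest assumption where the
kernel is unspecified; RBF available). The decision score is oriented so
positive means stressed; sensitivity, specificity and accuracy are
reported at score threshold 0, the ROC is traced over all distinct scores,
and AUC is the trapezoidal integral — identical to the normalized
Mann–Whitney U statistic, which the test suite verifies by brute-force
pair counting.

## What the simulations do and do not show

The generator emulates: carrier-encoded interference with realistic count
levels, band-limited optics, two noise regimes calibrated to reported
sensitivities, biological size/phase jitter (5% CV), and a volume-
conserving stress deformation matching the reported direction pattern. It
does **not** model diffraction propagation or defocus, partially coherent
transfer functions, motile (video) cells, refractive-index tomography, or
the biological diversity of real semen (debris, agglutination, abnormal
forms). Passing tests therefore demonstrate the *analysis chain* is
correct and that the classifier separates classes whose differences match
the documented effect directions — not that any particular real-data
accuracy would be achieved.

## Numerical choices and problem sizes

* Volume conservation is solved with Brent's method on the lateral scale
  (tolerance 10⁻¹¹), with the nucleus height re-normalised on the full
  grid afterwards; conservation holds to ~10⁻⁸ relative.
* Border pixels (16 px) are excluded from all fidelity metrics (filter
  edge effects).
* The test suite uses 256-px phantoms for unit tests and the full 512-px
  default for fidelity and population checks; population statistics use
  20 phantoms per stress level at five levels, and classifier null checks
  use 2000 scores per class. The strongest stress effects (peak phase,
  mean, variance, area, sphericity) separate cleanly at these sizes; the
  entropy and energy shifts are the smallest effects and their medians,
  while reproducibly ordered at 20 cells per level, overlap substantially
  cell by cell.
* All randomness derives from explicit integer seeds through a
  counter-based per-cell derivation, so datasets and reports are
  bit-reproducible.

## Known limitations

* The IoU of automatic segmentation is measured against the phantom's own
  band-limited support (geometric ellipse + half a PSF sigma); against the
  bare geometric ellipse the halo of the band-limited field costs a few
  points of IoU by construction.
* Measured optical volume sits ~1–2% below the phantom's stored head
  phase volume: the rim annulus below the segmentation threshold is not
  counted. The deficit is self-similar across stress levels, so
  volume-conservation comparisons remain valid.
* Sub-bin carrier estimation uses a 3×3 centroid; the residual tilt
  (≲ 10⁻³ cycles/pixel) is absorbed by the polynomial background fit.
* With heads much larger than ~6 µm or peaks far above ~6 rad the object
  band approaches the sideband window and fidelity degrades; the window
  fraction and carrier are configurable for such regimes.
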