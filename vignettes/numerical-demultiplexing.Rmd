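---
title: "Numerical demultiplexing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical demultiplexing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdemux)
```

## The problem

An ordinary color camera records three numbers per pixel — the red, green and
blue channel intensities behind a Bayer color filter array — while the light
arriving at that pixel has a full spectral distribution. Many applications
(material classification, vegetation and skin imaging, microscopy) want that
distribution, or at least a usable estimate of it, at every pixel and in a
single exposure. `specdemux` implements a numerical route to this: model the
sensor well enough that the mapping from spectra to RGB can be simulated, then
learn an inverse of that mapping from simulated data.

## The forward model

Everything rests on a linear measurement model. Spectra are discretized on a
uniform wavelength grid of $n$ points (default 61 points, 410–710 nm in 5 nm
steps, chosen to cover the visible response of an RGB sensor at the step size
a narrowband characterization sweep naturally produces). With $S$ the
$p \times n$ matrix of per-channel spectral sensitivities and
$\Lambda \in [0,1]^n$ the (radiance) spectrum arriving at a pixel,

$$ C = S\,\Lambda, \qquad C \in \mathbb{R}^p . $$

When the scene is a reflective target, $\Lambda = R \cdot E$ element-wise,
with $R$ the reflectance and $E$ the illuminant. The simulation experiments
work directly in reflectance (equivalently, $E \equiv 1$), matching how real
measured spectra are reduced to reflectance by *detrending*: dividing by the
spectrum measured off a white reference of known reflectance (0.99 by
default), which cancels the illuminant. `detrend_by_illuminant()` implements
exactly that quotient.

Assumptions worth stating:

* **Linearity.** Sensor responses are treated as linear in intensity (no
  gamma, no saturation). Image I/O maps k-bit codes to $[0,1]$ by dividing by
  $2^k - 1$ and applies no transfer curve.
* **One sensitivity per channel.** The per-pixel sensitivity of a real
  sensor is collapsed to one curve per color channel; a narrowband
  characterization that uniformly illuminates a large sensor region and
  averages pixels per filter justifies this.
* **No mosaic.** Every simulated pixel carries all $p$ channels (the
  post-demosaic view); demosaicing itself is out of scope.
* **Unit-intensity sweep convention.** `characterize_from_narrowband()`
  assumes the narrowband probe light has unit intensity at every wavelength,
  so the mean response at $\lambda_k$ *is* column $k$ of $S$. Real sweeps
  would need per-wavelength exposure normalization; that normalization is the
  caller's responsibility. Negative mean responses (noise artifacts) are
  clipped to zero because physical sensitivities are nonnegative.

## Sensor sensitivity: synthetic and characterized

Real cameras publish no sensitivity matrices, so the package ships a
parametric stand-in: `synth_sensitivity()` builds a Gaussian filter bank,
channel $c$ responding as
$a_c \exp\!\left(-(\lambda - \mu_c)^2 / 2\sigma_c^2\right)$. The defaults
(blue 460 nm / green 530 nm / red 600 nm, widths 35 nm, peak amplitudes
0.8 / 1.0 / 0.9) give the qualitative shape of consumer RGB sensors: green
peaks highest, strong overlap between neighboring channels. These are
synthetic curves, not measurements of any particular camera; absolute
reconstruction quality depends on them, method *comparisons* are insensitive
to modest changes in them.

```{r sensitivity}
S <- synth_sensitivity()
sens_channels(S)
```

`characterize_from_narrowband()` is the measured-data route: feed it a table
of per-channel responses to a narrowband sweep and it returns the estimated
$S$. On noise-free responses generated by the forward model itself the
round trip is exact to machine precision (the unit test asserts this), which
pins down the convention consistency between the two functions.

## The demultiplexers

The inverse problem — recover $\Lambda \in \mathbb{R}^{61}$ from
$C \in \mathbb{R}^3$ — is severely underdetermined, so every inverse is a
statistical estimator shaped by the population of spectra it was trained on.
Three are provided:

* **WEM** — classical Wiener estimation. With training spectra as columns of
  $A$ and $C = SA$ their simulated measurements, the estimator is the linear
  map $W = (A C^{\mathsf T})(C C^{\mathsf T} + \varepsilon I)^{-1}$:
  cross-correlation times inverse auto-correlation, non-centered moments, the
  standard convention in Wiener spectral estimation. WEM is trained on a
  small fixed prior — `wem_prior_spectra()`, 24 broad smooth synthetic
  spectra emulating color-chart patches.
* **DEMUX-WEM** — identical mathematics, but trained on a large population
  (default 10,000 spectra) drawn from the package's generator and pushed
  through the characterized forward model. The only difference from WEM is
  the training set, which isolates the value of forward-model-based training.
* **DEMUX-RFM** — a random-forest regression from measurements to spectra,
  the package's primary non-linear inverse.

Numerical choices for the Wiener solve: when `ridge_eps = NULL` the ridge
defaults to $10^{-8}\,\mathrm{tr}(CC^{\mathsf T})$, which rescales with the
data and keeps degenerate training sets (e.g. all-identical spectra)
solvable; `ridge_eps = 0` requests the exact solve and raises a
singular-matrix error if the auto-correlation's reciprocal condition number
falls below $10^{-12}$. In the square, invertible limit $p = n$ the
unregularized estimator reduces algebraically to $S^{-1}$, and the tests
verify that limit to $10^{-8}$.

### The forest

The forest is grown jointly over all outputs: each split maximizes the
variance reduction summed across the $n$ wavelengths, and each leaf predicts
the mean training *spectrum* of its samples. This keeps reconstructions
spectrally coherent — one tree cannot predict wavelength 550 from one
neighborhood of measurement space and wavelength 555 from another — and it
is why the joint mode outperforms independent per-wavelength forests at equal
total tree count (the package also offers `mode = "per_wavelength"`, backed
by ranger, which doubles as an independent implementation for cross-checking;
the two agree on toy problems by construction of the target function).
The joint trees are implemented in compiled code with a portable per-tree
random stream, so a fixed seed gives bit-identical forests across platforms.

Hyperparameters the ensemble needs but standard practice fixes: unlimited
depth, minimum leaf size 1, bootstrap resampling with replacement, and all
$p$ features tried at every split ($p = 3$ is too small for feature
subsampling to help). `n_trees` counts trees in the whole ensemble; the
full-scale default is 8,000, and reduced-scale runs use a few hundred.

All demultiplexed spectra are clipped to $[0,1]$ — physical reflectance
bounds — after prediction; `clip = FALSE` exposes the raw linear output.

## The synthetic spectra generator

`generate_random_spectra()` draws each spectrum as a flat baseline plus
1–3 Gaussian bumps (count uniform, centers uniform over the grid, widths
20–80 nm, amplitudes 0.2–1.0, baseline 0–0.2), clipped to $[0,1]$. The
design goals: smooth unimodal/bimodal shapes typical of diffuse reflectance;
every wavelength well represented across a large population (the tests check
the per-wavelength mean of a 10,000-spectrum population stays inside
[0.1, 0.9] and that every wavelength sees values on both sides of 0.5); and
deterministic output for a fixed seed. Clipping rather than renormalizing
keeps bump geometry interpretable.

What it does **not** emulate: sharp absorption or emission lines, spectral
signatures of specific materials, correlated noise, or fluorescence. Passing
tests therefore demonstrate the machinery and the method ordering under a
smooth-spectra prior, not performance on arbitrary real scenes.

`make_test_icon()` is the spatial counterpart: a block layout of uniform
sections, each carrying one distinct 1–2-bump spectrum, mirroring a printed
test chart imaged by the sensor.

## Experiments and evaluation

Fidelity is scored with PSNR, $10 \log_{10}(\text{peak}^2/\text{MSE})$, with
peak fixed at 1.0 (full-scale normalized reflectance) — absolute dB values
depend on this choice, so it is worth stating prominently. Aggregation over a
test population defaults to *pooled* MSE (pool squared errors over all
spectra and wavelengths, then take the ratio): a handful of exact
reconstructions would make a mean of per-spectrum PSNRs infinite, while the
pooled form is infinite only if every reconstruction is exact. A
`per_spectrum` mode (averaging finite per-spectrum PSNRs) is available.

`run_simulation_experiment()` trains all three methods and scores them on a
disjoint test population; `run_icon_experiment()` renders the icon through
the forward model, reconstructs a spectral cube per method, and scores each
section's mean predicted spectrum. Both harnesses demand explicit seeds,
warn if training and test seeds coincide (leakage guard), and are
deterministic end to end: identical configs give byte-identical JSON reports.

```{r experiment}
cfg <- simulation_config(n_train = 500, n_test = 100, n_trees = 60,
                         train_seed = 1, test_seed = 2)
run_simulation_experiment(cfg)
```

The package's own test battery runs the experiment at a reduced scale —
2,000 training spectra, 500 test spectra, 300 trees — which preserves the
qualitative result of interest (DEMUX-RFM > DEMUX-WEM > WEM in pooled PSNR)
while keeping a full run in seconds. The acceptance script
(`scripts/acceptance.R`) re-runs exactly this scale.

## Known limitations

* **Bump-center localization is information-limited.** Three overlapping
  channel responses do not pin down the center of a single Gaussian bump
  when its width, amplitude and baseline are also unknown: distinct
  parameter combinations produce identical RGB triples, and the confusion
  worsens toward the red end of the grid where all three synthetic channel
  sensitivities decay. Reconstructions from any estimator — forest or Wiener
  — localize the peak of a held-out unimodal spectrum only coarsely. The
  test suite keeps a strict ±10 nm localization check precisely to document
  this limit; the forest does not meet it, and that is a property of the
  measurement geometry, not of the implementation.
* Absolute PSNR values depend on the synthetic sensitivity curves and the
  generator's spectra distribution; only method orderings and the exact
  algebraic limits are stable quantities.
* Shot (signal-dependent) noise, optics, color management and demosaicing
  are all out of scope; measurement noise is additive Gaussian only.
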