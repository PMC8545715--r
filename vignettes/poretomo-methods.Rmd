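---
title: "Methods: pore-structure and multifractal analysis of microtomography volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore-structure and multifractal analysis of microtomography volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretomo)
```

## The problem

Biochar produced from pelletized softwood is a porous carbon whose
micrometer-scale pore system — elongated voids between compressed wood
fragments, plus remnants of tracheid lumina — controls water transport,
gas exchange and microbial habitability when the material is used as a soil
amendment or biofilter medium. Synchrotron phase-contrast X-ray
microtomography resolves this pore system in 3D at sub-micrometer voxel
size (0.87 µm here). `poretomo` implements the downstream analysis chain:
binarization of the reconstructed volume, pore-network metrics, per-axis
pore frequency curves, and 1D multifractal analysis used to test two
structural hypotheses — *homogeneity* (no multi-scale clustering of
porosity) and *isotropy* (no preferred direction), which distinguish
pelletized char from raw wood char with its strongly axial tracheid
structure.

Tomographic reconstruction itself (filtered back-projection, ring-artifact
removal, phase retrieval) is out of scope: the pipeline starts from a
reconstructed grayscale volume.

## Segmentation chain

1. **Quantize**: intensities are multiplied by a scale factor (default
   100,000) and rounded half-away-from-zero to 16-bit signed integers,
   clipped to $[-32768, 32767]$. The rounding rule is a documented choice;
   the convention upstream only says "converted".
2. **Threshold**: voxels with quantized value strictly greater than 8 are
   solid, all others pore. *Polarity* is an interpretation: the retained
   above-threshold phase is taken to be the solid matrix, consistent with
   denser carbon being brighter after phase retrieval. Both the threshold
   and polarity are configurable.
3. **Largest solid component**: only the largest 26-connected group of
   solid voxels is kept (isolated solid specks become pore). Ties are
   broken toward the component containing the earliest voxel in array scan
   order — deterministic and documented. Pore voxels are never modified.
4. **Centered ROI**: a cube (1024³ at production scale) is cropped from the
   center; an odd remainder puts the cube `floor(remainder/2)` voxels from
   the origin.

At 0.87 µm voxels a 1024³ ROI is $\approx 0.707\ \mathrm{mm}^3$.

## Pore-network metrics

Pores are connected components of the pore phase (26-neighborhood by
default; 6 selectable, and reported in output metadata).

* **Total porosity** counts only pores of $\ge$ 4 voxels, divided by the
  ROI voxel count — components below the minimum size are unreliable at
  the scan resolution. Frequency curves (below) deliberately use *all*
  pore voxels; this asymmetry is intentional and mirrors the reference
  workflow.
* **Largest-pore fraction** (largest pore volume / total pore volume, no
  size filter) is the connectivity indicator: values near 1 mean a single
  percolating network.
* **Surface area** is the bwperim-style 3D perimeter: the number of pore
  voxels with at least one face-adjacent non-pore neighbor (the volume
  boundary counts as non-pore). **SA/V** divides this count by the pore's
  voxel count. Note a property established by brute force in the tests:
  for digitized balls this boundary-*voxel* count sits a stable
  $\sim 20\%$ *below* the continuum $3/r$ (each surface voxel is counted
  once no matter how many faces it exposes). The sphere-equivalent
  baseline $3/r$, $r = (3V/4\pi)^{1/3}$, is the continuum formula in voxel
  units, as conventionally reported.
* **Unit conversions**: `physical_volume()` (voxels → mm³) and
  `equivalent_cube_width()` ($V^{1/3} \times$ voxel edge, µm); a 43-voxel
  pore at 0.87 µm is $\approx 3$ µm wide, the cutoff used to summarize
  isolated small pores.

## Frequency curves and multifractal analysis

For each axis of the ROI the pore voxels in every perpendicular slice are
counted, giving a 1D measure of length $L$ (1024 at production scale). The
curve is dyadically partitioned into $2^k$ contiguous bins of relative
size $\varepsilon = 2^{-k}$, $k = 1,\dots,10$, and normalized to bin
probabilities $\mu_i(\varepsilon)$.

With partition sums $Z(q,\varepsilon) = \sum_i \mu_i^q$ over non-empty
bins and the direct-method weights
$\mu_i(q) = \mu_i^q / Z(q,\varepsilon)$, ordinary least squares over
$\log \varepsilon$ gives, for each moment order $q \in \{-9,\dots,9\}$:

$$\alpha_q = \text{slope of } \sum_i \mu_i(q)\,\log \mu_i(\varepsilon), \qquad
  f_q = \text{slope of } \sum_i \mu_i(q)\,\log \mu_i(q),$$

$$D_q = \frac{1}{q-1}\,\text{slope of } \log Z(q,\varepsilon)
  \quad (q \ne 1), \qquad
  D_1 = \text{slope of } \sum_i \mu_i \log \mu_i .$$

Estimates carry the OLS slope standard error and $R^2$; an estimate is
*accepted* only if $R^2 \ge 0.9$ (configurable). A monofractal measure has
a point-like $f(\alpha)$ spectrum at $(1, 1)$ and a flat Rényi spectrum
$D_q \equiv D_0$; multifractality shows up as spectrum width
$\Delta\alpha = \alpha_{\max} - \alpha_{\min}$ and as $D_0 - D_2 > 0$.

### Numerical choices

* **$\varepsilon$ convention**: dimensionless $\varepsilon = 2^{-k}$.
  Slopes against $\log \varepsilon$ are invariant to the constant offset
  $\log L$, so this matches the "$\varepsilon = 2^{-k} L$" convention
  exactly for all reported quantities.
* **Empty bins** are excluded from all sums. For $q < 0$, where
  $\mu^q \to \infty$ as $\mu \to 0$, any level containing an empty bin is
  dropped from that $q$'s regression entirely; fewer than 3 surviving
  levels is an estimation failure (the q is rejected, or an error when the
  estimator is called directly).
* **$q = 1$** uses the entropy (L'Hôpital) forms.
* **Non-power-of-two lengths** are truncated to the largest centered
  $2^m \le L$ window, with a warning. Curve construction itself accepts
  any length $\ge 2$.
* **Descriptors** ($\alpha_0$, $\alpha_{\min}$, $\alpha_{\max}$,
  $\Delta\alpha$, asymmetry $A = (\alpha_0-\alpha_{\min})/(\alpha_{\max}-\alpha_0)$,
  $D_0, D_1, D_2$, $D_0-D_2$, $D_{q\min}-D_{q\max}$) are computed from
  *accepted* q values only; rejected q are listed alongside. $A$ is
  reported as `NaN` when $\alpha_{\max}-\alpha_0 < 10^{-9}$ (point
  spectrum).

### Validation against analytic spectra

The estimators are validated on binomial multiplicative cascades, whose
spectrum is known in closed form:
$D_q = -\log_2(p^q + (1-p)^q)/(q-1)$,
$\alpha_q = -(p^q \log_2 p + (1-p)^q \log_2(1-p))/(p^q+(1-p)^q)$,
$f_q = q\alpha_q - (q-1)D_q$. On exact depth-10 cascades the regression
recovers these to floating-point accuracy, because the scaling is exactly
geometric:

```{r cascade}
sp <- run_multifractal(generate_binomial_cascade(0.7, 10), q_grid = -3:3)
round(cbind(est = sp$table$D, true = cascade_true_spectrum(0.7, -3:3)$D), 4)
```

A subtlety the tests document: *shuffling* the cascade's bins preserves
the weight distribution but destroys the dyadic nesting, and the estimate
collapses toward the homogeneous value 1. That is the correct behavior —
the method measures spatial scaling, not the value histogram — and is
exactly what the optional seeded shuffle is for. A claim that the shuffled
measure should still return the cascade's $\alpha_{\min}$ would be wrong,
and is deliberately not asserted.

## The synthetic-phantom world

No raw beamline volumes are redistributable, so all volumetric tests run
on phantoms:

* **`fragment_pack`** deposits overlapping solid ellipsoids (random
  centers, Haar-random orientations, semi-axes uniform in 0.5–1.5 × half
  the nominal fragment size, default 16 voxels ≈ 14 µm — the scale of
  milled-wood fragment features) until the solid fraction reaches
  $1 - $ target porosity (default 0.577, the porosity regime of
  softwood-pellet char). The stopping rule controls porosity to about
  ±0.02. The result is approximately isotropic by construction.
* **`tube_array`** pierces a solid block with parallel cylindrical pores
  on a regular grid — an idealized tracheid bundle and the anisotropy
  contrast case: per-slice pore counts are exactly constant along the tube
  axis and fluctuate across it.
* **Binomial cascades** provide 1D measures with known spectra (above).

What the phantoms do *not* emulate: the real material's spatial
correlation structure (which is only described qualitatively), pore wall
roughness, reconstruction artifacts, or the full 1024³ scale. Test volumes
are 128³ or smaller, so per-slice porosity fluctuates more than in the
production-scale data: measured over seeds, fragment-phantom slice
porosity spans roughly 0.40–0.83 around the 0.577 mean, wider than the
0.51–0.67 reported for real 1024³ scans. A green phantom test therefore
establishes the *code's* behavior (detection of anisotropy, monofractal
spectra for homogeneous media, porosity control), not agreement with any
particular specimen.

All random draws flow through one explicit seed per operation; global RNG
state is saved and restored, and fixed seeds make phantoms and rendered
volumes bit-reproducible.

## Pipeline verdicts

`run_pipeline()` chains the stages and emits per-sample artifacts plus a
manifest holding every parameter and seed (a rerun from the manifest is
bit-identical). The cross-axis summary calls a sample *homogeneous* when
every axis' $\Delta\alpha < 0.15$ and *isotropic* when the maximum
pairwise absolute difference of $\{\Delta\alpha,\ D_0-D_2,\
D_{q\min}-D_{q\max}\}$ across axes is $< 0.1$. Both thresholds are tool
settings, not statistical tests (the underlying comparison is
descriptive).

A design choice made here: the asymmetry $A$ is *reported* but excluded
from the isotropy verdict. As a ratio of two spectrum-width differences it
is ill-conditioned exactly in the regime of interest — when the spectrum
degenerates toward a point, tiny absolute fluctuations flip $A$ by O(1).
Empirically, isotropic 128³ fragment phantoms give per-axis $A$ anywhere
in 0.5–1.8 while all other descriptors agree to within 0.02; thresholding
$A$ at 0.1 would misclassify genuinely isotropic media.

## Known limitations

* The TIFF codec is deliberately minimal: uncompressed, single-sample
  grayscale, 8-bit unsigned / 16-bit signed / 32-bit float, multipage or
  one-file-per-slice. That covers the stacks tomography pipelines
  exchange; compressed or RGB TIFFs are rejected with a format error.
* Threshold polarity (which phase is above the threshold) is an
  interpretation of the upstream convention; it is configurable and the
  default is documented above.
* Perimeter counting is boundary-voxel based (see the ball calibration
  above); exposed-face counting would give systematically larger surface
  areas.
* The multifractal analysis is strictly 1D along each axis — no 2D/3D
  box counting, wavelet leaders, or lacunarity.
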