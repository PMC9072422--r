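---
title: "Mapping ON/OFF domains and receptive-field structure in mouse V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ON/OFF domains and receptive-field structure in mouse V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In carnivores and primates, thalamic afferents to primary visual cortex
segregate by their preference for luminance increments (ON) or decrements
(OFF), producing columnar ON/OFF domains that are thought to scaffold the
emergence of orientation maps. `onoffdomains` implements the full analysis
needed to ask the same question in mouse V1 from sparse-noise two-photon
data, together with a simulator that generates populations whose answer is
known by construction:

1. Does the cortical surface contain regions where ON- or OFF-dominated
   cells cluster (ON/OFF domains)?
2. Do those domains mirror biases in the distribution of ON/OFF
   receptive-field centers on the visual field, as a *biased-input* account
   predicts?
3. Does the local balance of ON/OFF signals shape the two-dimensional
   structure of simple-cell receptive fields?

## Pipeline and model assumptions

**Kernel estimation.** For each neuron the ON kernel at delay $t$ is the
average activity $t$ microscope frames after onsets of stimuli that had a
bright tile at each location; analogously for OFF with dark tiles
(`estimate_kernels()`). Kernels are raw event-triggered averages — no
smoothing. The norm curve $S(t) = \lVert K(t)\rVert / \lVert K(0)\rVert$
(Frobenius norm) is anchored at the pre-response map at onset, and the peak
delay is its argmax (ties toward the smaller delay). A polarity is
*significant* when $\max_t S(t) > 5$ and a two-dimensional elliptical
Gaussian fit at the peak delay explains at least half of the map variance.
Cells with one significant polarity are mono-contrast ON or OFF; cells with
both are split at a normalized distance of one half — center separation
divided by the average Gaussian width — into simple ($> 0.5$) and complex
($\le 0.5$). Cells with no significant kernel are excluded downstream.

Because the standard form of this rule does not pin down every numerical
detail, the
package makes these choices and records them here: the Gaussian fit includes
rotation and a constant offset, is initialized from image moments (with a
second start at the brightest tile) and bounded so the center stays within
one tile of the grid; "average standard deviation" means the mean of each
fit's two principal widths, averaged across the two fits; when
$\lVert K(0)\rVert$ is exactly zero (possible only in noiseless simulation)
a machine-epsilon-scaled floor replaces it and the stack is flagged.

**Domain mapping.** Densities of ON and OFF cells are Gaussian kernel
density estimates, $f(x) = \frac{1}{n}\sum_i G_\sigma(x - x_i)$, with no
edge correction; the fluctuation map is $f_{\mathrm{on}} - f_{\mathrm{off}}$
(`fluctuation_map()`). Pointwise significance comes from label-shuffle
Monte Carlo (positions fixed, ON/OFF labels permuted with group sizes
preserved); with the default 1000 shuffles and $\alpha = 0.001$ the
envelopes are the min/max order statistics, and significance is pointwise by
design — no family-wise correction, matching the level-set construction.
Two implementation details matter for exactness: pooled points are put in a
canonical order and each shuffle assigns the *smaller* group from the front
of a fresh permutation, so exchanging the ON and OFF inputs negates the map
and swaps the significance masks exactly (for equal group sizes antithetic
complement pairs achieve the same); and domain polygons are traced through
the outermost flagged grid nodes (marching squares on the mask at a level
just below one), so a polygon's area corresponds to the flagged-node
footprint rather than extending half a node beyond it. Bandwidths follow
the experimental convention: $\sigma = 30\ \mu m$ in native cortical space
and $\sigma = 0.25$ in canonical space (the $0.9\,n^{-1/5}$ rule of thumb at
$n \approx 500$). Default grids are 10 µm spacing over the
$900 \times 540\ \mu m$ field padded by $2\sigma$, and 0.05 spacing over
$[-2.5, 2.5]^2$.

**Canonical alignment.** Cortical positions $(x_1, x_2, x_3)$ and
receptive-field centers $(y_1, y_2)$ of mono-contrast cells are aligned by
canonical correlation analysis with the row-vector convention
$\hat{x} = (x - \bar{x})A$, $\hat{y} = (y - \bar{y})B$; canonical variables
have unit sample variance, cross-pairs are uncorrelated, and
$\rho_1 \ge \rho_2 \ge 0$ with signs fixed by making each cortical
projection's largest loading positive. Depth is included so the first
projection can compensate for a slight tilt of the objective relative to
the cortical surface. Dual-polarity cells are excluded from this stage by
default (they contribute two centers); `map_correlation()` then correlates
the ON$-$OFF fluctuation maps in canonical cortical and canonical visual
space over the full $[-2.5, 2.5]^2$ grid and derives its p-value from a
joint label-shuffle null in which both maps are recomputed per shuffle.

**Receptive-field structure.** The signed receptive field of a simple cell
is its ON kernel minus its OFF kernel at their peak delays. The
neighborhood model (`nnls_fit()`) expresses it as a non-negative linear
combination of the receptive fields of the k nearest mono-contrast ON and k
nearest OFF cells (k per polarity, 3-D cortical distance, ties by cell id;
a 2-D and a pooled-2k variant sit behind flags). ON neighbor maps enter
the design with positive sign and OFF maps with negative sign, so
non-negative weights assemble an ON$-$OFF field; the solver is
Lawson–Hanson active-set NNLS. No spatial normalization is applied to
neighbor maps — weights absorb scale. `sweep_k()` reports the smallest k
whose median fit correlation is within $\varepsilon = 0.02$ (default) of
the best over the range.

One caveat is worth stating: `neighbor_distance_comparison()` pools the k
neighbor distances of every target cell before the rank-sum test, exactly
as the original construction does. Distances from one target share its
local density fluctuation, so the pooled samples are dependent and the
rank-sum p-value is anti-conservative; it is a descriptive contrast, not a
calibrated test.

## The synthetic population generator

`make_bias_field()` builds the ON/OFF imbalance $b(y) \in [-1, 1]$ as a sum
of randomly placed signed Gaussian bumps (defaults: 6 bumps, amplitude 0.5,
length scale 25 deg) clipped to $[-1, 1]$. ON receptive-field centers are
drawn from a density proportional to $1 + b$, OFF centers from $1 - b$,
over a uniform base — the bias field is the *only* spatial structure, which
isolates the mechanism under study. An affine retinotopy (6.25 and
8.44 µm/deg) maps centers onto a $900 \times 540\ \mu m$ field; cells
scatter around their mapped position with SD 45 µm (ON) and 30 µm (OFF),
encoding the observation that ON cells have larger retinotopic scatter, and
depth is drawn from optical planes every 30 µm between 150 and 360 µm.

Mono-contrast cells carry one Gaussian subregion (width 8 deg — one tile —
jittered ±15%). Simple cells are non-negative combinations of up to three
nearby ON and three nearby OFF mono-contrast receptive fields with sparse
Dirichlet(0.3) weights; components are required to have co-clustered
centers (within one subregion width of the seed component) so each subunit
stays single-lobed, and a draw is accepted only when the generating ON and
OFF centroids are separated by more than 0.5 normalized distance. Complex
cells get co-centered ON and OFF Gaussians. Because composites are built
from the same mono-contrast pool the estimator sees, the NNLS stage has an
exactly recoverable generative truth.

The stimulus follows the standard protocol: an 18 × 8 tile grid (tiles
8 × 8 deg), each tile independently bright with probability 0.1, dark with
0.1, gray otherwise; 166 ms flashes at 1/s; 1500 presentations in a 25-min
session; microscope frame rate 15.6 Hz. The ensemble stores one frame per
flashed image plus onset frame indices, since kernels are indexed by delay
from onset. Responses are linear–nonlinear Poisson: the drive is the
rectified inner product of the ON map with bright tiles plus the OFF map
with dark tiles (complex cells: sum of the two rectified subunit drives),
events are Poisson with rate baseline $+$ gain × drive placed five frames
after onset, and all other frames carry Poisson background. The response
nonlinearity of cortical cells is a modeling choice, not an empirical
claim. Defaults — gain 2 events per unit drive, baseline 0.12 events/frame
(≈ 1.9 events/s of spontaneous activity, a plausible rate for deconvolved
GCaMP6s events) — were chosen so the median peak normalized norm of
significant cells is ≈ 10, i.e. comfortably above the significance
threshold of 5 but far from noiseless; under these conditions about 95% of
cells recover their generating class.

What the generator does **not** emulate: eye movements, running-state
modulation, calcium-indicator dynamics and deconvolution artifacts,
correlated (shared) noise across neurons, orientation tuning within
subregions, and any dependence of cell class on depth beyond none at all
(classes are depth-independent, i.e. perfectly columnar). Passing tests on
this ground truth therefore show that the estimators are correct and
calibrated under the stated statistical structure, not that real data meet
that structure.

## Numerical and statistical choices

* Permutation p-values are computed as $(1 + \#\{\text{null} \ge
  \text{obs}\}) / (N + 1)$, so they are never zero; `map_correlation()`
  uses the two-sided $|r|$ version, `split_half_columnarity()` the
  one-sided (greater) version.
* When the shuffle count cannot resolve the requested $\alpha$
  ($N < 1/\alpha$), $\alpha$ is clamped to $1/N$ with a warning.
* "Kernel SNR" in the recovery analyses means map-energy SNR — the
  Frobenius norm of the signal over that of the added noise.
* Tiles never flashed in an ensemble are imputed as 0 in kernels, with a
  warning; a cell whose delay-0 map is identically zero is flagged rather
  than dropped silently.
* The Gaussian-fit optimizer (L-BFGS-B, two starts) can in principle fail;
  a failed fit reports `variance_explained = 0`, which simply makes that
  polarity non-significant.
* Domain areas use the shoelace formula on marching-squares contours;
  halving the grid spacing changes areas by well under 10%.

## Problem sizes used by the test-suite and acceptance analyses

Simulation sizes are scaled to what the statistics require rather than to
the full experimental scale: classification recovery uses populations of a
few hundred cells at 1500 presentations; calibration loops use 50–100
seeds with 200 shuffles (the smallest count that resolves the clamped
$\alpha$); biased-input recovery uses 20 seeds of 820-cell populations
with 299 shuffles on a 0.1-spaced canonical grid. The defaults in
`default_config()` remain the full-scale settings (1000 shuffles,
$\alpha = 0.001$, 0.05 canonical spacing).

## Known limitations

* The pointwise min/max envelope at $\alpha = 0.001$ with 1000 shuffles is
  the extreme order statistic; its Monte-Carlo variability is larger than
  at interior quantiles.
* KDE mass is not edge-corrected, so densities are biased low near the
  imaged-field border; difference maps inherit this but symmetrically in
  the two polarities.
* CCA is linear; a curved retinotopy would leak into lower canonical
  correlations rather than being absorbed.
* The neighborhood model's weights are a statistical decomposition, not
  synaptic measurements; sparsity statements (n90) describe the fit, not
  connectivity.

## A minimal run

```{r, eval = FALSE}
library(onoffdomains)
man <- run_pipeline(default_config(master_seed = 1))
print(man)
plot(man$fluctuation)        # ON - OFF density with significance contours
man$cca                      # canonical correlations of the alignment
man$map_correlation$pearson_r
```
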