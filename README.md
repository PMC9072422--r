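# onoffdomains

Analysis of ON/OFF domains and receptive-field structure in mouse primary
visual cortex (V1) from sparse-noise two-photon imaging, with a
synthetic-population simulator that provides ground truth for every stage.

## The problem

In higher mammals, thalamic inputs to V1 segregate by their preference for
luminance increments (ON) or decrements (OFF), creating columnar ON/OFF
domains that may scaffold orientation maps. This package implements the
complete analysis chain needed to test, in mouse V1:

1. whether the cortical surface is parceled into ON/OFF domains — regions
   where the local density of ON cells significantly exceeds that of OFF
   cells or vice versa;
2. the **biased-input** prediction that these domains mirror fluctuations in
   the density of ON/OFF receptive-field centers on the visual field,
   carried into the cortex by an accurate retinotopy; and
3. whether the local balance of ON/OFF signals shapes simple-cell
   receptive-field structure.

## The methods at its core

* **Kernels.** For each neuron, the ON kernel at delay *t* is the
  event-triggered average response *t* frames after onsets of stimuli with a
  bright tile at each grid location (OFF: dark tiles). A polarity is
  significant when the normalized norm curve
  S(t) = ‖K(t)‖/‖K(0)‖ peaks above 5 and a 2-D Gaussian fit at the peak
  delay explains ≥ 50% of the variance. Cells are classified ON, OFF, or —
  when both polarities are significant — simple vs complex at a normalized
  center distance of one half.
* **Domains.** Kernel density estimates f_on, f_off
  (f(x) = (1/n) Σᵢ G_σ(x − xᵢ), σ = 30 µm cortical / 0.25 canonical); the
  fluctuation map f_on − f_off is thresholded by pointwise label-shuffle
  Monte-Carlo envelopes (1000 shuffles, α = 0.001) and the significant level
  sets become domain polygons with areas.
* **Alignment.** Canonical correlation analysis x̂ = (x − x̄)A,
  ŷ = (y − ȳ)B between 3-D cortical positions and 2-D receptive-field
  centers; the correlation between the canonical cortical and canonical
  visual fluctuation maps, with a joint label-shuffle null, tests the
  biased-input prediction.
* **Receptive-field structure.** Simple-cell RFs (ON − OFF kernel
  difference) are decomposed as non-negative combinations of the k nearest
  ON and OFF mono-contrast neighbors (active-set NNLS), with neighborhood
  sweeps, weight-sparsity summaries (n90) and ON/OFF neighbor-distance
  contrasts.

The simulator generates populations with a known smooth ON/OFF bias field
over the visual field, an affine retinotopy with polarity-specific scatter,
composite simple cells with sparse non-negative weights, the 10/10/80%
ternary sparse-noise protocol (18 × 8 tiles, 1500 presentations, 15.6 Hz),
and linear–nonlinear Poisson responses — so every estimator can be checked
against generative truth.

## Worked example

```r
library(onoffdomains)
cfg <- default_config(n_on = 120, n_off = 240, n_simple = 40, n_complex = 40,
                      n_shuffles = 500, master_seed = 7)
man <- run_pipeline(cfg)
print(man)
```

```
Pipeline run
  cells: 440 (COMPLEX 36, OFF 240, ON 120, SIMPLE 44)
  domains: 5 polygons; CCA rho = 0.991/0.968; map r = 0.883 (p = 0.00399)
  neighborhood model: median fit r = 0.737 over 44 simple cells
```

Reading the output: of 440 simulated cells, the classifier recovers the
mono-contrast groups and most dual-polarity cells (36 + 44 vs the 40 + 40
generated). Five significant ON/OFF domain polygons are found in native
cortical space. The CCA alignment is tight (ρ₁ = 0.99, ρ₂ = 0.97, as it
should be for an affine retinotopy with moderate scatter), and the
canonical cortical and visual fluctuation maps correlate at r = 0.88 with
shuffle p ≈ 0.004 — the biased-input signature. The neighborhood model
reconstructs simple-cell RFs from ~5 ON and OFF neighbors with a median fit
correlation of 0.74.

The packaged per-dataset summary of the thirteen published imaging volumes
pools to:

```r
population_composition(v1_dataset_summary())
#> Population composition (n = 24342):
#>   ON 6540 (27%), OFF 13372 (55%), ON+OFF 4430 (18%)
#>   within ON+OFF: 45.3% simple, 54.7% complex
```

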