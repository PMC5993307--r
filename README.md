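# hbflux

Finite-state transition analysis of the co-varying hemoglobin signal.

Resting-state near-infrared measurements of tissue yield, per voxel, two
concentration time series — the deviations of oxyhemoglobin (ΔO) and
deoxyhemoglobin (ΔD) from their temporal means — together with three
dependent components: total hemoglobin ΔT = ΔD + ΔO, the
tissue-oxygen-exchange surrogate ΔE = ΔD − ΔO, and the oxygen-saturation
deviation ΔS. The zero lines of the five components divide the (ΔD, ΔO)
plane into ten sectors, each a unique realizable permutation of the five
algebraic signs (the saturation line lies at tan⁻¹(S₀/(100−S₀)) from the
ΔD axis, ≈ 80° for S₀ = 85 %). Every voxel-time sample occupies exactly
one of these **Hb states**, and a voxel's trajectory becomes a symbol
sequence whose transitions carry the signal of vascular feedback
regulation.

`hbflux` implements the full analysis chain for researchers working with
functional NIRS or diffuse optical tomography time series:

* **state assignment** from ΔD/ΔO matrices (`assign_state_series()`),
  with linear detrending (`linear_detrend()`) and delimited-text I/O;
* **variable-dwell-time transition counting** (`accumulate_transitions()`,
  in C++): a transition is declared whenever the label changes, and the
  dwell preceding it is recorded, so no fixed Markov lag is imposed;
* **transition coefficients** per ordered state pair: probability
  P (off-diagonal cells sum to 100), mean dwell lag τ, rate constant
  k = 1/τ (s⁻¹), per-component intrinsic flux φ_X, transition mass
  m_X = P·φ_X, rate-weighted products k·φ_X and k·m_X, pre/post
  transition amplitudes, Ohm-analogy voltages V = k/P, and
  reciprocal-pair asymmetries;
* **occupancy statistics**: state volume fractions and the first-order
  kinetic prediction V = K·diag(Pᵀτ), with their mean relative percent
  discrepancy as a model check;
* **map comparison**: nRMSD, Pearson correlation and a t-score index
  over the 90 off-diagonal cells, plus the mass-action regression of
  flux on amplitude differences;
* **diagnostics**: laterality-corrected inter-breast Z metrics,
  cell-wise pooled t-test maps, and rank-sum ROC/AUC maps;
* a **semi-Markov synthetic-data generator** (geometric dwells, sector
  amplitude clouds, bilateral cohorts with a configurable disease
  effect) so every estimator is testable without external data.

## Worked example

```r
library(hbflux)

cfg  <- hb_sim_config(seed = 1)          # 50 voxels x 540 frames at 1.8 Hz
b    <- simulate_breast(cfg)
maps <- transition_coefficients(b$dD, b$dO, cfg$geometry)

summary(off_diagonal(maps$k))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9857  1.2254  1.3342  1.3542  1.4824  1.6777

V <- volume_fractions(maps$states)
round(V, 2)
#>     1     2     3     4     5     6     7     8     9    10
#>  8.57  8.41  9.17  9.38  9.46  9.92 10.19 11.41 11.63 11.86

model_discrepancy(V, predicted_volume_fractions(maps$P, maps$tau))
#> [1] 0.000957226
```

The rate constants span ~1.0–1.7 s⁻¹ (the reciprocal mean dwells times
the 1.8-Hz sampling rate); the volume fractions sum to 100 % and agree
with the first-order kinetic prediction to well under a tenth of a
percent on this generator, whose dwells are geometric by construction.

A command-line interface wraps the same functions
(`inst/cli/hbflux.R`): subcommands `simulate`, `assign`, `coefficients`,
`compare` and `diagnose`, each accepting `--config` (YAML/JSON),
`--seed` and `--log-level`.

```sh
Rscript inst/cli/hbflux.R simulate --out cohort_dir --seed 1
Rscript inst/cli/hbflux.R coefficients --dd cohort_dir/S001_left_dD.csv \
    --do cohort_dir/S001_left_dO.csv --out maps_dir
```

## Vignette

`vignettes/hb-state-flux.Rmd` documents the model and its assumptions,
the generator's defaults and what they emulate, the numerical
conventions (boundary handling, missing cells, saturation
linearization), and known limitations.
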