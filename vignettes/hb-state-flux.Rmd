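---
title: "Finite-state transition analysis of the co-varying hemoglobin signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-state transition analysis of the co-varying hemoglobin signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbflux)
```

## The model

Near-infrared measurements of tissue deliver two independent time-varying
quantities per voxel: the deviations of oxyhemoglobin ($\Delta O$) and
deoxyhemoglobin ($\Delta D$) concentration from their temporal means.
Three further components co-vary with them deterministically: total
hemoglobin $\Delta T = \Delta D + \Delta O$ (blood volume), the
tissue-oxygen-exchange surrogate $\Delta E = \Delta D - \Delta O$, and
the oxygen-saturation deviation $\Delta S$. Under resting-state
conditions each component fluctuates about zero, so its *algebraic sign*
is a natural binary reduction of the signal.

The zero sets of the five components are five straight lines through the
origin of the $(\Delta D, \Delta O)$ plane. The saturation line is
inclined at $\tan^{-1}\!\big(S_0/(100 - S_0)\big)$ from the $\Delta D$
axis, where $S_0$ is the mean tissue oxygen saturation in percent
(`demarcation_angle(85)` $\approx 80^\circ$). The five lines partition
the plane into ten angular sectors; each sector is an **Hb state**
carrying a unique realizable permutation of the five signs — only 10 of
the $2^5 = 32$ conceivable permutations are geometrically possible
(`enumerate_realizable_states()` verifies this by brute-force sweep).
Every voxel-time sample therefore occupies exactly one state, and a
voxel's trajectory becomes a symbol sequence on a ten-letter alphabet.

### Transition counting with variable dwell times

Rather than fixing a lag (as a true finite Markov chain would), a
transition is declared whenever the state label changes. Per voxel the
scan starts at frame $t$; the lag $n$ grows while the label is
unchanged, and at the first differing frame a transition of type
$(i \to f)$ with dwell $n$ is recorded, after which the post-transition
frame becomes the new pre-transition frame. Runs reaching the end of the
series are discarded. The counts land in a $10 \times 10 \times N$
accumulator (row = final state, column = initial state, layer = dwell).
From it the package derives, per ordered state pair:

* **Transition probability** $P_{fi}$: lag-summed counts normalized so
  the 90 off-diagonal cells sum to exactly 100, making subjects with
  different recording lengths comparable;
* **Mean dwell lag** $\tau_{fi}$ (frames) and **rate constant**
  $k_{fi} = 1/\tau_{fi}$, reported in s$^{-1}$ by multiplying by the
  sampling rate;
* **Intrinsic flux** $\varphi_X(f,i)$: the mean change of component
  $X \in \{O,D,T,E,S\}$ per transition of that type;
* **Transition mass** $m_X = P \varphi_X$ and the rate-weighted products
  $k\varphi_X$, $k m_X$ (per-unit-time versions);
* **Pre/post mean amplitudes**, whose difference reconstructs
  $\varphi_X$ exactly (a telescoping identity the tests enforce at
  $10^{-12}$ relative tolerance);
* **Ohm-analogy voltages** $V = k/P$ (and $k\varphi_X/P$), treating $k$
  as a conductance and $P$ as a current.

Because a component whose sign differs between the initial and final
state *must* move in a fixed direction, the flux maps have forced-sign
regions (`flux_sign_regions()`); these hold on any input and are part of
the test suite.

### Occupancy and the first-order check

The volume fraction $V_j$ is the percentage of defined voxel-time
samples in state $j$. If transitions behave as first-order processes,
occupancy must equal dwell-weighted outflow:
$V_j = K \sum_i P_{ij}\tau_{ij}$ with $K$ normalizing the sum to 100
(equivalently $V = K\,\mathrm{diag}(P^\top \tau)$). The package computes
both the observed and model-predicted fractions and their mean relative
percent discrepancy; on synthetic first-order data the discrepancy
shrinks with series length and is far below 2 % at
$50 \times 10^5$ samples.

### Group comparison and diagnostics

Per-subject maps are computed per breast; group maps are unweighted
cell-wise means. Two maps are compared over their 90 off-diagonal cells
by nRMSD,
$\sqrt{\sum(\alpha-\beta)^2 / [(\sum\alpha^2 + \sum\beta^2)/2]}$
(0 iff equal, at most 2), and Pearson correlation; a t-score index
standardizes a tumor-pairing value against the three control pairings.
The laterality-corrected inter-breast metric
$Z = 100\,(Y^l - Y^r)/Y^r$ (with the swapped, bias-corrected form for
right-sided tumors) feeds cell-wise Student t-tests (pooled variance)
and rank-sum ROC/AUC maps with midrank tie handling.

## The synthetic generator

No public data accompany this methodology, so the package ships a
semi-Markov generator that makes every estimator testable end to end.
Per voxel an embedded jump chain selects successive distinct states and
dwells in each for a geometrically distributed number of frames — the
discrete-time analogue of first-order kinetics, matching the assumption
the volume-fraction model tests. Amplitudes are then drawn per sample:
a direction uniform within the state's sector (inset by 1 % of the
sector width so state assignment round-trips exactly despite float
rounding) and a radius with Gaussian noise (redrawn while
non-positive).

Default conditions, chosen once as a realistic resting-state breast
recording:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 1.8 Hz | instrument frame rate |
| frames | 540 | 5 minutes of recording |
| voxels | 50 | desk-scale stand-in for a reconstructed volume |
| dwell means | 1.1–1.6 frames | matches observed rate constants of ~1.2–1.75 s$^{-1}$ |
| jump matrix | $\propto e^{-d/2}$ in circular sector distance | transitions favour adjacent states |
| amplitude radius / noise | 2 µM / 0.5 µM | micromolar resting-state fluctuations |
| cohort | 18 cancer (12 left, 6 right) + 45 non-cancer | study design |
| disease effect | dwell ×0.8, amplitude ×1.5 | elevated rates and amplitudes in the tumor breast |

What the generator does **not** emulate: spatial correlation between
voxels, tomographic blurring, physiological oscillations (cardiac,
respiratory, vasomotor), history-dependent dwell distributions, and
measurement noise that moves samples across sector boundaries. Passing
tests therefore demonstrate the estimators' correctness and internal
consistency, not that real tissue obeys the first-order model — on real
data that is an empirical finding, not a guarantee.

## Numerical and design choices

* **Boundary convention.** Sector membership bins the direction angle
  `atan2(dO, dD)` into half-open arcs $[\text{lower}, \text{upper})$
  anchored at the five boundary angles. Samples exactly on a line (a
  measure-zero event for real data) get a deterministic label, and each
  point maps to exactly one of the ten states. The origin has no
  direction and maps to the sentinel 0, excluded from all counting.
* **Saturation linearization.** $\Delta S$ defaults to the first-order
  form $(100/T_0)(\Delta O - (S_0/100)\,\Delta T)$, whose zero set is
  the straight demarcation line of the sector geometry; the exact ratio
  form is available via `saturation_mode = "exact"` for amplitude
  studies (it errors when $T_0 + \Delta T \le 0$).
* **Geometry validity.** The canonical state labels assume the
  physiological regime $S_0 > 50\,\%$, where the saturation line falls
  between the $\Delta E = 0$ and $\Delta D = 0$ lines. At exactly
  $S_0 = 50$ the saturation and exchange lines coincide and only eight
  sectors exist; below 50 the ten sectors carry a different sign-pattern
  set. The package accepts any $S_0 \in (0, 100)$ but documents the
  labels as canonical only above 50.
* **Lag depth.** The accumulator allocates
  $N = \max(60, \text{longest counted dwell})$, so long dwells on
  synthetic inputs are never silently dropped.
* **Missing cells.** Transition types never observed yield missing (not
  zero) $\tau$, $k$, $\varphi$; similarity indices, regressions and
  group means drop missing cells pairwise, since zero-imputation would
  bias every ratio-based coefficient.
* **nRMSD radical.** The index includes the square root — the closed
  form $\beta = -\alpha \Rightarrow \mathrm{nRMSD} = 2$ and its
  scale-invariance hold only with it.
* **Mass-action regression.** When flux and pre/post amplitudes come
  from a single accumulator, $\varphi = \text{post} - \text{pre}$ holds
  exactly and the regression is the identity (slope 1, $r = 1$). Slopes
  below 1 can only arise when the three inputs are averaged
  independently — e.g. group-mean maps across subjects — so
  `mass_action_regression()` takes its three maps as independent
  arguments rather than deriving them from one accumulator.
* **t-test choice.** Cell-wise group comparisons use the Student
  (pooled-variance) two-sample test, not Welch; its type-I error at
  $\alpha = 0.05$ is verified at $0.05 \pm 0.01$ over $10^4$ null
  replicates.
* **AUC orientation.** The cancer group is the positive class; the
  stored map holds the raw oriented value, with
  `fold = TRUE` offering $\max(\mathrm{AUC}, 100 - \mathrm{AUC})$ since
  fold-orientation conventions vary between reports.
* **Seeding.** Cohort simulation derives one seed per subject-breast
  stream from the global seed via a counter
  ($\text{seed} + 7919\,c \bmod 2^{31}-1$), so outputs do not depend on
  generation order.

## A worked example

```{r example, eval = FALSE}
library(hbflux)

cfg <- hb_sim_config(seed = 1)          # 50 voxels x 540 frames at 1.8 Hz
b <- simulate_breast(cfg)
maps <- transition_coefficients(b$dD, b$dO, cfg$geometry)

summary(off_diagonal(maps$k))           # rate constants, s^-1
V <- volume_fractions(maps$states)
pred <- predicted_volume_fractions(maps$P, maps$tau)
model_discrepancy(V, pred)              # mean relative percent discrepancy
```

Problem sizes used by the checks: the run-length oracle comparison uses
1,000 random sequences; parameter recovery 200 voxels × 2,000 frames;
the first-order model check 50 voxels × 100,000 frames; the null-AUC
and type-I-error calibrations a full 18 + 45-subject cohort at
30 voxels × 300 frames and $10^4$ null replicates. These sizes make the
Monte-Carlo error small relative to each tolerance while keeping a
default run quick.

## Limitations

The method reduces a continuous bivariate signal to ten symbols;
amplitude information within a sector enters only through the flux and
amplitude maps, and any distance-from-origin refinement of the state
definition is deliberately out of scope. Estimates in rarely-visited
cells are noisy, and the diagnostic maps inherit the usual caveats of
per-cell univariate testing (no multiplicity correction is applied, by
design). The generator's independence across voxels means spatially
clustered disease effects are not represented.
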