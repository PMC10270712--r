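---
title: "Edge-centric information decay: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric information decay: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgefid)
```

## The problem

Cortical regions differ systematically in how long their activity retains
information: sensory regions operate on fast intrinsic timescales,
associative regions on slow ones, producing the familiar spatial gradient
of nodal timescales. `edgefid` moves this question from nodes to *edges*:
for every pair of regions it asks how long information persists in their
joint co-activation, and whether that edge-level persistence is explained
by the two nodes alone or reflects genuinely nonlocal (inter-regional)
dynamics.

The pipeline has five stages:

1. **Edge co-activation signals.** For regions $i, j$ with signals
   $X_i(t), X_j(t)$ inside one epoch, the edge time series is
   $E_{ij}(t) = z(X_i)(t) \cdot z(X_j)(t)$, the element-wise product of
   the z-scored signals. With the population ($1/T$) normalization used
   here, $\frac{1}{T}\sum_t E_{ij}(t)$ is exactly the Pearson correlation
   of $X_i$ and $X_j$ — the edge series unfolds static functional
   connectivity over time. (Some texts print "variance" in the z-score
   denominator; the Pearson-average identity forces the standard
   deviation, which is what `zscore()` uses.)
2. **Auto-mutual information (AMI) profiles.** For each signal (edge or
   node) the AMI at delay $\tau$ is the mutual information
   $I(X(t); X(t-\tau)) = H(X) + H(Y) - H(X,Y)$ estimated by the plug-in
   histogram method from a $64 \times 64$ contingency table, in bits. The
   profile starts at the binned entropy ($\tau = 0$) and decays toward a
   noise floor.
3. **Decay time $\tau^*$.** The last 80 of 128 profile points are fitted
   with a straight line; the *stable minimum* is the mean fitted tail
   level, and the threshold adds one standard deviation of the tail
   residuals. $\tau^*$ is the smallest delay whose AMI falls at or below
   this threshold. At 256 Hz one delay step is $1000/256 = 3.90625$ ms.
4. **FID matrix.** Decay times are standardized across edges within each
   trial (population SD), then averaged across trials into the
   region-by-region functional information decay matrix. Its fastest and
   slowest tails define the short- and long-storage subnetworks (SSN,
   LSN; default tail fraction 10%).
5. **Null models and trial classification.** Three nulls isolate what the
   edge decays add beyond nodal properties, and each trial's distance
   from its regional null (1 minus the Spearman correlation of the edge
   decay patterns) defines a *nonlocality* score.

## Null models

- **Gaussian spectral surrogates** (`gaussian_surrogate`): per region,
  white Gaussian noise is given the parent's amplitude spectrum. Nodal
  spectra (hence nodal autocorrelation) survive; every cross-regional
  relationship is destroyed.
- **Phase-randomized surrogates** (`phase_surrogate`): one phase per
  positive frequency, uniform on $[0, 2\pi)$, applied *identically* to
  every region (conjugate-mirrored; DC and Nyquist untouched). Because a
  shared rotation cancels in every cross-product
  $X_i(f)\overline{X_j(f)}$, the full cross-spectrum is preserved — so
  not only the static correlation matrix but all stationary (circular)
  lagged cross-correlations are reproduced exactly. What the surrogate
  destroys is the *nonstationary* structure: the temporal organization of
  the co-activation signal itself (e.g. the autocorrelation of
  $E_{ij}(t)$ changes, and with it the edge AMI decay). This is a
  stronger statement than "zero-lag is preserved", and the test suite
  asserts it in this form.
- **Regional null** (`regional_null_fid`): the best purely local
  prediction of an edge decay, the geometric mean
  $\tau_{ij} = \sqrt{\tau_i \tau_j}$ of the two nodal decay times
  estimated with the same AMI machinery.

The *deviation* of a trial is the null minus the empirical standardized
decays (`deviation_sign = -1` flips it). Under this convention an edge
that is slower than its local prediction has a negative deviation; the
convention is exposed rather than hidden because the literature is not
consistent about the sign.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bins` | 64 | — | A stable histogram estimate for ~2560-sample epochs; the $64\times64$ table has ~0.6 samples/cell, giving a large but *delay-stable* plug-in bias that the tail fit absorbs. |
| `max_delay` | 127 | samples | 128 delays ≈ 500 ms at 256 Hz; empirical decays occur well inside this range. |
| `tail_points` | 80 | samples | The last 80 points estimate the noise floor; decay transients live in the first ~48. |
| `k_sd` | 1.0 | SD units | Threshold width above the fitted stable minimum. |
| `sd_mode` | `"residual"` | — | "One standard deviation from the stable minimum" is read as the SD of tail residuals about the fitted line; `"raw"` (SD of tail values) is provided as a switch. |
| `tail_fraction` | 0.10 | proportion | SSN/LSN tail size; reported with results since no canonical value exists. |
| `extreme_fraction` | 0.10 | proportion | Standard/inverse gradient label cutoff. |
| `fs`, `epoch_duration` | 256 Hz, 10 s | | The sampling regime the analysis targets. |

Numerical conventions worth knowing:

- Binning uses equal-width bins over each variable's own observed range,
  index $\lfloor (v - \min) \cdot b / (\max - \min) \rfloor$ clamped to
  the top bin. The compiled batch path and the R reference
  implementation use the *same* arithmetic, so they agree to the last
  bit; empty cells contribute $0 \log 0 = 0$.
- The crossing search runs over all delays $\tau \ge 1$ including the
  tail; the smallest crossing wins. If nothing crosses (possible only
  for pathological thresholds) the result is flagged at `max_delay`.
- $\tau^*$ is invariant under positive rescaling of the AMI values, so
  the choice of bits over nats is cosmetic.
- Constant signals are refused with errors naming the region and epoch
  (z-scoring) or produce MI 0 with a warning (`histogram_mi`).

## The synthetic generator

No public dataset accompanies this analysis style at source level, so
`generate_dataset()` produces epoched multiregion data with known ground
truth. Each region is an AR(1) process (discretized Ornstein–Uhlenbeck),
$x_i(t) = \phi_i x_i(t-1) + \varepsilon_i(t)$, whose closed-form
timescale $-1/\ln\phi_i$ makes parameter recovery testable. A linear
gradient of $\phi$ across regions (default $0.3 \to 0.95$ over 78
regions) emulates the cortical timescale gradient. Dynamic coupling is a
lagged linear influence $x_i(t) \mathrel{+}= c\, x_j(t - d)$ (default lag
$d = 2$ samples), active only in configured epochs and pairs. Each epoch
discards a 500-sample burn-in and is band-pass filtered with a
zero-phase 4th-order Butterworth (0.5–48 Hz), matching the band the
analysis assumes; `bandpass = NULL` yields the raw AR(1) processes.

What the generator emulates: nodal timescale gradients, band-limited
spectra, epoch structure, switchable nonlocal interactions with ground
truth. What it does not: 1/f spectra, oscillatory peaks, nonstationarity
within an epoch, volume conduction (the toy leakage module handles that
separately), and any anatomical geometry. Passing tests therefore
demonstrate estimator correctness and sensitivity under controlled
conditions, not performance on real recordings.

### Design of the coupled condition

Two coupling motifs behave very differently, and the packaged "nonlocal
epoch" condition uses both deliberately:

- **Reciprocal pairs** ($i \leftrightarrow j$, both directions at lag 2)
  create a genuinely relational resonance whose timescale belongs to the
  pair. They are the strongest driver of the trial-level nonlocality
  score. Stability requires $c^2 < (1-\phi_i)(1-\phi_j)$; at $c = 0.4$
  this confines reciprocal pairs to the faster half of the gradient
  (pairs between slow regions become explosive).
- **Unidirectional influences** ($i \leftarrow j$) transplant the
  source's timescale into the receiver. The receiving node slows down,
  the regional null partially adapts, and the clean signature is that
  the *coupled edge* decays slower than the geometric-mean prediction —
  the deviation concentrates on the coupled edges themselves.

The default coupled test condition uses 20 regions with five reciprocal
pairs in the fast half and five unidirectional influences in the slow
half, every region participating, coupling strength 0.4, lag 2, active
in epochs 6–10 of 10.

## Known limitations

- The plug-in MI estimator with 64 bins is strongly biased at these
  sample sizes; the pipeline relies on the bias being near-constant
  across delays (it varies slowly as $T - \tau$ shrinks, which the
  linear tail fit tracks). Absolute AMI values should not be
  interpreted, only the decay structure.
- $\tau^*$ is an integer number of samples. Signals whose true
  timescales differ by less than one delay step tie; the fastest nodes
  of a gradient are separated reliably only in aggregate (e.g. the
  across-seed median profile). The 0.5–48 Hz band-pass additionally
  floors the fastest observable timescale.
- The regional null shares estimator noise with the empirical decays at
  the single-trial level; comparisons of the two are most meaningful at
  the trial-averaged level, which is where the consistency checks in
  the test suite operate.
- The toy leakage model (hemispherical sources, $1/d^2$ leadfield,
  distance-correlated sensor noise at SNR 12, LCMV inverse with 5%
  diagonal loading) is deliberately minimal: it reproduces the
  qualitative leakage phenomenology (inflated short-range zero-lag
  correlations) without any claim to anatomical realism.

## Problem sizes used by the tests

The test-suite and acceptance-script simulations use 20-region,
10-epoch datasets (190 edges) for the coupled/uncoupled studies, 20
seeds each; parameter recovery uses 5-region single-epoch gradients; and
one full-scale configuration (78 regions, 3003 edges, 10 epochs of 2560
samples, 128 delays) verifies that the complete pipeline runs at the
scale the analysis targets. These sizes are the package's chosen study
conditions and are reported alongside every result.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(n_subjects = 1, n_epochs_per_subject = 10,
                         n_regions = 20, coupling_strength = 0.4,
                         coupling_pairs = list(c(1, 6), c(6, 1)),
                         coupling_epochs = 6:10, seed = 1)
ds   <- generate_dataset(cfg)
emp  <- trial_decay_table(ds, "edge")
fid  <- fid_matrix(emp)
null <- null_decay_tables(ds, "regional")
cls  <- classify_trials(emp, null, fid,
                        nodal = nodal_gradient_analysis(ds))
head(cls$table)
```
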