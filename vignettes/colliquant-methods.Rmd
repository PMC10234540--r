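---
title: "Quantifying superior colliculus circuit-mapping experiments with colliquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying superior colliculus circuit-mapping experiments with colliquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colliquant)
```

The lateral superior colliculus (LSC) is a midbrain hub where whisker-related
signals from motor cortex (MC), barrel cortex (BC) and the trigeminal
brainstem (Bs) converge onto recipient neurons (RNs) and are relayed onward to
diencephalic and brainstem targets. `colliquant` implements the quantitative
half of this kind of circuit-mapping study: the statistics applied to sorted
spike trains, trans-synaptically labeled cell counts, and axon-count tables.
Raw recordings and histology are replaced by synthetic generators with known
ground truth, so every stage can be calibrated and tested end to end.

## Spike-train responsiveness

### The whisker test

A unit is called whisker-responsive when its per-trial spike counts in the
response window differ from those in an identical-length spontaneous window
(defaults `[20, 50)` ms and `[-50, -20)` ms around airpuff onset, half-open
in milliseconds) by a two-sample Wilcoxon (Mann-Whitney) rank-sum test at
$\alpha = 0.05$. We use `stats::wilcox.test`, which switches between the
exact null distribution (small samples, no ties) and the tie- and
continuity-corrected normal approximation. All windows in the package are
half-open $[a, b)$ so a boundary spike is never counted twice.

The effect size is the modulation index,

$$\mathrm{MI} = \frac{R - C}{R + C},$$

where $R$ and $C$ are firing rates in the response and spontaneous windows
(total in-window spikes divided by `n_trials` times the window length). MI is
$-1$ when the unit is fully suppressed ($R = 0$, $C \neq 0$), $0$ when
unmodulated, $+1$ when it fires only after the stimulus; it is undefined when
both rates are zero, and the unit is then flagged unscorable. The response
sign reported with the test follows the sign of MI; when $R = C$ exactly the
sign is `none`.

A note on calibration: at a 5 Hz baseline the 30-ms windows contain mostly 0
or 1 spikes, and no rank test has exactly nominal size under such heavy ties.
The tie-corrected normal approximation runs very slightly hot (about 0.057
at $\alpha = 0.05$ in our null simulations), while exact conditional
(permutation) variants run conservative (0.018-0.037). We keep the
field-standard corrected rank-sum; the type-I suite documents the achieved
rate on 1,000 null units.

### Unit quality control

Units enter the analysis when fewer than 3% of inter-spike intervals fall
below a 1.5-ms refractory period and the session-wide rate exceeds 0.1 Hz.
Units with fewer than two spikes have no intervals; their violation fraction
is defined as 0 (they are then typically removed by the rate criterion).

### Optogenetic response classification

During successive photostimulation of MC-L5 and BC-L5, evoked spike counts
(`[6, 18)` ms) are z-scored per trial against the mean and standard deviation
of the unit's spontaneous counts (`[-18, -6)` ms); trials with $z > 1.96$
count as successes. A unit is responsive to a pathway when a one-tailed
one-sample t-test rejects $H_0{:}\ p = p_0$ (alternative "greater") on the
success indicators at $\alpha = 0.05$, with $p_0 = 1/3$; dual-input
convergence is the conjunction of both pathway calls. Two degenerate rules
are fixed by convention: a zero-variance spontaneous vector gives $z = +\infty$
(success) for trials above the spontaneous mean, $0$ at the mean, $-\infty$
below; a zero-variance success vector is decided by comparing the proportion
to $p_0$ directly.

The trial-number design asks for the smallest $N$ at which the exact
one-sample binomial test of $H_0{:}\ p = p_0$ (two-sided $\alpha$ split
equally between tails) reaches power 0.8 under the true proportion $p_1$.
For $p_1 = 1/3$ against $p_0 = 2/3$ the exact search gives $N = 19$ and the
classical normal approximation $N = 16$; both are reported by
`required_trial_count()`, and the package deliberately does not hard-code
any other figure.

`threshold_sweep()` automates the choice of $p_0$: it counts responsive
units along an ascending grid of candidate null proportions (the curve is
non-increasing) and selects the first grid point from which the count stays
stable across a configurable window — a reproducible stand-in for visually
locating the inflection of the inclusion curve.

### Unit localization by trilateration

Unit positions on the probe plane are estimated from per-channel spike
amplitudes under an inverse-square decay model $A(d) = a/d^2$, fit on the
four largest-amplitude channels (configurable). For a candidate position the
source strength $a$ has a closed-form least-squares solution, so only the
2-D position is optimized (Nelder-Mead from the amplitude-weighted centroid,
then a BFGS polish). Noiseless inverse-square sources are recovered to below
$10^{-6}$ µm on a standard dual-column probe layout. Collinear channel
geometries with equal amplitudes cannot be inverted and fall back to the
weighted centroid with a `degenerate` flag. Note that a source lying exactly
on a channel is inconsistent with the model (its self-distance is zero), so
"recovery of a channel position" is only meaningful through symmetric
geometries, which the tests use.

## Anatomy: binned distributions, proportions, convergence

### Rostro-caudal binning

Cell counts are binned along the anterior-posterior (AP) axis into thirteen
100-µm bins covering the sampled atlas sections from -3.08 to -4.28 mm
(bregma-relative). Because that range spans 1.2 mm, the 13 bins are centered
on the 13 section positions, with edges at -3.03 ... -4.33 mm; a cell at
exactly -3.08 mm falls in the first bin, and the most caudal bin is closed.
Counts are normalized per brain to that brain's maximum bin
(`normalize_per_brain()`, idempotent), and cells outside the range are
reported, never silently dropped.

### The comparison battery

`compare_distributions()` reproduces the study's nonparametric battery:
per-group one-sample Kolmogorov-Smirnov normality checks (values are
z-scored against their own mean and SD and tested against N(0,1), mirroring
how the MATLAB one-sample test is conventionally applied), Wilcoxon rank-sum
for two groups, Kruskal-Wallis with Bonferroni-adjusted pairwise rank-sum
tests (`p_adj = min(1, p·k)`) for three or more. Groups with fewer than two
values are excluded and flagged.

### Proportions and slice exclusion

`proportion_summary()` computes marker proportions such as GABA/NeuN or
iRN/RN: overall percent, per-slice percents with mean ± SEM, and an
exclusion list. Rounding is explicit: one decimal reproduces `84/384 =
21.9%`, integer rounding reproduces `41/119 = 34%`. Slices whose denominator
cannot support the comparison are excluded via `min_slice_n_for_power()`,
the smallest per-group $n$ at which a pooled two-proportion z-test reaches
power 0.8 (the normal-approximation formula; a Monte-Carlo oracle in the
test suite confirms it to ±1).

### Convergence statistics and the mixture zone

For convergence neurons (CVG-RNs, innervated by two sources),
`convergence_stats()` z-scores the per-pair mean CVG counts across the
compared pairs (the z-scoring axis is the set of pair means; this is
documented because other readings are possible), reports the fold difference
between pair groups on mean per-bin counts, and summarizes CVG/RN
proportions.

`fit_convergence_gmm()` localizes the convergence zone: a two-component
full-covariance bivariate Gaussian mixture fit by EM with k-means++-style
seeding, 10 restarts, and a $10^{-6}$ log-likelihood tolerance. The reported
zone peak is the mixture-density mode, found on a 200×200 grid over the data
bounding box and refined by Nelder-Mead ascent; by construction its density
is at least that of both component means. Two numerical safeguards matter in
practice: covariance eigenvalues are floored at $10^{-3}$ of the data
variance (degenerate, e.g. collinear, inputs are regularized with a
warning), and restarts whose solution sits on that floor — collapsed
single-point components, whose likelihood is spuriously high — are discarded
in favour of non-collapsed restarts whenever one exists. The EM is
implemented in the package because the likelihood trace, restart policy and
mode search are part of the analysis contract; an independent mixture fitter
(mclust) is used as a cross-check in the test suite only.

## Axon output maps

Per-slice axon counts are organized into AP-bin × nucleus matrices: 15
diencephalic nuclei over -1.22 to -2.54 mm and 7 brainstem nuclei over -5.4
to -6.4 mm (the shipped nucleus lists are documented defaults; regions are
divided equally into 13 and 10 bins respectively, and per-animal bin counts
are configurable). Two summaries follow:

* relative axon counts, $\mathrm{RAC} = \mathrm{counts}/\max(\mathrm{counts})$,
  a matrix in $[0, 1]$ invariant to overall scaling;
* per-nucleus z-scores of the AP-summed totals (sample SD by default,
  configurable). Because "normalized to the pathway maximum" admits two
  readings, both are emitted: `z_maxnorm` (z divided by the maximum absolute
  z) and `totals_maxnorm` (raw totals divided by the maximum total).

## The synthetic generators

The generators emulate the statistical structure the analyses assume — not
the biophysics:

* **Whisker sessions** (`gen_spike_dataset()`): airpuffs at uniform 1-100 s
  intervals; units are piecewise-constant Poisson processes at a 5 Hz
  baseline. A planted fraction (default 0.32) is modulated: the rate is
  multiplied by the gain (default 4) in a window starting at a per-unit
  latency drawn from a fast/slow mixture — fast (25 ± 4 ms, weight 0.6) and
  slow (60 ± 10 ms, weight 0.4), chosen so both modes intersect the 20-50 ms
  analysis window — and lasting 20 ms. A default 7% of modulated units are
  suppressed instead (rate divided by the gain). At these settings the
  rank-sum test detects only part of the planted 32% at 30 trials; the
  planted fraction and the detected fraction are both reported by the
  acceptance script, and recovery tests compare against ground-truth labels
  rather than assuming perfect power.
* **Optogenetic blocks** (`gen_opto_dataset()`): 40 pulses every 5 s per
  cortex; units belong to (`mc_only`, `bc_only`, `dual`, `none`) with
  planted probabilities; driven units fire a burst (default gain 100 on the
  5 Hz baseline, i.e. ~500 Hz) starting 9-12 ms after the pulse. The default
  gain is chosen so that 3-4.5 burst spikes fall inside the fixed 6-18 ms
  evoked window despite the latency offset — a reliable, strong response.
* **Soma tables** (`gen_soma_tables()`): per-pathway Gaussian clouds in the
  DV×ML plane with default centroids (MC 1123/1505, BC 1035/1297, Bs
  1276/993 µm), uniform AP positions over the sectioning range, a 23%
  GABAergic fraction (GABAergic RNs also carry the iRN marker), and per-pair
  convergence experiments (default CVG fractions 0.23 for MC+BC and 0.10
  for the brainstem pairs, cell clouds centered between the parent
  pathways; 1,000 cells per pair put the strongest pair's CVG population at
  the few-hundred-neuron scale of the mapped data).
* **Axon counts** (`gen_axon_counts()`): Poisson draws around per-nucleus
  mean profiles modulated by a smooth unimodal AP envelope.

One integer seed drives everything through fixed per-stage offsets, so
identical specs give bitwise-identical outputs and adding a stage never
perturbs another. What the generators deliberately omit: spike-sorting
artefacts, bursting and refractory structure, rate drift, spatially varying
cell density, and section-to-section counting noise beyond Poisson. Passing
tests therefore certify the statistics pipeline, not robustness to every
failure mode of real recordings or histology.

## Problem sizes and reproducibility

The test suite and the acceptance script run the calibration suites at 1,000
null units × 30 trials (type-I), 250-300 units for classifier recovery,
$10^4$ randomized inputs for the modulation-index properties, 100 random
matrices for the output-map oracle checks, and $n = 1000$ for mixture
recovery — sizes at which binomial and standard-error bands are tight enough
to be meaningful while keeping a full run in minutes on one core.
`run_pipeline()` executes every stage on synthetic data from one validated
JSON configuration and writes a manifest (configuration hash, seed, package
version, MD5 of every output); identical configuration and seed reproduce
identical manifests.

## Known limitations

* The whisker responsiveness test inherits the discreteness of small spike
  counts; its achieved size at a 5 Hz baseline is slightly above nominal
  (see above), and any correction would trade this for conservatism.
* The GMM mode is a density peak of a two-component fit; on unimodal point
  clouds the two components overlap and the mode is near the cloud center,
  but it should not be over-interpreted as evidence of bimodality.
* The threshold-sweep stabilization rule replaces a visual judgement; its
  window and tolerance are configurable and reported, not canonical.
* Axon-map bin counts in real data vary per animal; the fixed default
  shapes exist for reproducibility, and `build_axon_matrix()` accepts any
  bin count.
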