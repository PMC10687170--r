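---
title: "Internal-state models of movement variability and their neural analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-state models of movement variability and their neural analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statereach)
```

# The behavioral model

The task is a center-out delayed reach with an instructed speed (fast or
slow), four target directions, and a 20% chance per trial of a physical
perturbation (uniform force in [2.5, 15] N at a uniform angle,
classified towards/away by whether its absolute circular distance to the
target bearing is below $\pi/2$; the boundary counts as away). Two
behavioral outputs are measured per completed trial: reaction time (RT,
go cue to leaving the center) and speed error (SE, the instructed-speed
midpoint, 0.67 or 0.33, minus the realized speed as a fraction of the
subject's calibration speed). A trial is correct iff $|SE| \le 0.13$;
session performance is the percent of completed trials that are correct.

Two scalar internal states carry trial history. The error state
integrates past speed errors and the perturbed state integrates past
perturbation pulses, each under a forgetting factor $\alpha \in
[0.01, 0.99]$ with initial condition 0:

$$x^{SE}_t = \alpha^{SE} x^{SE}_{t-1} + y^{SE}_{t-1}, \qquad
  x^{P}_t = \alpha^{P} x^{P}_{t-1} + \mathbb{1}\{\text{perturbed at } t-1\}.$$

Both admit the closed form $x_t = \alpha^{t-1}x_1 +
\sum_{i<t}\alpha^{t-i-1}u_i$ (implemented independently in
`closed_form_state()` and used as a cross-check of the recursion).
States are constant within a trial: planning and execution read the same
value, and updates happen only between trials.

The observation equations are linear. Planning predicts the per-subject
z-scored RT from a constant, both (z-scored) states, and complete
one-hot codings of speed and direction; execution predicts the raw SE
from a constant, both states, the z-scored RT, and the six
speed-by-perturbation cells. RT is z-scored before modeling; SE is not
(it is already bounded and approximately uniform). Gaussian noise closes
each equation.

**Identifiability.** A constant plus complete one-hot codings is rank
deficient, so only contrasts between condition levels are identifiable.
`fit_weights()` returns the minimum-norm (pseudo-inverse) solution so a
weight exists for every level, mirroring how fitted-weight tables are
usually reported; `reference_fit()` provides the treatment-coded `lm`
refit when standard errors and confidence intervals are needed. Columns
that are identically zero (the perturbed state in a perturbation-free
session) are flagged non-identifiable rather than propagating NaN, and a
constant state trace z-scores to zeros by convention.

## Fitting and the selection criterion

`grid_search_fit()` evaluates all 99 × 99 decay pairs (step 0.01,
configurable), z-scoring the states and refitting both weight vectors at
each pair. One decay pair is shared by the two equations, matching a
single state process feeding both movement phases; `outputs = "rt"` or
`"se"` restricts the selection score to one equation for sensitivity
analysis.

The selection criterion was a genuinely open design point: minimizing
the summed root-mean-squared error and maximizing the observed/estimated
Pearson correlation are both defensible readings of the fitting
procedure. We score by **summed RMSE by default**. The alternative —
averaging the two outputs' Pearson correlations — normalizes each
equation to its own scale, which hands the execution equation (whose
score surface is nearly flat in the decay constants, because the state
contributes a small share of SE variance) an equal vote; in recovery
simulations this inflates the median decay-constant error roughly
threefold. The summed-RMSE selector weights each equation by its
residual scale, which in practice lets the better-identified planning
equation pin down the decay constants. `criterion = "pearson"`
implements the correlation selector (with RMSE tie-break) for
comparison.

Internally the grid is solved from sufficient statistics: the fixed
condition columns are orthonormalized once, the 99 candidate state
traces per axis are residualized against them, and each grid point
reduces to a 2 × 2 solve — the full grid costs well under a second for a
300-trial session.

## Model evaluation

`evaluate_fit()` reports, per output: Pearson correlation between
observed and estimated values, $R^2$ (reported clamped to [0, 1]),
Gaussian deviance (the residual sum of squares, zero iff the fit is
perfect), and a 10-fold cross-validated $R^2$. Because the states are
history-dependent, CV refits only the weights per fold while holding the
states fixed at their full-data estimates — the CV score therefore
measures the stability of the weights, not out-of-sample state
estimation. `fit_baseline()` fits the same designs minus both state
columns; since the baseline is nested, in-sample $R^2$ always favors the
full model, and the cross-validated comparison is the meaningful one on
state-free data.

# The synthetic generator

`simulate_session()` runs the model generatively: conditions are sampled
with the task's probabilities, then the state recursion advances
causally on the **raw** state scale while the observation equations draw
RT (z-units, mapped to seconds by an affine transform with mean 0.80 s
and sd 0.15 s) and SE with Gaussian noise. Z-scoring a state requires
the whole trace, so a causal generator cannot emit z-scored states; this
is harmless because z-scoring is an affine map absorbed by the
intercept — the fitted column space, and hence the selected decay
constants, are unchanged, and generating slopes map to the fitted scale
by the raw-state sample sd.

Incomplete trials (optional, default none) are skipped by the state
recursion, matching the fitter's default convention;
`carry_incomplete = TRUE` in `evolve_states()` switches both to the
alternative of evolving through them with zero SE input.

SE is **not clipped** to [−0.67, 0.67] by default: a clipped Gaussian
violates the linear model's assumptions and would bias recovery tests,
so the noise sd is chosen to keep essentially all mass inside the bounds
instead (clipping is available as an option for realism studies).

**Default design point.** The generator defaults are a calibrated
parameter-recovery testbed: $\alpha^{SE} = 0.30$, $\alpha^P = 0.70$,
n = 300 trials, raw-scale state weights 3.5 / 1.3 (RT equation) and
0.25 / 0.08 (SE equation), RT noise sd 0.10 (z-units) and SE noise sd
0.11. The execution side is realistic — SE $R^2 \approx 0.5$, session
performance spanning roughly 40–57% — while the planning side is
deliberately high-signal so the decay constants are sharply identifiable
at n = 300: the precision of $\hat\alpha$ scales with
$\beta\,\sigma_{SE}\sqrt{n}/\sigma_{RT}$, and with behavioral-scale
noise on both equations no estimator resolves $\alpha$ to ±0.02 at this
sample size. One structural constraint matters when changing weights:
the SE equation feeds back into the error state, so the effective pole
$\alpha^{SE} + c_{SE} + c_{RT}\,b_{SE}$ must stay well below 1 or the
generated session diverges (the defaults give ≈ 0.6).

`simulate_cohort()` varies execution noise across subjects (low noise →
high performance) and scales the state weights *against* the performance
gradient — strong positive error-state weights perpetuate errors, so
large weights co-occur with poor performance in this design.

## Synthetic LFP

`synthesize_lfp()` is minimal-sufficient for the analysis chain: per
channel, 1/f-colored background noise plus a 60 Hz line component, and,
for each encoding target, a band-limited noise burst (FFT-masked white
noise under a Tukey envelope) in the target's epoch/time/frequency slot
whose per-trial amplitude is $\max(a_0(1 + g\,z_t), 0)$ for the trial's
z-scored target state $z_t$.

Two deliberate departures from real recordings:

- the 1/f background is generated **independently per trial segment**,
  so trials are exchangeable — exactly the assumption the permutation
  test relies on. Session-long 1/f noise induces across-trial power
  autocorrelation which, combined with the autocorrelated internal
  state, makes naive trial permutation anti-conservative (we measured
  ~11% type-I at nominal 5%); handling that on real data requires
  block-aware permutation schemes and is out of scope here. Passing
  tests on this generator therefore validate the pipeline under its own
  assumptions, not robustness to slow drifts in real recordings.
- epoch durations are task configuration. The eight task epochs are
  exposed as a required layout with 0.6 s placeholder defaults; tests
  and the acceptance script use reduced layouts (1–2 epochs of 1.0–1.4 s)
  and reduced sample rates (200 Hz) and permutation counts (99–200) so
  the suite runs in minutes — these are the package's documented
  simulation sizes, while the configuration defaults keep the analysis
  constants (2 kHz, N = 1000, 1–200 Hz, 12 bins/octave) at their
  full-scale values.

# Spectral preprocessing

`notch_filter()` designs one biquad notch per 60 Hz harmonic with the
−1 dB bandwidth set to 3 Hz (the pole radius is solved numerically from
the bandwidth specification) and applies the zero-phase
(forward–backward) response — the squared magnitude of the cascade — in
the frequency domain on a reflection-padded copy of the signal. This is
the ideal filtfilt response without its edge transients; note that a
finite-duration tone still leaves spectral-skirt energy near the signal
edges, so filter-response measurements use the settled mid-section.

`morlet_cwt()` implements the analytic Morlet CWT ($\omega_0 = 6$) by
FFT, with scales mapped to center frequencies by the standard Fourier
factor and L2-normalized wavelets (white noise → flat expected power
across frequencies). The frequency axis is log2-spaced with ≈ 12 bins
per octave by default, adjusted so both endpoints of 1–200 Hz are hit
exactly; 12/octave makes the one-octave cluster filter ≈ 12 bins.
Signals are reflect-padded by twice the e-folding time of the largest
scale; the per-frequency cone-of-influence is attached as an attribute
rather than masked, since session-long inputs dwarf it.

`window_average()` takes linear means over 100 ms windows every 50 ms
and labels each bin with its **end** time; `normalize_log_z()` z-scores
the natural log of power per frequency bin over the entire session
(power floored at machine epsilon), storing the per-bin statistics for
inversion. Averaging is linear-then-log: bins average power, and the log
is taken at normalization. `epoch_lock()` then slices bins whose end
labels fall inside each trial's epoch window, counting bins from the
realized labels so rounding of the hop size at awkward sample rates
cannot misalign trials.

# The cluster statistic

Per channel, each time-frequency pixel receives
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for the Spearman correlation $\rho$
between the state and normalized power across trials ($|\rho| = 1$ is
capped at a large finite sentinel). Channel maps are averaged within
subject, then across subjects (`aggregate_hierarchical()`); regions with
fewer than two subjects are excluded.

**Cluster-forming threshold.** The reference distribution of the
hierarchically averaged t is not a textbook t, so the pixel threshold
treats subjects as the unit of inference: a pixel enters a cluster when
the one-sample t of the subject-level means exceeds the two-tailed
Student-t critical value at $\alpha = 0.05$ with $n_{subjects} - 1$
degrees of freedom. A pixel with zero spread across subjects and nonzero
mean is treated as infinitely consistent (included), not undefined. An
absolute-threshold alternative is available. Clusters are 4-connected
components (time and frequency neighbors, no diagonals) of
supra-threshold pixels sharing the sign of the averaged map, scored by
their **mass** (sum of the averaged t) — the standard statistic in the
cluster-permutation framework.

**Permutation scheme.** Each of N permutations shuffles the state's
trial order once per subject — identically across that subject's
channels (preserving spatial correlation), independently across
subjects — and reruns the identical map/threshold/cluster pipeline,
recording the maximum absolute cluster mass. Observed clusters get the
add-one estimate $p = (k+1)/(N+1)$, signed by the correlation direction;
at N = 1000 with zero exceedances this floors at $9.99\times10^{-4}$,
which is why that value dominates well-separated effects.

**Size filter and FDR.** Clusters must span ≥ 250 ms (bin count × 50 ms
step), ≥ 1 octave (log2 ratio of bounding bin centers), and at least the
product of those minimum bin counts in pixel area. The filter is applied
to observed clusters after p assignment; null maxima are not
size-filtered, which can only be conservative. Benjamini–Hochberg at
q = 0.015 then corrects the surviving |p| across regions and epochs
(`stats::p.adjust`). Surviving clusters in the same region with
overlapping frequency bins are merged across epochs (union–find), each
group labeled with the canonical band (delta 1–4, theta 4–8, alpha 8–15,
beta 15–30, low gamma 30–60, high gamma 60–100, hyper gamma 100–200 Hz)
holding the majority of its pixel area, and called *persistent* if its
members cover all task epochs, else *phasic*.

Under the null the pre-size-filter minimum cluster p per region is
calibrated at $\alpha$ by exchangeability; the size filter removes
essentially all null clusters at desk scale, so calibration checks are
made before it and false-discovery checks after it.

# Encoding and connectivity

For each cluster group, a channel's trial signal is the mean normalized
power over the group's window, averaged across the epochs it spans
(`trial_power_series()`). Encoding strength is the channel-mean
$|\rho_{Spearman}|$ between that signal and the state — in [0, 1] by
construction. Region selection correlates per-subject encoding strength
with session performance across subjects and selects when $|r| > 0.75$
**or** $p < 0.05$ (small cohorts make the magnitude threshold necessary)
provided the cohort has subjects strictly above and strictly below the
average performance; requiring two per side is available as the stricter
variant of that ambiguous representation rule. No multiplicity
correction is applied to these performance correlations by default,
matching the exploratory usage; a BH flag exists.

Connectivity strength is the $|\rho_{Spearman}|$ between two channels'
trial signals (a Pearson/zero-lag cross-correlation option exists);
subject strength averages unique channel pairs (diagonal
autocorrelations excluded within-region); population strength
Fisher-z-averages subject strengths (clamped at $1 - 10^{-7}$) and is
always bounded by the subject min/max; performance connectivity is the
across-subject Pearson correlation with session performance, evaluable
only with ≥ 3 subjects and both performance sides represented, and the
> 0.5 truncation applies to graph export only — the stored value is
always the full correlation.

# Validation strategy and limitations

The patient-data results this pipeline mirrors are not reproducible at
desk scale, so validation is property-based, implemented in the test
suite and recomputed by `scripts/acceptance.R`:

- exact agreement of the state recursion and closed form (1000 random
  instances, 1e-10);
- the permutation floor $9.99\times10^{-4}$ at N = 1000;
- decay-constant recovery (20 sessions, n = 300: median error ≤ 0.02
  per axis) with 95% weight-CI coverage in [0.85, 1];
- full-vs-baseline model comparison in ≥ 19/20 seeds with states on, and
  no systematic cross-validated gain with states off;
- type-I calibration of the cluster statistic on zero-gain cohorts
  (4 subjects, 3 regions, 200 permutations) within the binomial band
  around 5%, and ~zero false discoveries after the size filter plus FDR;
- localization of an injected window (bounding-box Jaccard ≥ 0.5,
  correct sign) in ≥ 90% of seeds;
- notch depth, CWT tone localization, normalization moments;
- performance-coupled encoding selection: planted regions selected,
  null-region false selections within the binomial band around the
  rule's nominal 5% level (the p < 0.05 arm of the selection rule makes
  a strictly-zero false rate unattainable by construction).

Known limitations: trial exchangeability is built into the generator
(see above); the CWT's spectral smearing makes recovered cluster
bounding boxes overshoot injected windows by roughly one bin per edge,
bounding achievable Jaccard; encoding/connectivity operate on the
cluster groups as given and do not revisit upstream uncertainty; and the
behavioral CV score is conditional on full-data states. None of these
affect the contracts above, but all matter when interpreting runs on
real recordings.
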