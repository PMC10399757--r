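---
title: "Discriminant classification and class-mean feature selection for multichannel EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant classification and class-mean feature selection for multichannel EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Motor-control experiments that record surface electromyography (EMG) produce
high-dimensional data: many muscles, sampled at 1000 Hz, over many trials and
subjects. The conventional analysis is univariate — pick a muscle and a
summary statistic in advance, then test it. `emgdiff` implements the
complementary multivariate route: classify whole multichannel activation
patterns between two task conditions (here, pointing movements in different
directions relative to gravity), then ask the fitted classifier *which*
features — which muscles, and which moments within the movement — carried the
discrimination.

The pipeline has five stages, each a module of the package:

1. **Preprocessing** — from raw interference EMG to duration-normalized
   envelopes on a common time base.
2. **Vectorization** — concatenate each trial's channels into one long
   feature vector; min–max normalize per subject and muscle; assign
   subject-wise cross-validation folds.
3. **Classification** — binary linear discriminant analysis (LDA) of the
   trial vectors.
4. **Feature selection** — difference the two class-mean models, partition
   the features by an iteratively lowered cutoff into High-Diff and Low-Diff
   sets, and map these back to muscles.
5. **Statistics** — χ² comparison of right/wrong counts, Bonferroni
   correction, Friedman and Wilcoxon tests on the composite separation
   index.

A sixth module generates synthetic EMG-like and kinematic datasets with
known ground truth, so that every stage is testable although the original
recordings are not redistributable.

## The classifier

For a trial vector $x \in \mathbb{R}^p$ and class $k \in \{k_1, k_2\}$, LDA
models each class as a multivariate Gaussian $f_k$ with class mean $\mu_k$
and a covariance $\Sigma$ shared between classes, and assigns the class with
the larger Bayes posterior

$$\Pr(Y = k \mid X = x) = \frac{f_k(x)\,\pi_k}{\sum_l f_l(x)\,\pi_l},
\qquad \hat Y = \arg\max_k \Pr(Y = k \mid X = x),$$

with priors $\pi_k$ equal to the training class proportions (0.5 in the
balanced designs considered here).

Two numerical points matter at $p = 9000$ features against at most a couple
of hundred training trials:

* **Covariance representation.** The full pooled $p \times p$ covariance is
  necessarily singular at this ratio, so the default is the pooled
  *diagonal* covariance ("diagonal LDA"), with a variance floor of $10^{-8}$
  for numerically constant features. This is the standard stable choice in
  the $p \gg n$ regime, and the feature-selection stage uses only the class
  means, which are unaffected by the choice. A `pooled` variant (full
  covariance, pseudo-inverted when singular) is available for
  low-dimensional problems and is cross-checked against `MASS::lda` in the
  tests. The exact regularization used by any particular analysis tool on
  real data is generally unreported, so accuracies from different
  covariance treatments are not expected to agree to the decimal.
* **Log-space arithmetic.** Densities of 9000-dimensional Gaussians under-
  or overflow; all posterior computations run on log densities with a
  log-sum-exp normalization. Exact posterior ties are broken
  deterministically toward the first class label in sorted order.

`cross_validate()` accepts any classifier supplied as a `fit`/`predict`
pair, so external algorithms can be plugged into the same protocol; the
package itself ships only the LDA pair.

## Feature selection by differencing the class means

The importance score of feature $i$ is the absolute difference of the class
mean models, $d_i = |\mu_{k_1,i} - \mu_{k_2,i}|$ (`lda_diff()`), and the
composite separation index is $\sum_i d_i$ (`lda_distance()`). A cutoff is
scanned from $\max_i d_i$ downward in steps of `step_frac` (default 0.05,
i.e. a 20-step scan — fine enough to resolve the profile, coarse enough to
keep the scan at forty cross-validations) of the range. At each step the
features strictly above the cutoff and those at or below it are classified
*separately* (features removed, not zeroed: zeroed features would still
enter through covariance terms under non-diagonal representations), and the
scan stops at the first cutoff where the above-set beats the below-set.
Muscles containing any above-cutoff element are the High-Diff muscles; the
reported Low-Diff muscles are the complement, so the muscle table is a
partition. A `min_frac` option tightens "any element" to a minimum fraction
of a muscle's samples when single-sample noise is a concern.

Three design points were genuinely open:

* **Which means are differenced under cross-validation.** Each fold's
  training model yields its own difference vector; the package averages the
  per-fold vectors and uses one global mask for all folds. This makes the
  reported mask satisfy `high_mask == (lda_diff > threshold)` exactly and
  keeps the muscle sets well-defined; because normalization precedes the
  fold split, per-fold difference vectors are near-identical anyway.
* **Where the scan accuracies are evaluated.** The scan evaluates both
  restricted classifications on the same outer cross-validation folds. This
  is the reading that keeps the procedure a single pass; it is optimistic
  in the sense that the threshold is chosen on the same folds it is
  evaluated on, which is why the package's own validation (below) rechecks
  the selected partition on freshly generated data.
* **Empty restricted sets.** When a scanned cutoff leaves one side empty,
  the classifier degenerates gracefully to a prior-only rule (log-prior
  comparison, deterministic tie-break), which scores at chance on balanced
  designs; no special-casing is needed.

If the scan reaches the minimum of the difference vector without the
above-set ever beating the below-set, selection *fails* with an error
carrying the full trace — on null data this is a correct outcome, not a
defect, and reports record it as such.

## Preprocessing chain

The conditioning chain per channel is: zero-phase Butterworth band-pass
20–300 Hz (design order 4, applied forward–backward); extraction of the
movement window from 200 ms before movement onset to movement offset, with
onset/offset defined by hand tangential velocity crossing 5% of its peak;
rectification; sliding integration over 5 ms (a centered moving average
whose window shrinks at the edges rather than padding); zero-phase low-pass
at 5 Hz; linear interpolation onto a 1000-sample common time base.

Decisions worth recording:

* "Integration over a sliding window" is implemented as a rectified moving
  average. Integrating a zero-mean band-passed signal without rectification
  would cancel to nothing; a `rectify = FALSE` flag exists for
  already-rectified inputs.
* Zero-phase filtering uses odd-symmetric reflection padding of a few time
  constants of the slowest corner frequency at each end, so edge transients
  decay inside discarded pads. Without this, a 5 Hz low-pass visibly biases
  the first and last few hundred samples of an 800–1000-sample window.
* The low-pass is applied before duration normalization (the order the
  chain is described in), and is also zero-phase for consistency with the
  band-pass stage.
* A pre-onset margin that would reach before the start of the recording is
  clamped to the first sample with a warning rather than an error.
* Every stage is linear or positively homogeneous, so
  `preprocess(a·x) = a·preprocess(x)` for `a > 0`; per-subject gains are
  therefore fully cancelled by the later min–max normalization. This
  composition is asserted in the tests.

## Normalization and its grouping

Within each subject and muscle, values are mapped linearly so the group
maximum becomes 1 and the minimum −1. Two groupings are provided:

* `per_class` (default): min and max computed separately within each
  condition. This is the literal repeated-measures protocol, but it exactly
  erases a whole-muscle multiplicative amplitude difference between
  conditions (both conditions' peaks map to 1).
* `joint`: min and max computed over both conditions together, which
  preserves between-condition amplitude differences.

These two goals — equalizing muscles and preserving condition differences —
are in genuine tension, and only the joint grouping achieves the second.
The package's validation runs and the acceptance script use `joint`
normalization wherever planted amplitude effects must remain measurable;
`per_class` remains the default for protocol fidelity. Normalization is
computed on the full dataset before the fold split (again protocol
fidelity); a leakage-free variant is obtained by normalizing training folds
only and applying the training extremes to test folds, which users can do
by calling `minmax_normalize()` on subsets.

## The synthetic generator

`gen_emg_dataset()` emulates the study design: 11 subjects × 9 trials per
condition × 9 muscles sampled at 1000 Hz over a 1000-sample movement
window. Each channel is a tonic baseline (0.2) plus up to three phasic
Gaussian bursts (agonist / antagonist / second agonist, the classical
tri-phasic organization), with burst parameters staggered across channels.
Planted channels differ between conditions by a whole-envelope factor
$1 + \text{effect\_size}$ and a burst-centre shift of `timing_shift` of the
window; all other channels are drawn from identical distributions in both
conditions, so any selection of them is a false positive by construction.

Variability has two scales, both chosen once as realistic for surface EMG
envelopes and then left alone:

* **Trial-to-trial** (`noise_sd`, default 0.4): lognormal per-burst
  amplitude jitter (log-SD 0.4 ≈ ±40% burst-to-burst variation),
  burst-timing jitter of SD `noise_sd/10` of the window, and additive
  sample noise of SD `noise_sd/4`.
* **Between-subject** (`subject_gain_sd`, default 0.2): a multiplicative
  gain per subject and channel (electrode placement and impedance), and a
  per-subject burst-timing offset of SD `subject_gain_sd/10` of the window
  (motor style). The latter is what makes cross-subject generalization
  genuinely imperfect.

Under these defaults the full-vector cross-validated accuracy of the
planted-effect design lands in the low-to-high 90s — the regime reported
for cross-subject EMG classification of pointing direction — rather than a
saturated 100%, which matters because the threshold scan terminates on an
accuracy comparison. Amplitude effects multiply the whole envelope rather
than single bursts so that the condition means differ by exactly
$1+\text{effect\_size}$ at every sample in the noise-free limit, which
gives the tests a sharp oracle.

A `raw` mode amplitude-modulates band-limited (20–300 Hz) unit-variance
noise with the envelope, emulating raw interference EMG so the
preprocessing chain can be exercised end to end; the recovered envelope
correlates above 0.95 with the generating one in the noise-free setting.
The generator is deterministic given its configuration: a single seed is
split into per-subject and per-trial streams, so enlarging a design leaves
previously generated trials untouched.

`gen_kinematic_dataset()` produces the low-dimensional proof-of-concept:
up/down point-to-point reaches with minimum-jerk displacement along Y, only
drift and noise along X and Z, per-subject amplitude (log-SD 0.1),
per-trial amplitude jitter (log-SD 0.1) and 0.02 position noise. Only the Y
axis differs between conditions by construction.

What the generator does *not* emulate: biomechanics (no gravity torques, no
muscle model), motor noise structure, correlated noise across muscles,
non-stationary baselines, movement-duration differences between conditions.
Passing tests on synthetic data therefore show that the *procedure* recovers
planted structure under realistic variability — not that any particular
muscle finding on real data is correct.

## Statistics

Classification outcomes are compared with Pearson's χ² on the 2×2 table of
right/wrong counts, one degree of freedom, without continuity correction
(the plain named test; the correction choice would otherwise be silent).
Expected counts below 5 warn but do not switch the test. Multiple planned
comparisons use Bonferroni division (0.05/4 = 0.0125 for four pointing
directions). The separation index, a continuous quantity, is compared
across conditions with the Friedman rank test followed by Wilcoxon
signed-rank planned comparisons (exact null distribution up to 25 non-zero
differences, normal approximation beyond; two-sided by default). The
replication unit for these rank tests is the cross-validation fold, since
the index is produced once per fold; all-tied and all-zero degenerate
inputs are reported as statistic 0 / p 1 and as an error, respectively.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles
(brute-force Bayes posteriors, closed-form χ², rank-formula Friedman,
sign-pattern enumeration for Wilcoxon, `MASS::lda` for the pooled variant)
and the pipeline against the generator's ground truth at the full study
scale: 20 replicates of planted-channel recovery with fresh-data
generalization, 20 null seeds for chance-level soundness, a 4-point effect
grid × 10 seeds for monotonicity of the separation index, and the kinematic
proof of concept. Property loops run on a scaled-down design (6 subjects,
4 channels, 80-sample windows) that preserves the generative model. The
acceptance script reruns the same computations at 10 replicates per
quantity. These sizes give stable averages while keeping a full run in the
minutes range on one core.

## Known limitations

* The threshold scan optimizes on the outer folds; its reported
  High/Low-Diff accuracies are optimistic. Use fresh data (or nested folds)
  for unbiased estimates, as the validation runs do.
* Diagonal LDA ignores feature correlations; with 1000 strongly
  autocorrelated samples per muscle this discards information, and is the
  price of stability at $p \gg n$.
* Per-class min–max normalization erases whole-muscle amplitude effects;
  choose the grouping to match the scientific question.
* The muscle partition depends on the `min_frac` membership rule when the
  difference profile is noisy near the chosen cutoff.
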