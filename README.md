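# emgdiff

Binary discriminant classification of multichannel surface EMG (and
kinematic) time series, with embedded feature selection by differencing the
class mean models.

## What it is for

Motor-control studies record many muscles at high sampling rates, yet are
mostly analysed one variable at a time. `emgdiff` takes the multivariate
route for two-condition designs (for example, pointing at one angle vs the
gravity-neutral horizontal): it classifies whole trials from the
concatenation of all channels' time series, and then interrogates the
fitted classifier for *which* muscles — and which moments within the
movement — carried the discrimination. The package is aimed at researchers
who want a composite index of muscular adjustment between task conditions
plus an interpretable map of where that adjustment lives, without choosing
variables in advance.

## The method

Each trial's nine muscle envelopes (1000 samples each, duration-normalized)
are concatenated into a vector `x` of p = 9000 features, min–max normalized
to [−1, 1] per subject and muscle. Binary LDA models each class `k` as a
Gaussian with mean `μ_k` and a shared covariance, and classifies by the
Bayes posterior

    Pr(Y = k | X = x) = f_k(x) π_k / Σ_l f_l(x) π_l ,   Ŷ = argmax_k Pr(Y = k | X = x)

evaluated in log space with a pooled *diagonal* covariance (p is far larger
than the number of trials). Accuracy is estimated by subject-wise 5-fold
cross-validation (11 subjects split 2/2/2/2/3), so no subject is ever in
training and test at once. Feature selection then differences the class
means,

    d_i = | μ_k1,i − μ_k2,i | ,      separation index = Σ_i d_i ,

and lowers a cutoff on `d` step by step until the features above the cutoff
classify better than those below; muscles containing above-cutoff features
are the "High-Diff" muscles. Right/wrong counts are compared with Pearson's
χ² (Bonferroni-corrected across comparisons: 0.05/4 = 0.0125), and the
separation index across conditions with Friedman plus Wilcoxon planned
comparisons.

Because the underlying human recordings are available only on request, the
package ships a tested synthetic generator (envelope bursts with planted
direction-tuned channels, plus minimum-jerk reach kinematics) so the whole
pipeline is verifiable against known ground truth. See the methods
vignette (`vignettes/emgdiff-methods.Rmd`) for the model, the design
decisions and their rationale.

## Worked example

```r
library(emgdiff)

cfg <- sim_config(seed = 1)   # 11 subjects, 9 trials/condition, 9 muscles;
                              # AD and MD are planted as direction-tuned
ds  <- gen_emg_dataset(cfg)
tm  <- minmax_normalize(vectorize_dataset(ds), grouping = "joint")
folds <- make_folds(tm$meta$subject, k = 5, seed = 1)

cross_validate(tm, folds)
#> cv_result: mean accuracy 98.89% over 5 folds (right 196 / wrong 2)

sel <- threshold_search(tm, folds)
sel
#> feature_selection: threshold 0.463, 356/9000 features High-Diff
#>   High-Diff channels: AD, MD
#>   accuracy high 97.96% vs low 97.78%; separation index 856.2

recovery_score(sel$high_channels, ds$ground_truth$planted_channels,
               cfg$channel_names)
#> $precision  [1] 1
#> $recall     [1] 1
```

Reading the output: the full 9000-feature vectors classify the two
conditions at 98.9% under subject-wise cross-validation; the threshold scan
stops at a cutoff of 0.463 on the class-mean difference, above which lie
356 features, all belonging to the two muscles (anterior and medial
deltoid) whose activity was actually planted to differ — perfect precision
and recall against the generator's ground truth. The separation index
(856.2) is the summed class-mean difference and serves as a composite
measure of how much the muscle pattern changed between conditions.

A thin command-line front end over the same functions is installed as
`exec/emgdiff` (subcommands `simulate`, `preprocess`, `vectorize`,
`classify`, `select`, `report`), exchanging long-format CSV and JSON files.

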