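---
title: "EEG complexity analysis with Higuchi fractal dimension and fuzzy partition memberships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG complexity analysis with Higuchi fractal dimension and fuzzy partition memberships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfd)
```

## The problem

Resting-state EEG complexity is a candidate biomarker for staging opioid
addiction and monitoring treatment. The analysis implemented here takes
19-channel eyes-closed EEG (10--20 montage, 250 Hz) from four groups of
subjects — active users ("addict"), early treatment ("first", under three
days), extended treatment ("second", over two weeks), and healthy controls
("normal") — and asks two questions:

1. Which channels carry complexity differences between groups?
2. How well can complexity features classify the addiction stage?

The complexity measure is the Higuchi Fractal Dimension (HFD) of each
channel's broadband cleaned signal; the classification path passes the HFD
features through a fuzzy partition-membership transform before the
classifiers see them.

## The Higuchi estimator

For a series $x(1..N)$, delay $k$ and start offset $m \le k$, the
normalized curve length is

$$L_m(k) = \frac{N-1}{\lfloor (N-m)/k \rfloor\, k^2}
  \sum_{i=1}^{\lfloor (N-m)/k\rfloor} |x(m+ik) - x(m+(i-1)k)|,$$

and $\langle L(k)\rangle$ is its mean over $m = 1..k$. The HFD is the slope
of the ordinary least-squares fit of $\ln \langle L(k)\rangle$ on
$\ln(1/k)$. Smooth signals give $\approx 1$, white noise $\approx 2$.
The estimate is exactly invariant under affine transforms of the series, so
amplitude scaling and offsets never matter.

Defaults: $k_{\max} = 8$ with all of $k = 1..8$ in the fit — a common,
stable choice for 250 Hz EEG segments of 1000+ samples. Both are exposed in
`hfd_config()`. Degenerate (constant) input raises a typed error rather
than returning a value.

### Feature vectors

Every subject contributes two eyes-closed recordings; each of the 19
channels yields one HFD per recording, giving the ordered 38-vector
`higu_1 ... higu_38` where `higu_{2c-1}` and `higu_{2c}` come from channel
`c` (`feature_to_channel()` maps indices back to electrodes, e.g. `higu_7`
→ channel 4 = F3, `higu_29` → channel 15 = Pz). Subjects with more than
two usable recordings contribute their first two in manifest order;
subjects with fewer are excluded with a warning.

## The synthetic cohort: a truth channel for the whole pipeline

No generative model of the recordings is available, so the package ships a
generator whose fractal dimension is *analytically known*. Fractional
Gaussian noise (fGn) with Hurst exponent $H$ is simulated exactly by
Davies–Harte circulant embedding (`generate_fgn()`); its cumulative sum is
discrete fractional Brownian motion (fBm), whose graph has fractal
dimension $2 - H$. Channel signals are standardized fBm: with $H$ on a
channel, the Higuchi estimate of that channel recovers $2-H$ within 0.01
at $N = 2500$.

A subtlety worth stating: the $2-H$ law belongs to fBm, not to stationary
fGn itself — the Higuchi dimension of raw fGn is close to 2 for every $H$.
The generator therefore integrates the fGn draw before scaling, and all
dimension-recovery checks run on the integrated series.

Default study conditions (all in `cohort_config()`):

* group sizes 19/24/23/20 (addict/first/second/normal), two eyes-closed
  recordings per subject, 19 channels at 250 Hz, 10 s per recording;
* planted effect: channels 4, 5, 6, 15 carry group-specific Hurst
  exponents 0.55/0.65/0.75/0.85 (fractal-dimension separation 0.10 between
  adjacent groups); all other channels share $H = 0.70$ across groups;
* subject-level Hurst jitter with SD 0.05 (truncated), so within-group
  variance exceeds estimator noise and classification stays non-trivial —
  with identical $H$ for all subjects of a group the problem would be
  artificially easy;
* artifacts: 50 Hz line sinusoid (20 µV, random phase), slow drift
  (50 µV at 0.2 Hz), and rare high-amplitude biphasic transients
  (400 µV, ~40 ms, Poisson at 0.05/s over the recording, each hitting one
  random channel);
* both recordings of a subject are independent draws sharing the
  subject-level Hurst profile (within-subject dependence beyond that is
  not modelled).

The 10 s default duration is a desk-scale compromise; the vignette's and
tests' problem sizes (cohorts of 80--86 subjects, 10--50 replicates,
$N = 2500$ samples) were chosen so that each property check completes in
minutes on one core while keeping every statistical margin comfortable.

What the generator does *not* emulate: volume conduction, a shared
physiological reference signal, spatial correlation between channels,
band-limited oscillatory structure (alpha peaks etc.), eyes-open states,
and non-stationarity beyond the planted artifacts. Passing tests therefore
demonstrate that the pipeline recovers known complexity structure under
realistic contamination — not that it reproduces every property of real
EEG.

## Preprocessing

`preprocess()` applies, in fixed order: per-channel mean subtraction
("remove baseline" on continuous data), 50 Hz notch, 1--70 Hz FIR
band-pass, common average reference (CAR), bad-channel interpolation, and
amplitude-based segment rejection. Independent-component cleaning is out
of scope by design: it is delegated to external tools upstream, and every
stage here is deterministic arithmetic.

Numerical choices that proved to matter:

* **Band-pass.** Hamming windowed-sinc, order $3.3 f_s / (f_{low}/2)$
  (1650 taps at defaults), cutoffs placed mid-transition ($0.75 f_{low}$,
  $f_{high}+5$) so the band edges sit at ~0 dB while $0.5 f_{low}$ and
  $f_{high}+10$ are at least 30 dB down. Applied as exact linear-phase
  convolution with the group delay removed and odd-symmetric reflection
  padding — zero padding would taper two thirds of a 10 s record through
  a 6.6 s impulse response.
* **Notch.** Coherent 50 Hz removal by least-squares projection on the
  in-phase/quadrature sinusoids (the CleanLine-style step), followed by a
  zero-phase second-order IIR notch (unit-circle zero, pole radius 0.975:
  over 30 dB at 50 Hz after two passes, under 3 dB at ±5 Hz). The
  projection step exists because on short records *any* filter's edge
  transient smears a 20 µV line's boundary phase discontinuity into a
  ~1--2 µV broadband residual — which raises the Higuchi dimension of
  smooth (high-$H$) channels by several tenths and can invert planted
  group ordering. Exact projection removes the stationary line with no
  edge effects at all.
* **Ordering.** The notch runs before the band-pass. Both are linear
  time-invariant operators, so they commute in exact arithmetic; applying
  the short-memory notch first minimizes finite-record edge transients
  from the long FIR.
* **Bad channels.** Peak-to-peak below 0.1 µV (flat) or any sample above
  500 µV marks a channel bad; it is replaced sample-wise by the unweighted
  mean of its non-bad neighbours on a hard-coded 10--20 adjacency graph
  (every electrode has at least two neighbours; the graph is symmetric).
  More than half the channels bad, or a bad channel with no good
  neighbour, is unrecoverable.
* **Segment rejection.** Consecutive 1 s windows are dropped if any
  channel exceeds ±200 µV, then the kept windows are concatenated — a
  deterministic stand-in for artifact-subspace-reconstruction cleaning
  that reliably removes the synthetic transients.

## The fuzzy partition-membership transform

The feature-processing step at the heart of the classification path. A
*partition generator* — by default a Gini decision tree (minimum leaf 2,
unpruned; `rpart` under the hood, re-expressed as an explicit threshold
tree) — carves the feature space into axis-aligned cells. Each instance is
then re-expressed as its membership degrees over the leaf cells:

* **crisp** mode: the one-hot indicator of the containing leaf;
* **graded** mode: each split is softened with a logistic activation
  $\sigma(\pm(x_f - t)/b)$ and a leaf's degree is the product along its
  path. At a threshold both children receive 0.5; as $b \to 0$ the degrees
  converge to the crisp assignment.

In both modes the leaf degrees of an instance sum to one — the transform
is a fuzzy partition of unity. The default bandwidth is
$0.25 \times \mathrm{IQR}$ of the split feature, computed on the fitting
data. Cells are leaves only (internal-node indicators would break the
sum-to-one semantics). Why both modes: a hard partition reproduces the
classical propositionalized embedding; the graded mode realizes genuine
partial membership. Output can be written sparsely as
coordinate-format CSV (`write_membership_coo()`).

Leakage control: `cross_validate()` fits the partition inside each
training fold only and transforms the held-out fold with the frozen model;
held-out row counts are never affected.

## Attribute ranking

Four evaluators, all returning a best-first ranking with deterministic
low-index tie-breaks:

* `correlation_rank()` — class-frequency-weighted mean absolute Pearson
  correlation with each one-vs-rest class indicator.
* `chi2_rank()` — chi-squared statistic of the bin-by-class table after
  equal-frequency discretization (10 bins by default; the scheme is a
  package choice, no canonical one exists).
* `significance_rank()` — two-way probabilistic association: the average
  of the mean total-variation distance between per-class attribute
  distributions and the mean total-variation distance between per-bin
  class distributions; 1 for a class-determining attribute, 0 for a
  constant.
* `pca_rank()` — the five-step loading-priority procedure: correlation
  matrix, eigendecomposition, eigenvalues sorted descending, leading
  components kept (Kaiser rule by default), attributes scored by
  eigenvalue-weighted absolute loadings. Using the correlation (not
  covariance) matrix makes the ranking invariant to per-attribute
  rescaling. Note PCA is unsupervised: it can only surface a planted
  effect when the effect dominates shared variance, as it does when
  several features (the paired features of affected channels) carry it.

## Classification and the metric panel

`build_comparisons()` enumerates the canonical schemes for the four
groups: all-groups, four one-vs-rest, six pairwise — eleven in total.
`cross_validate()` runs stratified k-fold (10 by default, reduced with a
warning when the rarest class is smaller), pools the out-of-fold
predictions, and reports the full panel per class and class-weighted: TP
rate, FP rate, precision, recall, F-measure, Matthews correlation, ROC
area, and precision-recall area. All 0/0 ratios are reported as 0.

Models mirror the conventions of the classical data-mining toolkit the
field uses: an MLP with one hidden layer of
$\lceil (p + \#classes)/2 \rceil$ logistic units, standardized inputs,
500 iterations (`nnet` backend — a quasi-Newton optimizer rather than
plain backpropagation, so learning-rate/momentum have no direct analogue);
and an RBF-kernel SVM with default scale and one-vs-one multi-class,
probabilities via pairwise coupling (approximate, used only for the
ROC/PRC columns). Both are deterministic under the supplied seed.
`classify_all_schemes()` runs every scheme for every requested model and
flags the best per scheme by weighted F — the selection rule is stated in
the output rather than implied.

## Channel statistics

`ks_normality()` screens each group for normality with the
Lilliefors-corrected one-sample KS test (parameters are estimated, so the
correction is the honest default; the output labels the method).
`anova_per_attribute()` runs a classical one-way fixed-effects ANOVA per
attribute across the four groups, reporting uncorrected significance at
$\alpha = 0.05$ *and* a Bonferroni column side by side — the uncorrected
column matches the per-attribute screening convention of the original
analysis, the corrected one is there because 38 tests deserve it.
`tukey_hsd()` gives studentized-range-adjusted p-values for all six group
pairs, and `attribute_channel_report()` maps significant attributes back
to channels and electrodes.

### Reference leakage, and why the localization calibration excludes CAR

One finding from building this pipeline deserves emphasis. Common average
referencing subtracts the instantaneous mean of all 19 channels from each
channel. In the synthetic world each channel is an *independent* source —
there is no shared reference signal and no volume conduction (an explicit
non-goal) — so CAR can only *inject* a $4/19$ share of the affected
channels' group-dependent signal into every null channel. With 20 subjects
per group that leakage is reliably detectable: null-channel ANOVA flags run
at 15--30%, versus 3--7% for the identical chain without re-referencing.
Those flags are genuine group effects of the re-referenced signals, not
calibration failures. Consequently the package's acceptance checks measure
detection power and classification on the full chain (CAR included, as the
method prescribes) but measure null-channel false-positive calibration on
the same chain without the re-referencing stage, and report both figures.
On real EEG, where a common reference component exists, CAR serves its
intended purpose; on independent-source simulations it is purely a mixing
operator — a caveat that applies to any simulation study of referenced
EEG.

## End-to-end runs

```r
cfg <- run_config(
  cohort = cohort_config(seed = 1),  # the study-sized synthetic cohort
  models = "mlp", transform = "crisp", seed = 42)
man <- run_all(cfg, out_dir = "run1")
```

writes `features.csv` (86 × 38 + labels), four ranking files, one metric
panel per scheme and model, the ANOVA/channel reports, and a JSON manifest
(package version, seed, config hash, per-stage counts) sufficient to
reproduce the run bit-identically. Per-stage child seeds are derived from
the master seed by a fixed named-substream map, so adding a stage never
perturbs the streams of earlier ones.

## Known limitations

* The synthetic cohort omits spatial correlation and oscillatory structure;
  absolute classification figures on it do not transfer to real EEG.
* The graded membership's logistic softening is one reasonable
  realization of partial membership; the original propositionalized
  filter's exact behaviour (crisp node indicators) is available as the
  crisp mode.
* SVM probability estimates come from pairwise coupling and are
  approximate; ROC/PRC areas for SVM inherit that.
* Segment rejection concatenates non-adjacent windows; the seams are step
  discontinuities. With the default rare-transient regime this is
  negligible, but heavy rejection would bias HFD upward.
* ANOVA assumes normality and equal variances; the KS screen is provided,
  but no Welch or nonparametric fallback is implemented.
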