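---
title: "Personalizing activity recognition models with incremental ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing activity recognition models with incremental ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A human activity recognition (HAR) model trained on pooled data from many
people — a *user-independent* (UI) model — systematically underperforms on a
new user: body build, gait, sensor placement and personal style shift the
feature distributions per activity class. Collecting a labeled personal
training set from every new user is impractical, and retraining a deployed
model on-device is expensive. `persohar` instead *personalizes* an existing
UI model incrementally: the model is an ensemble to which new base models,
trained on the user's own streaming chunks, are appended. Nothing is ever
retrained or discarded, so the memory and compute cost per update is the
cost of fitting one weak classifier on one chunk.

The package implements the full loop — synthetic multi-subject data,
windowing, feature extraction, base learners, the incremental ensemble, the
three chunk-labeling policies, per-chunk training, and the
leave-one-subject-out (LOSO) evaluation protocol.

## The ensemble and its combination rule

An ensemble holds ordered base models $h_1,\dots,h_m$, each a weak
classifier with its own selected feature subset. Prediction is equal-weight
soft voting: each member's posterior is embedded into the union of class
lists (zero for classes the member does not know) and averaged,

$$P(c \mid x) = \frac{1}{m} \sum_{j=1}^m P_j(c \mid x),$$

with hard label $\arg\max_c P(c\mid x)$ and confidence $\max_c P(c \mid x)$.
Two design points deserve justification:

* **Equal weights.** Classic incremental ensembles weight members by
  estimated accuracy, but estimating accuracy requires trusted labels — and
  in the non- and semi-supervised settings the chunk labels are partly
  predictions. Uniform weights avoid feeding label noise back into the
  combination rule, and they are used in the supervised setting too so that
  the three policies differ *only* in how labels are obtained.
* **Soft voting rather than hard majority voting.** The semi-supervised
  policy thresholds a graded confidence. Hard votes from a handful of
  members produce a few coarse confidence levels; posterior averaging
  produces the smooth confidence distribution the threshold mechanism
  needs. Argmax ties are broken by lexicographic class order, so
  predictions are deterministic.

## Base learners

Three classical, cheap classifiers are supported, all exposing the same
posterior contract (`predict_posterior()` returns a row-stochastic matrix):

* **LDA** via `MASS::lda`, priors from training frequencies.
* **QDA** as a shrinkage-regularized Gaussian discriminant implemented in
  the package: per-class covariances are shrunk toward their diagonal,
  $\Sigma_c \leftarrow (1-\lambda)\Sigma_c + \lambda\,\mathrm{diag}(\Sigma_c)$
  with $\lambda = 0.1$, plus a relative ridge of $10^{-8}$ on the diagonal.
  Personal chunks are small and noisy; unregularized per-class covariances
  are routinely singular there.
* **CART** via `rpart` (depth ≤ 6, leaf size ≥ 3, no complexity pruning),
  with **Laplace-smoothed** leaf posteriors $(n_{c}+1)/(n_{\text{leaf}}+K)$.
  Raw leaf proportions are often exactly 0 or 1, which would make every
  prediction maximally confident and silently disable the query mechanism;
  smoothing keeps the threshold semantics meaningful.

## Labeling an incoming chunk

Three policies produce labels for an unlabeled personal chunk:

* *non-supervised*: ensemble predictions only — free, but wrong predictions
  are fed back into training and can snowball (concept drift);
* *supervised*: the user labels everything — the accuracy ceiling at maximal
  annotation cost;
* *semi-supervised*: predictions are kept where the ensemble is confident;
  windows with `confidence < th` (strictly below) are queried from the user.

The threshold is **dual**: 0.95 while the ensemble has only UI members and
0.75 once any personal member exists. UI-only ensembles produce optimistic,
compressed posterior distributions, so few windows fall under even a high
cutoff; personal members spread the posteriors out, and keeping 0.95 there
would flood the user with queries. The pair (0.95, 0.75) balances the query
load between rounds.

Because activities occur in long bouts, a queried label for window $w$ is
also **propagated** to the in-chunk windows $w\pm1, w\pm2$ (unless they were
themselves queried), so one user input corrects up to five labels. Numerical
tie-breaks: a window in reach of two queries takes the nearest one, with
distance ties going to the earlier (smaller-$w$) query; propagation never
crosses chunk boundaries; propagated windows count as "replaced" but not as
"user inputs". Setting both thresholds to 0 reproduces the non-supervised
policy exactly; setting them to 1.01 (confidence is at most 1 and the
comparison is strict) reproduces the supervised policy — the test suite
asserts both equivalences end to end, bit for bit.

## Training a base model from a chunk

Personal chunks are small, so three steps precede fitting
(inject → sample → select → fit):

1. **Noise injection**: `noise_copies = 2` noisy replicates of each window
   are appended, with per-feature Gaussian noise of sd
   `noise_scale = 0.1` × the feature's within-chunk sd. This operates in
   feature space — chunks arrive featurized, and augmenting features
   directly avoids a second featurization pass.
2. **Bootstrap sampling**: uniform with replacement. For personal chunks the
   default draws as many instances as the *raw* chunk held
   (`bootstrap_size_rule = "original_size"`); for the UI pool, as many as
   the pool holds. The alternative rule (augmented-pool size) is exposed in
   the configuration.
3. **Sequential forward selection (SFS)**: greedy wrapper selection using
   the mean stratified 3-fold CV balanced accuracy *of the same classifier
   kind being trained* as the criterion, stopping at `sfs_max_features` or
   when the gain is non-positive; score ties go to the smallest feature
   index. For LDA/QDA the wrapper caches per-fold class moments (counts,
   means, crossproducts, pooled scatter) once and scores each candidate
   subset by subsetting those moments in a compiled kernel, which is what
   makes wrapper SFS over a 210-feature bank tractable; CART refits per
   candidate.

Each of the three models per chunk runs in its own RNG stream derived from
`(seed, subject, round, replicate)` via `derive_seed()`, giving reproducible
diversity: replicates differ in their noise draws, bootstrap samples and
hence selected features, while reruns are bit-identical.

## The evaluation protocol

LOSO: each subject in turn is the "new user"; all other subjects form the UI
pool. The held-out subject's recording is split **per class** into three
equal contiguous thirds at sample resolution, windows are computed
independently inside each third (no window straddles a cut, so the parts
share no raw samples), and the thirds become personalization part 1,
part 2, and the test part, in temporal order (the assignment is a
configurable permutation; temporal order is the default since a deployed
system meets earlier data first).

The protocol then runs: three UI models trained on bootstrap samples of the
pool (Step 1), three personal models from part 1 labeled under the chosen
policy (Step 2), three more from part 2 (Step 3) — the threshold rule makes
Step 2 use 0.95 and Step 3 use 0.75 under the semi-supervised policy. After
every addition the ensemble is evaluated on the test part, giving nine
evaluation points; the "static UI baseline" is the score after Step 1. The
simulated user (oracle) is a ground-truth label lookup by subject and window
index. A chunk whose assigned labels collapse to a single class is recorded
as a failed round and skipped with a warning rather than aborting the run.

Metrics: balanced accuracy (mean per-class recall over classes present in
the truth), error rate $= 1 -$ balanced accuracy, and macro false negative
rate, which for these definitions is identically the error rate; the traces
record all three so the identity is visible and testable.

The UI-only control (`run_ui_only_control()`) repeats Steps 2–3 with fresh
bootstrap models from the UI pool instead of personal chunks. If
personalization rather than mere ensemble growth drives the improvement,
this control's error curve should stay flat — which is exactly what the
study shows.

## The synthetic cohort

`generate_cohort()` emulates the essential structure of multi-subject
triaxial accelerometer studies: every subject records every class for the
same duration (`seconds_per_class = 120` at 50 Hz by default, five classes),
as a sinusoid per axis,

$$x_a(t) = A\,g\,\sin(2\pi f\,\phi\,t + \theta_a) + o_a + u_a + \varepsilon(t),$$

with axis phases $\theta_a = 0, 2\pi/3, 4\pi/3$, class parameters $(A, f,
o_a)$, and subject-and-class deviations drawn once per block: gain
$g \sim N(1, 0.15)$, offset $u_a \sim N(0, 0.3)$, frequency factor
$\phi \sim N(1, 0.05)$, plus white noise $\varepsilon \sim N(0, 0.2)$ per
sample. The default class table spreads amplitudes over 0.25–1.6 (fractions
of g) and fundamentals over 0.4–2.0 Hz (gait-band), with per-axis mean
offsets on a circle of radius 0.4. These choices make neighbouring classes
overlap across subjects (amplitude gaps are comparable to the gain sd,
offset gaps to the offset sd) while staying cleanly separable within a
subject — so UI models are imperfect, personal data is genuinely
informative, and the frequency cues (which crossing-count features pick up
robustly) keep the UI model respectable rather than useless. Deviations are
drawn per subject *and* class so that every class, not just a few, carries a
personal signature.

What the generator does **not** emulate: gravity orientation, biomechanical
waveform shape, sensor drift, activity transitions inside a bout, or
imbalanced class durations. Passing tests on this cohort therefore show
that the *mechanism* works when between-subject shift is the dominant
nuisance — they do not certify accuracy figures on any real dataset.

## Windowing and features — numerical conventions

Sample counts are `round(seconds × Hz)`: a 4.2 s window at 50 Hz is 210
samples with a 70-sample slide; a 1 s window with a 1/3 s slide is 50 and 17
samples. Sample intervals are 0-based and half-open. A window's label is
the modal per-sample label, ties broken by first occurrence inside the
window; windows whose majority-label purity falls below `min_purity`
(default 1) are dropped — synthetic bouts are contiguous, so nothing is
lost there, and the cutoff is configurable for real data with fuzzy
transitions.

Per derived signal (3 raw axes + triad magnitude + 3 pairwise magnitudes),
30 features: std, min, max, median; percentiles 10/25/75/90 (linear
interpolation between order statistics); sums and square sums of values
strictly below the low percentiles and strictly above the high ones (one
tail per percentile — symmetric tail summaries); level-crossing counts per
percentile (sign changes of $x_t - q$, zeros carrying the previous nonzero
sign); and sums of the FFT magnitude spectrum over 10 equal contiguous bins
of the non-negative frequencies, zero-frequency term excluded. Every one of
these has an independently coded brute-force counterpart (explicit loops, a
direct DFT) in the test suite, and the batched compiled path is asserted
against the plain-R `extract_features()` path.

## Study conditions and problem sizes

The reference study (`run_study()`) uses 10 synthetic cohorts (seeds 0–9) of
8 subjects × 5 classes × 120 s per class, full LOSO under all three
policies with LDA base models, plus the UI-only control — 216 base models
per cohort. Its one deviation from the per-module defaults is
`sfs_max_features = 5` instead of 10: on the 210-feature bank the wrapper's
CV score has typically plateaued well before five features, and halving the
cap roughly halves the dominant cost of a study, so five is the study
protocol's choice for multi-seed runs on a single core. The acceptance
script runs the same study over three cohorts derived from its `--seed`.

## Known limitations

* Balanced accuracy on the default synthetic cohort saturates near 1.0 for
  the supervised policy — the within-subject signal is nearly
  deterministic at window level. Gaps between policies are therefore
  conservative relative to messier real data.
* The ensemble grows without bound (by design, matching the incremental
  setting); pruning strategies are out of scope.
* Sensor position is assumed fixed between the UI pool and the personal
  stream; body-position independence is out of scope.
* The oracle never errs: simulated user inputs are ground truth, so the
  semi-supervised results assume a perfectly reliable annotator.
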