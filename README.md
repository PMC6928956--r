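# persohar

Personalizing human activity recognition (HAR) models from streaming
inertial-sensor data via incremental ensemble learning.

User-independent HAR models — trained on pooled data from many people — lose
accuracy on a new user, because people differ systematically in how they move.
`persohar` starts from such a user-independent model and *personalizes* it
without ever retraining it: as the new user's unlabeled stream arrives in
chunks, new base models trained on those chunks are appended to a
Learn++-style ensemble, so the ensemble gradually adapts to the user's own
movement style.

## The method

The ensemble holds an ordered set of base models \(h_1, \dots, h_m\)
(LDA, regularized QDA, or CART classification trees), combined by
equal-weight soft voting:

    P(c | x) ∝ (1/m) Σ_j P_j(c | x),

with the hard label `argmax_c P(c | x)` and confidence `max_c P(c | x)`.
Equal weights are used deliberately: with unlabeled personal data there are no
trustworthy labels from which to estimate per-member accuracies.

Each incoming personal chunk is labeled by one of three policies before new
base models are trained on it:

* **non-supervised** — every window keeps the ensemble's predicted label;
* **supervised** — the user labels every window (the accuracy ceiling);
* **semi-supervised** — predicted labels are kept where the ensemble is
  confident, and windows with `confidence < th` are queried from the user.
  The threshold is *dual*: `th = 0.95` while the ensemble contains only
  user-independent members (their posteriors are optimistic) and `th = 0.75`
  once any personal member exists. Because activities come in long bouts,
  each user answer for window `w` is also propagated to windows
  `w±1, w±2`, so one user input corrects up to five labels.

Per chunk, training follows inject → sample → select → fit: the chunk is
augmented with noisy copies (per-feature Gaussian noise at a fraction of the
feature's sd), a bootstrap sample is drawn, sequential forward selection
picks a small feature subset by cross-validated balanced accuracy, and the
base model is fitted on it. Windows are 4.2 s with a 1.4 s slide by default,
expanded into a 210-dimensional feature bank (per raw/derived signal: order
statistics, percentile tail sums and square sums, level-crossing counts, and
banded Fourier magnitude sums).

Evaluation uses leave-one-subject-out: every subject in turn becomes the new
user, whose recording is split per class into two personalization parts and
one test part (sample-disjoint, so no window leaks across parts). Metrics are
balanced accuracy (mean per-class recall; the error rate is its complement)
and macro false negative rate.

A seeded synthetic cohort generator stands in for real recordings: each
subject performs each activity as a sinusoidal triaxial pattern perturbed by
subject-specific gain, offset and frequency deviations plus white noise, so
the between-subject shift is real and personalization has something to learn.

## Worked example

```r
library(persohar)

cohort <- generate_cohort(synthetic_config(n_subjects = 4,
                                           seconds_per_class = 60, seed = 42))
cfg <- experiment_config(policy = labeling_policy("semi_supervised"),
                         train = train_config(sfs_max_features = 5), seed = 42)
trace <- run_personalization("S01", cohort, cfg)
trace$steps[, c("step", "n_members", "origin", "balanced_accuracy", "error_rate")]
#>   step n_members           origin balanced_accuracy error_rate
#> 1    1         1 user_independent         0.6000000 0.40000000
#> 2    2         2 user_independent         0.7500000 0.25000000
#> 3    3         3 user_independent         0.9666667 0.03333333
#> 4    4         4         personal         1.0000000 0.00000000
#> ...
#> 9    9         9         personal         1.0000000 0.00000000
trace$queries
#>   round threshold query_fraction replaced_fraction
#> 1     1      0.95     0.40000000        0.40000000
#> 2     2      0.75     0.01666667        0.08333333
```

The ensemble grows from three user-independent members (balanced accuracy
0.967 on subject S01's held-out test part) to nine members — three
user-independent plus six personal — reaching balanced accuracy 1.0. Round 1
queried 40% of the first chunk's windows at threshold 0.95; by round 2, with
personal members in the ensemble and threshold 0.75, only 1.7% of windows
needed a user label, and ±2-window propagation replaced 8.3% of labels in
total.

`run_loso()` repeats this for every subject (optionally under several
policies at once) and `run_study()` averages full LOSO runs over several
generated cohorts; `policy_table()` lays out the final scores per policy.

A thin command-line front end ships in `inst/scripts/persohar.R`
(`simulate`, `featurize`, `predict`, `run` subcommands, YAML-configured).

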