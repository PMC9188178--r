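---
title: "Seed variety genuineness detection: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed variety genuineness detection: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genuseed)
```

## The problem

Commercial maize seed lots are routinely adulterated with genetically and
phenotypically similar varieties; a variety's *genuineness* — whether a given
seed really belongs to the declared variety — is a binary decision:
**target** versus **non-target**, where "non-target" deliberately collapses
every other variety into one class so that the model remains usable for
varieties it has never seen. `genuseed` implements this screening pipeline
for two imaging modalities:

* **VIS/NIR hyperspectral imaging (HSI)**: each pixel carries a full
  reflectance spectrum; per-seed mean spectra on 400–1000 nm are the
  features. Chemical composition differences (protein, starch/oil, water)
  leave small but consistent signatures in specific spectral regions.
* **RGB scans (machine vision)**: 54 shape/color/texture features per seed.
  Cheaper, but genetically close varieties overlap heavily in these
  features, which is precisely why the HSI branch exists.

## Pipeline

1. `read_cube()` / `calibrate_reflectance()` — ENVI-style cubes,
   flat-field calibration \(R = (I - D)/(W - D)\) against white/dark
   reference frames.
2. `trim_bands()` — the spectrometer edges are noise-dominated; the working
   range is the **closed** interval [400, 1000] nm. (Closed, because
   selected characteristic wavelengths in practice include values at the
   upper boundary region such as 919 and 935 nm; a band at exactly
   1000 nm is retained.)
3. `threshold_mask()` / `extract_mean_spectra()` — Otsu threshold on the
   band-averaged image, 8-connected components, regions under `min_area`
   (default 50 px) discarded as specks, one arithmetic-mean spectrum per
   seed. Seeds are scanned non-touching, so no watershed splitting is
   attempted.
4. `spa_select()` — successive projections algorithm (SPA) for
   characteristic-wavelength selection.
5. `train_classifier()` / `evaluate_model()` — RF, RBF-SVM, MLP with
   stratified 3:1 splits and ten-run averaged test accuracy.
6. `verify_external()` / `active_update()` — external verification on
   varieties outside the training set and accuracy-threshold active
   learning.

## Models and parameters

**Splits.** `split_dataset()` draws a stratified random 3:1 train:test
split; each stratum contributes `round(n/4)` test rows (so 315-seed strata
give 236 train / 79 test; 8 rows give 6/2). This fixes the ±1 rounding
ambiguity once.

**SVM.** C-classification with RBF kernel
\(K(x, z) = \exp(-g\,\lVert x - z\rVert^2)\), solved by a
maximal-violating-pair SMO on the full kernel matrix (datasets here are a
few hundred rows). The penalty \(c\) and kernel width \(g\) are tuned by
stratified \(k\)-fold cross-validated grid search; the canonical grid is
\(c, g \in \{2^e : e = -10, -9.8, \dots, 10\}\) — 101 values per axis,
10201 pairs, 5 folds. Exponents are base-2 because a raw range of
\(10^{-10}\)–\(10^{10}\) would be degenerate for both parameters; the
−10..10, step 0.2 convention is the standard libsvm log₂ grid. Ties go to
the smallest \(c\), then smallest \(g\). Features are z-scored with
statistics fit on the training rows only.

**MLP.** One hidden layer of sigmoid units (default width 32), a 2-unit
softmax output, cross-entropy loss with a small L2 penalty (1e-4),
full-batch Adam (lr 0.01, up to 400 epochs), and early stopping on a 10%
stratified validation slice with best-weights restore. The early-stopping
criterion is validation *cross-entropy*, not 0/1 error: 0/1 error
saturates at zero long before the decision margin is grown, and freezing
weights there measurably hurts test accuracy.

**RF.** Bagged CART trees (gini), 500 trees, \(\lfloor\sqrt p\rfloor\)
features per split, grown to purity. No standardization — trees are
scale-equivariant.

**Evaluation.** `evaluate_model()` re-splits, re-fits and re-scores
`runs = 10` times and reports the per-run accuracies, their mean (the
"ten-run averaged accuracy") and the confusion matrix pooled over runs.
When the SVM has no fixed \((c, g)\), grid search is re-run inside every
run — each split is an independent realization of the full protocol (a
configurable choice; pass `config = list(c = ..., g = ...)` to freeze).

## SPA

SPA is forward selection for spectra: starting from a band, it repeatedly
adds the band whose (column-mean-centered) reflectance vector has the
largest norm after orthogonal projection onto the complement of the span
of the bands already chosen — the "most new information, least
collinearity" band. For every start band and every chain length \(k \in
[k_{\min}, k_{\max}]\), an ordinary least-squares model of the class label
(target = 1, non-target = 0) on the chain prefix is fit on the training
rows, and the subset minimizing *held-out* validation RMSE wins (ties:
smaller \(k\), then lexicographically smaller index set). Mean-centering
before the projections is standard practice — otherwise the shared
baseline dominates every chain. Using the binary label as the MLR response
is a deliberate resolution of an ambiguity: nothing else is available as a
response in a genuineness screen. Rank-deficient prefixes are solved with
a tiny ridge (1e-8 of the Gram diagonal) and flagged.

SPA only ever sees subsets reachable by its projection chains; it is not
exhaustive best-subset selection. The test suite therefore checks (a)
chains against an independent brute-force implementation of the projection
recursion, (b) achieved RMSE against an exhaustive oracle *whenever the
oracle's optimum is chain-reachable*, and (c) exact RMSE-0 recovery on
noise-free linear targets constructed to be reachable (support columns
given dominant norms).

## The synthetic world

Real seeds cannot ship with a package; every claim the tests make is
therefore relative to a generative model chosen once to emulate the
structure of real VIS/NIR seed spectra:

* **Mean spectrum** per variety: a logistic ramp rising from ~0.18 to
  ~0.65 toward the NIR (reflectance capped below 0.8, as measured seed
  reflectance is), minus three Gaussian absorption features — protein-linked
  at 450 nm (depth 0.08, σ 30 nm), starch/oil-linked at 650 nm (0.06,
  60 nm), and the ~980 nm water band (0.10, 25 nm).
* **Variety divergence** `d`: a non-target variety's band depths are the
  target's plus `d · u`, with `u` a seeded random unit direction in depth
  space. The map is exactly linear in `d`, and `d = 0` reproduces the
  target. Mapping genetic distance (differing SSR loci) to `d` linearly at
  0.016 per locus is a modeling convenience, not a biological claim; it
  places the 2–10-loci default scenario (d 0.032–0.16) in the regime where
  full-spectrum SVM/MLP models score ≈0.98, mirroring the near-perfect
  separability reported for real varieties.
* **Noise**: a flat between-lot shift (σ 0.01, drawn once per lot), a flat
  per-seed scattering offset (σ 0.02 — coat gloss and geometry, the
  dominant seed-to-seed spread in raw reflectance plots), and a smooth
  spectral residual (kernel-smoothed white noise, ~20 nm bandwidth,
  marginal σ 0.008). The scattering offset is a deliberate deviation from
  a pure smoothed-noise design: at realistic amplitude, 20 nm-smoothed
  noise is spectrally indistinguishable from the chemical band-depth
  differences that carry the class signal, and no divergence regime could
  then be both realistically noisy and near-perfectly separable. Real
  within-variety spread lives mostly in scattering-type directions that a
  classifier can project out; band-shaped chemistry differences do not.
* **Design defaults**: 9 target lots × 35 seeds vs 9 non-target varieties
  × 35 seeds (the reference design); wavelength grid 400–1000 nm in 4 nm
  steps (151 bands — the band count of the source instrument is not
  published consistently and is parameterized here; 4 nm keeps the default
  workload inside 1-CPU test budgets).

What a green test establishes: the pipeline's *operations* are correct
(oracle-checked), and its *behavioral properties* — chance accuracy at
`d = 0`, accuracy monotone in `d`, ≥0.99 at `d/σ_seed = 10`, the update
loop's improvement pattern — hold in this stated world. What it does not
establish: the headline accuracies of any real seed study, which depend on
physical samples. The generator also omits instrument effects (spectral
smile, keystone, sensor QE) and models surfaces as a fixed germ/non-germ
offset rather than paired measurements of one physical seed ("mixed"
surface mode pools both surfaces as independent rows).

## The update loop

`active_update()` implements accuracy-threshold active learning: verify
per external variety; absorb one variety with recognition accuracy below
the trigger (default 0.60) — lowest first by default, or a seeded random
choice among the sub-trigger set, matching the practice of picking the
worst and then sampling — into the training table with correct labels;
retrain from scratch; repeat until the average over the *remaining*
external varieties reaches the stop target (default 0.99, "about 99%"),
nothing is below trigger (status `"stalled"`, logged rather than thrown),
or `max_iter` is hit. Absorbed varieties leave the external average —
they are training data now. Retraining from scratch (rather than
warm-starting) keeps every iteration a clean realization of the training
protocol.

A structural observation the test suite encodes: an external variety whose
divergence direction was represented in training is recognized almost
perfectly even at moderate distance, while a variety along a *new*
direction can be almost entirely misclassified as target even at large
distance. That is exactly why external verification and model updating
are part of the method, and why full-spectrum models generalize to unseen
varieties at least as well as characteristic-wavelength models on average:
a subset selected against the training varieties can simply lack the bands
where a new variety differs.

## Numerical choices and edge cases

* Reflectance above 1 after calibration is kept and counted in
  `meta$n_above_one` (glossy coats locally out-reflect the white
  reference); `white == dark` pixels become `NA` and are counted.
* Simulated reflectance outside (0, 0.8) is clipped with a warning.
* Region perimeter uses a Cauchy–Crofton transition-count estimator with
  the constant +π convexity correction — near-exact for disc/ellipse
  (seed-like) regions, biased low for rectilinear shapes (documented
  limitation). GLCM texture uses a 32-level ITU-R 601 gray conversion,
  distance 1 px, orientations 0/45/90/135°, symmetric and normalized;
  degenerate (single-level) regions define energy 1, contrast 0,
  correlation 1.
* The per-feature overlap coefficient integrates the pointwise minimum of
  two kernel density estimates on a shared grid. At n = 300 per class the
  estimator's own sampling noise puts same-distribution overlaps at
  ~0.89–0.96 — bounds in tests derive from a simulation of that null, not
  from the idealized value 1.
* SPA tie-breaks (equal projected norms, equal RMSE) are deterministic:
  lowest band index, then smaller subset, then lexicographic order.
* `split_dataset()` errors on single-row strata rather than silently
  producing an empty side.

## Limitations

* No TIFF reader in this environment: RGB input is PNG or an in-memory
  array.
* The 54-feature registry is a functional stand-in with the documented
  group structure (14 shape / 24 color / 16 texture); the commercial
  tool's exact feature definitions are unpublished, and no byte-matching
  is attempted.
* SMO, CART forest and the MLP are in-package implementations (no R SVM/RF
  ML stack is available offline here); they are tested against analytic
  cases, permutation nulls and separability oracles, but are not drop-in
  numerical clones of libsvm/randomForest/keras.
* The simulator's divergence model perturbs band depths only; real variety
  differences can also shift band centers and widths.
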