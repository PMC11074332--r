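---
title: "Modelling clinical DDI severity from molecular structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical DDI severity from molecular structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arvddi)
```

## The problem

Clinical resources for HIV therapy grade every antiretroviral (ARV) /
comedication pair on a four-level traffic-light scale — Green (no expected
interaction), Yellow (weak relevance), Amber (manageable with monitoring or
dose adjustment), Red (do not co-administer). Curating those grades requires
literature review and expert judgement; `arvddi` implements a
structure-only predictive model of the grade, so that unreviewed or new
pairings can be screened computationally. The working hypothesis is the
similar-property principle: structurally similar drugs tend to engage
similar metabolic machinery and therefore to show similar interaction
patterns.

## Representation: fingerprints and similarity profiles

Each drug is reduced to a Morgan (extended-connectivity) fingerprint: the
circular atom environments up to bond radius 2 are hashed into a 1024-bit
binary vector. The chemistry engine is OpenBabel's ECFP implementation,
which natively hashes into 4096 bits; the vector is folded to the
configured length by modular OR, the standard way of resizing such
fingerprints. A fixed-dose combination product is one record whose
fingerprint is the bitwise union of its component fingerprints — the only
reading of "merge while maintaining the fingerprint size" that is actually
size-preserving — so `LPV/r` is a single drug with one fingerprint.

A drug's learned representation is its *similarity profile*: the vector of
Tanimoto coefficients (intersection over union of set bits) against a
fixed, ordered reference panel of drugs. Two design choices deserve
explanation:

* **Panel order and freezing.** Model weights are positional, so the panel
  is sorted lexicographically by drug id with a locale-independent radix
  sort, frozen at training time, and persisted with the model.
* **Membership.** Training drugs stay in the panel — self-similarity 1.0 at
  a drug's own position is informative — while held-out drugs are absent
  from it, so an independent test never leaks structure through the panel.

A drug *pair* is the concatenation of the two profiles, ARV half first
(the database is asymmetric by construction; a configuration flag can
additionally train on the flipped orientation). With a panel of `R` drugs
the pair feature has length `2R`. An alternative featurizer contract
produces 768-dimensional embeddings per drug (pair feature length 1536);
the shipped backend is a deterministic stub — a fixed seeded random
projection of the merged fingerprint — standing in for an external
pretrained sequence model so the full pipeline runs offline. An
`embedding-external` adapter accepts any user function
`f(components) -> numeric(768)`; such an adapter must document its token
pooling choice, which external featurizers leave open.

## The imbalance machinery

Grade distributions in curated DDI databases are heavily skewed (roughly
72% Green, 7.6% Yellow, 16% Amber, 4.4% Red), and the rare Red class is the
clinically costly one. Two complementary devices address this:

* **Undersampling ensemble.** The majority grade is shuffled (seeded) and
  split into `k = 5` equal chunks of `floor(n_majority / k)` pairs; the at
  most `k - 1` leftover pairs are dropped and logged. Every minority pair
  is copied into all `k` subsets. One network per subset is trained and
  predictions are averaged (soft voting), so no majority information is
  discarded overall, yet each member sees a far flatter distribution.
* **Inverse-frequency class weights.** Within each training subset, class
  `c` receives loss weight `w_c = N / (C * n_c)` with `C` the number of
  classes present; each sample's cross-entropy term is multiplied by its
  class weight. This equalizes the total weighted mass per class
  (`n_c w_c` constant) and penalizes Red misclassification the most. The
  per-subset counts, not the pre-sampling counts, feed the formula, since
  the loss being reweighted is the member's own. Absent classes get weight
  0 and are excluded. With all counts equal every weight is 1, so the
  scheme degrades gracefully to plain training.

`k = 1` with weighting disabled reproduces the "single model" baseline the
ensemble is compared against.

## Network and training protocol

Members are feed-forward softmax classifiers over 4 classes. Two presets
reproduce the published optimized architectures — `"sim"`
({1024, 512, 256, 128} hidden units, ReLU) for similarity profiles and
`"embedding"` ({256, 128}, tanh) for embeddings — plus a light `"small"`
preset ({64, 32}, ReLU) used in this package's synthetic studies and test
suite, where input dimensions are an order of magnitude smaller than in
the motivating application. Training minimizes class-weighted sparse
categorical cross-entropy with Adam (learning rate 0.001, beta1 0.9, beta2
0.999, epsilon 1e-7) and dropout 0.2 after each hidden layer.

The training loop, batching and stopping rule are this package's choices
(the protocol behind "early stopping was applied" is otherwise
unspecified): batch size 128, at most 200 epochs, early stopping on the
weighted loss of a 10% stratified slice held back *inside* each training
subset with patience 10 and restoration of the best weights. Drawing the
stopping slice inside the subset — never from an outer validation fold —
prevents a subtle leak in cross-validated comparisons. Initialization is
He (ReLU) or Glorot (tanh), seeded; member `i` of an ensemble derives its
seed as `master seed + i`, so runs are bit-reproducible on one machine.
Exact argmax ties in soft voting resolve to the more severe grade — the
clinically conservative choice, configurable in principle but deliberate
as a default. A diverging (non-finite) loss aborts with diagnostics rather
than returning a silently broken member.

## Evaluation harness

Two complementary evaluations mirror how such models should be validated:

* **Stratified k-fold cross-validation** deals each grade round-robin into
  folds after a seeded shuffle, with the dealing pointer carried across
  grades, so per-fold class counts are within one pair of exact
  proportionality and fold sizes within one pair of each other. This
  measures in-distribution performance: test *pairs* are new, test *drugs*
  are not.
* **Drug-anchored hold-out** removes all pairs of selected ARVs; held-out
  drugs are never seen in training (nor in the reference panel). This is
  the stringent test of transfer to genuinely new chemistry.

Metrics are one-vs-rest per class: accuracy, precision, sensitivity,
specificity, F1 (`2TP / (2TP + FP + FN)`), balanced accuracy
(`(sensitivity + specificity) / 2`) and ROC-AUC computed on soft-voted
probabilities by pairwise concordance (ties half; identical to trapezoidal
integration of the ROC curve, which the tests verify to 1e-9). Aggregates
are the plain macro mean and the frequency-weighted macro
(`sum(n_i / N * metric_i)`). Reports also carry overall accuracy and
*macro sensitivity* (mean per-class recall), whose four-class chance level
is 0.25 — useful as a skew-robust chance reference, since the weighted
balanced accuracy of a chance classifier sits at 0.5 by construction.
Conventions for empty cells: precision and F1 are 0 when a class is never
predicted; a class absent from the truth carries zero aggregate weight and
an undefined (`NA`) AUC, which is reported as missing rather than
imputed. Confusion matrices are row-normalized (by true grade), matching
how per-grade correct-prediction rates are usually quoted.

## The synthetic data generator

Real graded DDI tables cannot be redistributed, so the generator emulates
their statistical shape well enough that every pipeline property is
testable offline:

* **Chemistry.** SMILES come from a seeded grammar: chains of small
  carbon/nitrogen/oxygen fragments on aromatic, aliphatic-ring, pyridine
  and ester scaffolds. Every candidate is validated by the chemistry
  toolkit and deduplicated on canonical form, so universes of hundreds of
  distinct, parseable molecules are generated in seconds. A configurable
  fraction of ARVs (rounded half up) become 2-3-component combinations.
* **Grade mechanism.** Each drug gets a latent pharmacology vector:
  `sigma * (seeded random projection of its fingerprint, standardized) +
  (1 - sigma) * per-drug seeded noise`, with `latent_dim = 16`. A pair's
  interaction score is a bilinear form of the two latents through a fixed
  seeded matrix; grades are assigned by exact rank quotas at the target
  proportions (largest-remainder rounding), so realized counts match
  targets exactly — a multinomial draw would not. The bilinear latent
  route, rather than rules on raw bits, gives a continuously tunable
  signal strength and guarantees the similarity premise: at `sigma = 1`
  structurally similar drugs provably have similar latents and hence
  correlated grade patterns.
* **What `sigma` does and does not switch off.** At `sigma = 0` grades
  depend only on per-drug noise latents. They are then independent of
  *chemistry*, but not of *drug identity* — and similarity profiles
  identify drugs (self-similarity 1). A pair-level stratified evaluation
  can therefore still beat chance at `sigma = 0` by memorizing drug
  effects. Chance-level behaviour (macro sensitivity near 0.25) is the
  correct expectation only under the drug-anchored split, where test
  drugs are unseen; the acceptance suite checks it there, and checks the
  learning bounds (weighted balanced accuracy at least 0.60 at
  `sigma = 1`, monotone in `sigma`) under the stratified evaluation that
  matches cross-validated training. This mirrors real data, where a model
  can interpolate known drugs far better than it extrapolates to new ones.
* **Defaults.** 25 ARVs x 200 comedications (5,000 pairs), combination
  fraction 0.2, proportions (0.72, 0.076, 0.16, 0.044), 8 held-out ARVs
  sampled across the synthetic ARV classes. A published-shape preset uses
  53 ARVs x 567 comedications with 9 held out, chosen because the
  generator's complete pair grid forces the independent-test size to be
  `holdout x n_comedications` and 9 x 567 factors the documented 5,103
  test pairs exactly, with the test block quota-graded to the documented
  per-class counts (3221, 358, 1146, 378).

What passing tests on this generator show: the feature path, imbalance
machinery, training loop and metric code interact correctly, recover a
planted structure-to-grade signal well above chance, and degrade to chance
when the signal is absent. What they cannot show: performance on real
pharmacology, where the structure-to-grade relation is far noisier and
non-bilinear, chemical space is more diverse, and grade assignments carry
curation noise. Synthetic accuracies are not forecasts of real-data
accuracy.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run the synthetic study at
5,000 pairs with the `"small"` network preset (120 epochs, patience 12),
three seeds per signal strength and five seeds for the ensemble-vs-single
comparison — sizes chosen so the full pipeline is exercised end-to-end many
times over in minutes on a single core. Tanimoto of two all-zero
fingerprints is defined as 0 with a warning (it cannot arise from valid
molecules). Gaussian naive Bayes variance smoothing follows the usual
convention (`var + var_smoothing * max feature variance`); exact density
underflows in its posterior are clamped at the smallest representable
double rather than flattening all small densities. Grid candidates whose
engine-level configurations coincide are fitted once with scores shared.

## Baseline engines

The comparison models keep the published hyperparameter grids as their
contract: Gaussian naive Bayes (priors in {(0.72, 0.076, 0.16, 0.044),
(0.1, 0.1, 0.3, 0.5)}, var_smoothing in {1e-9, 1e-8, 1e-7}), decision tree
(144 candidates) and random forest (432 candidates), searched exhaustively
with stratified seeded internal cross-validation scored by accuracy. The
estimator engines are e1071, rpart and ranger. Two grid knobs have no
equivalent in these engines and are enumerated but non-operative, which
the grid documentation states explicitly: per-split feature subsampling
(`max_features`) for the single tree — rpart always considers all features,
though the forest's `mtry` implements it — and `min_samples_split` for the
forest, where ranger only controls leaf size. `max_depth = None` maps to
the engine's unlimited setting, `criterion = entropy` to rpart's
information split, and `bootstrap = FALSE` to whole-data sampling without
replacement.

## Known limitations

* The similarity profile treats a combination product as one merged
  fingerprint; component-level interactions within a product are not
  modelled.
* The embedding stub preserves only fingerprint information; conclusions
  about a real pretrained featurizer require the external adapter.
* The generator's complete ARV x comedication grid is denser than real
  databases, which have missing pairs; readers should treat its absolute
  accuracies as pipeline diagnostics only.
* Training is plain R matrix arithmetic: ample for the panel-sized inputs
  used here, but the full 1376-input `"sim"` architecture at database
  scale would warrant a compiled backend.
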