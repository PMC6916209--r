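---
title: "Learning patient representations from EHR sequences with a denoising GRU autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning patient representations from EHR sequences with a denoising GRU autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepehr)
```

## The problem

A patient's electronic health record is a variable-length sequence of
hospital admissions, each carrying diagnoses, medication groups and lab
results. Most clinical classifiers want a fixed-length vector per patient,
and the standard workaround — summary statistics (mean, sum, max) of
per-admission features inside an observation window — throws away the
*order* of events. Whether a patient moved from stable to critical or the
reverse is invisible to an average.

`deepehr` learns a fixed-length "Deep Feature" vector per patient with a
denoising GRU sequence autoencoder (RNN-DAE), and provides the full
apparatus around it: the multi-hot record encoding, a synthetic cohort
generator with order-dependent outcomes, the window-based statistical
baselines it is compared against, supervised evaluations (mortality,
comorbidities, top-k), and a grid-mortality similarity heatmap.

## Record encoding

Each admission becomes a binary multi-hot vector over a fixed vocabulary:
one dimension per diagnosis code, one per medication group, and three per
lab test (high / low / normal relative to the test's reference range).
With the full-size vocabulary (1232 codes, 11 groups, 22 tests) this gives
a 1309-dimensional clinical vector; two demographic dimensions (min-max
normalized age, gender) make a 1311-dimensional raw record. A patient is
then an `n x d` binary tensor in admission order.

Choices the encoding fixes:

* **Lab flag boundaries are inclusive** — a value exactly at a reference
  bound counts as normal. Reference bounds mark the edge of the healthy
  range; flagging a boundary value as abnormal would alarm on healthy
  results.
* **Missing lab values set no flag** (all three dimensions zero), which is
  distinct from a reported normal.
* **Unknown codes warn and are dropped** by default; `strict = TRUE` turns
  them into errors. Real EHR extracts are noisy, and silently dropping
  events would hide data problems, while hard-failing on every stray code
  would make large dumps unusable.
* **Same-day admissions keep their file order** (stable sort).
* **Age bounds default to 0–120 years.**

Each patient with `n` admissions is split into `n` prefix samples (first
record, first two, ..., all `n`), and every prefix inherits the patient's
*final* death flag and comorbidity set. Early admissions labelled with the
eventual outcome are harder, more realistic prediction targets, and this is
the only labelling consistent with using every prefix as a training sample.
Note the ceiling this imposes: a one-record prefix of a patient who
deteriorated much later contains almost no outcome signal, so
cross-validated AUCs over prefix samples sit well below what full histories
would support.

## The model

The encoder is a single GRU without bias terms:

$$z_t = \sigma(W_z [h_{t-1}, x_t]), \quad r_t = \sigma(W_r [h_{t-1}, x_t]),$$
$$\tilde h_t = \tanh(W [r_t * h_{t-1}, x_t]), \quad
  h_t = (1 - z_t) * h_{t-1} + z_t * \tilde h_t,$$

run over the (corrupted) record rows from \(h_0 = 0\); the latent patient
vector \(c\) is the final hidden state. The decoder is a second GRU that
receives the *constant* input \(c\) at every step — no autoregressive
feedback, no teacher forcing — and its state \(s_t\) is mapped to a
reconstruction \(y_t \in (0,1)^d\). Training minimizes the summed
cross-entropy between the clean tensor and the reconstruction of its
corrupted version:

$$L(X, Y) = -\sum_{i=1}^{n}\sum_{j=1}^{d}
  \left[x_i^{(j)} \log y_i^{(j)} + (1 - x_i^{(j)}) \log (1 - y_i^{(j)})\right].$$

Corruption is i.i.d. Gaussian noise (mean 0, variance 0.1) applied to the
encoder input only, resampled at every presentation; setting the variance
to 0 gives the plain sequence autoencoder (RNN-AE) ablation. The Deep
Feature is `[normalized age, gender, c]` — 302 dimensions with the
full-size 300-dim latent. Demographics are appended, never fed to the
encoder, so `c` reflects clinical events alone.

**The output head.** The recurrences above define a decoder state of the
latent dimension `D`, but the cross-entropy needs outputs of the record
dimension `d` with entries strictly inside (0, 1). We therefore attach an
affine map `D -> d` followed by a logistic squash. This is the minimal head
satisfying both requirements, and the only place the implementation adds
parameters beyond the printed recurrences. A clamp of `1e-7` inside the
logs keeps the loss finite under saturated outputs.

Other numerical choices, all tested:

* **Initial states** \(h_0 = s_0 = 0\).
* **Optimizer**: Adam, learning rate `1e-3`, mini-batch 100. Training is
  specified only as mini-batch gradient descent; Adam is the default choice
  for this model family. The gradients are hand-derived and verified
  against finite differences to `1e-5` in the test suite.
* **Variable-length batching**: sequences are padded with zero rows to the
  batch maximum; a mask freezes encoder state updates past each true length
  (so `c` is the last *valid* state) and silences padded loss terms. The
  decoder needs no mask — padded steps receive zero loss gradient.
* **Bias vectors are off by default**, matching the bias-free recurrences;
  `use_bias = TRUE` adds them.
* **Reconstruction is forward-ordered** (first record first).

## The synthetic cohort generator

The hospital cohort this design emulates is private, so the generator
reproduces its statistical shape: ~4,682 patients averaging ~2.3 admissions (record count
`1 + Poisson(1.3)`, truncated at 10), an in-hospital death rate calibrated
to 12.1%, and ten comorbidity labels at the published prevalences
(hypertension 0.694 down to valvular disease 0.008).

Each patient follows a three-state latent Markov chain — stable, worsening,
critical — and each admission emits events from state-conditional
distributions: diagnosis codes drawn mostly (90%) from the current state's
20-code block, medication groups shifted toward higher indices in worse
states, and lab values whose dispersion around the reference midpoint grows
with the state (so abnormal flags become frequent when critical). Carriers
of a comorbidity additionally plant marker codes in about half their
records. Emission strengths are set so that the latent state is decodable
from a handful of records; with weaker emissions no desk-scale method —
sequential or not — rises meaningfully above chance, and the comparison the
generator exists to support becomes vacuous.

Death is drawn from a logistic model on the **final state** and the
**trajectory slope** (states ascending toward critical vs. descending),
with the intercept found by root-search so the expected death rate hits the
target exactly. The slope term is the deliberate order dependence:
two patients with identical event *frequencies* but opposite trajectories
have different risks, which no window statistic can express.
`order_sensitivity_probe()` certifies this on any generated cohort by
comparing death prevalence between ascending and descending trajectories
within record-count strata.

Admission dates start at a random point and advance by uniform 10–200 day
gaps, so 30/60/90/180-day observation windows genuinely truncate
histories. The gap law is a modelling choice; nothing in the emulated cohort's
published summaries constrains it.

What the generator does *not* emulate: real ICD-10 semantics or code
hierarchies, coding noise, informative missingness, visit-frequency
dependence on severity, or censoring. Passing tests on this cohort show
that the pipeline recovers planted structure, not that it would reach any
particular performance on hospital data.

## Baselines and evaluation

The window-based representations aggregate the multi-hot rows inside an
observation window (default 180 days before and including the last
admission) by elementwise mean, then optionally transform: PCA scores,
the assigned k-means centroid, or the diagonal covariance vector of the
most responsible Gaussian mixture component (mixtures restricted to
diagonal models). Study-scale settings are 512 PCA components, 16 clusters
and 512 mixture components; the scaled-down schema uses proportionally
smaller values since components cannot exceed the data dimension. All four
are order-invariant by construction — the property the test suite asserts
jointly with the encoder's order *sensitivity*.

Supervised evaluation uses stratified 5-fold cross-validation **grouped at
the patient level** (all prefix samples of a patient share a fold), because
prefixes of one patient are near-duplicates and splitting them across folds
would leak. The classifier default is an RBF SVM with Platt probability
estimates; accuracy and F1 are computed at the stated 0.8 score threshold,
AUC from rank statistics. Tasks whose positive prevalence is below 30% are
rebalanced in the training folds with NearMiss-1 (keep the majority samples
with the smallest mean distance to their 3 nearest minority neighbours);
test folds are never resampled, so reported metrics reflect the natural
class balance. One visible consequence: probabilities fitted on rebalanced
folds are calibrated to a 50% base rate, which inflates scores on the
unbalanced test fold and drags threshold-0.8 accuracy well below what a
calibrated model would show. AUC, being rank-based, is unaffected.

Top-k comorbidity prediction scores every label per patient with its own
cross-validated classifier, predicts the k highest-scoring labels, and
reports the mean fraction correct; the theoretical upper bound is
`min(|true set|, k) / k` averaged over patients. Patients with no
comorbidity at all are excluded from both means (the bound is undefined for
them), which makes the k = 1 bound exactly 1 here; a protocol that kept
zero-comorbidity patients in the mean would show a k = 1 bound slightly
below 1.

## Problem sizes used by the tests and the acceptance script

Desk-scale runs keep the full architecture but shrink the free sizes: the
synthetic schema has 102 diagnosis codes (60 progression-linked + 42
markers and padding), latent dimension 16–32 instead of 300, and cohorts of
400–5,000 patients. The method-comparison runs use 2,000 patients
(~4,600 prefix samples), a 32-dim latent trained 30 epochs, and three
independent seeds, taking the median. The dimension-contract checks
(1309/1311/302) run the full-size vocabulary through an initialized model,
since dimensions do not depend on the weights.

At this scale the mortality comparison reproduces the *ordering* —
Deep Features beat averaged raw features, with the denoising variant
reported against the plain autoencoder — but not the magnitudes reported on
the original hospital cohort, which is richer and not publicly available. On comorbidity
tasks the small latent visibly compresses away rare marker codes, so the
window statistics (which see marker columns directly) win there; the same
"no single representation wins every task" pattern is typical of real
multi-task comparisons as well. The acceptance script reports both representations'
comorbidity metrics for that reason.

## Known limitations

* Exact t-SNE (quadratic memory/time) caps similarity analyses at a few
  thousand points; the pipeline subsamples beyond that.
* The GMM representation can be slow at full-scale component counts;
  mixtures are fit with diagonal models only.
* Training is plain R linear algebra — fine for desk-scale latents,
  not for 300-dim latents over millions of records.
* NearMiss-1 with very small minorities (a handful of points) can select
  pathological majority subsets; the generator's rarest task (prevalence
  0.008) sits at that edge and its per-task metrics are accordingly noisy.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 1))
samples <- encode_samples(cohort$patients, cohort$schema)
model <- train_rnn_dae(samples$tensors, latent_dim = 16, epochs = 10,
                       seed = 2, schema = cohort$schema)
feats <- deep_features(cohort$patients, model, cohort$schema)
evaluate_mortality(feats$features, feats$labels$died,
                   feats$labels$patient_id, eval_config(seed = 3))
```
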