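# deepehr

Patient representation learning from longitudinal electronic health
records with a denoising GRU sequence autoencoder.

## What it does, and for whom

Clinical prediction models need a fixed-length vector per patient, but an
EHR is a variable-length *sequence* of admissions. The common fix —
averaging per-admission features over an observation window — discards the
order of events, and with it the difference between a patient who is
deteriorating and one who is recovering. `deepehr` is for clinical
informatics researchers who want order-aware patient vectors plus the full
evaluation harness to judge whether they help.

Each admission is encoded as a binary multi-hot vector over a fixed
vocabulary (one dimension per diagnosis code and medication group, three
high/low/normal flag dimensions per lab test; 1309 clinical dimensions at
the full vocabulary size). A patient is the chronological `n x d` tensor
of these rows. A GRU encoder reads a Gaussian-corrupted copy of the tensor,

    z_t = σ(W_z [h_{t-1}, x_t])
    r_t = σ(W_r [h_{t-1}, x_t])
    h̃_t = tanh(W [r_t ∗ h_{t-1}, x_t])
    h_t = (1 − z_t) ∗ h_{t-1} + z_t ∗ h̃_t

and its final hidden state `c` summarizes the sequence. A decoder GRU,
driven at every step by the constant input `c`, reconstructs the *clean*
tensor through a logistic output head, minimizing the summed binary
cross-entropy `L(X, Y) = −Σ_ij [x_ij log y_ij + (1 − x_ij) log(1 − y_ij)]`.
The "Deep Feature" is `[normalized age, gender, c]` — 302 dimensions with
the full-size 300-dim latent. Because the objective is unsupervised
reconstruction, one trained encoder serves every downstream task.

The package also provides:

* a synthetic longitudinal cohort generator (3-state latent disease
  progression, calibrated 12.1% death rate, published comorbidity
  prevalences, deliberately order-dependent mortality) so everything runs
  without protected data;
* the window-based baselines: averaged raw features ("Hand"), PCA,
  k-means centroids, diagonal-covariance GMM covariance vectors;
* patient-level stratified cross-validated evaluation (SVM/RF/GBDT/kNN/
  LR/NB), NearMiss-1 undersampling below 30% prevalence, threshold-0.8
  accuracy/F1, rank-based AUC, per-comorbidity tasks with average-rank
  comparison, and top-k comorbidity accuracy with its theoretical upper
  bound;
* t-SNE projection of the features with a 30×30 grid-mortality heatmap
  using the smoothed rate `H = K / (N + F)`, `F = 5`.

## Worked example

```r
library(deepehr)

cohort  <- generate_cohort(cohort_config(n_patients = 500, seed = 1))
samples <- encode_samples(cohort$patients, cohort$schema)
model   <- train_rnn_dae(samples$tensors, latent_dim = 16, epochs = 10,
                         seed = 2, schema = cohort$schema)
feats   <- deep_features(cohort$patients, model, cohort$schema)
res     <- evaluate_mortality(feats$features, feats$labels$died,
                              feats$labels$patient_id, eval_config(seed = 3))
probe   <- order_sensitivity_probe(cohort)
```

Output of this exact script:

```
patients: 500   death rate: 0.12
prefix samples: 1141   record dim: 157
first/final epoch loss: 208.4 / 103.6
deep feature dim: 18   mortality AUC: 0.568
ascending-vs-descending death gap: 0.407
```

Reading it: the generator hit its calibrated 12.1% death rate (0.12
empirically); 500 patients yielded 1141 prefix samples over a 157-dim
scaled-down vocabulary; ten epochs halved the reconstruction loss; the
16-dim latent plus two demographic entries gives an 18-dim Deep Feature;
and the 0.407 death-prevalence gap between ascending (toward critical) and
descending latent trajectories is the planted order signal that
frequency-based representations cannot see. Cross-validated AUC over
prefix samples is modest by construction — early prefixes carry the
patient's final outcome label but few of the events that explain it.

A YAML-configured end-to-end run (simulate → encode → train → featurize →
evaluate → heatmap) is available as `run_pipeline()` or through the thin
CLI at `inst/cli/deepehr`:

```sh
inst/cli/deepehr simulate --n 500 --seed 1 --output patients.jsonl
inst/cli/deepehr validate --input patients.jsonl
```

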