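# Shared fixtures, built in code. Heavy objects (cohorts, trained models)
# are cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Minimal 17-dim schema: 3 diagnoses + 2 medication groups + 4 lab tests.
tiny_schema <- function() {
  build_schema(
    c("A", "B", "C"), c("M1", "M2"),
    data.frame(test_id = c("T1", "T2", "T3", "T4"),
               ref_low = c(1, 10, 0, 5), ref_high = c(2, 20, 1, 15))
  )
}

tiny_record <- function(id = "r1", date = "2020-01-01", dx = character(),
                        med = character(), lab = numeric()) {
  clinical_record(id, date, diagnoses = dx, medications = med,
                  lab_results = lab)
}

tiny_patient <- function(n_records = 3, id = "p1", died = 0,
                         comorbidities = character()) {
  recs <- lapply(seq_len(n_records), function(i) {
    tiny_record(paste0("r", i), as.Date("2020-01-01") + 30 * (i - 1),
                dx = c("A", "B")[1 + i %% 2], med = "M1",
                lab = c(T1 = 1.5))
  })
  patient_history(id, 60, 1, recs, died = died,
                  comorbidities = comorbidities)
}

# Small cohort for fast unit tests.
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(cohort_config(n_patients = 150, seed = 42))
  })
}

# Mid-size cohort with a trained model, shared by the training-behaviour,
# order-sensitivity and robustness tests.
trained_fixture <- function() {
  cached("trained_fixture", function() {
    cohort <- generate_cohort(cohort_config(n_patients = 400, seed = 7))
    es <- encode_samples(cohort$patients, cohort$schema)
    model <- train_rnn_dae(es$tensors, latent_dim = 16, epochs = 8,
                           seed = 11, schema = cohort$schema)
    list(cohort = cohort, samples = es, model = model)
  })
}

# Independent step-by-step evaluation of the GRU recurrences and the
# decoder head, written with explicit scalar loops (no shared code with the
# package implementation).
oracle_gru_forward <- function(X, Wz, Wr, W, h0 = NULL) {
  H <- nrow(Wz)
  h <- if (is.null(h0)) rep(0, H) else h0
  for (t in seq_len(nrow(X))) {
    cx <- c(h, X[t, ])
    z <- r <- numeric(H)
    for (i in 1:H) {
      z[i] <- 1 / (1 + exp(-sum(Wz[i, ] * cx)))
      r[i] <- 1 / (1 + exp(-sum(Wr[i, ] * cx)))
    }
    cx2 <- c(r * h, X[t, ])
    cand <- numeric(H)
    for (i in 1:H) cand[i] <- tanh(sum(W[i, ] * cx2))
    h <- (1 - z) * h + z * cand
  }
  h
}

oracle_decoder <- function(cvec, n, Wz, Wr, W, V, b) {
  H <- nrow(Wz)
  s <- rep(0, H)
  Y <- matrix(0, n, nrow(V))
  for (t in seq_len(n)) {
    s <- oracle_gru_forward(matrix(cvec, 1), Wz, Wr, W, h0 = s)
    for (j in seq_len(nrow(V))) {
      Y[t, j] <- 1 / (1 + exp(-(sum(V[j, ] * s) + b[j])))
    }
  }
  Y
}

# All-pairs AUC oracle.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
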