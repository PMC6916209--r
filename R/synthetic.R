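#' Schema used by the synthetic cohort generator
#'
#' A scaled-down vocabulary for fast experiments: 60 progression-linked
#' diagnosis codes (20 per latent state), 2 marker codes per comorbidity,
#' 11 medication groups and 22 lab tests. Pass `full_size = TRUE` for the
#' 1232-code preset used in dimension-fidelity checks.
#'
#' @param comorbidity_labels labels needing marker codes.
#' @param full_size pad the diagnosis vocabulary to 1232 codes.
#' @return an `ehr_schema`.
#' @export
synthetic_schema <- function(comorbidity_labels = names(default_comorbidity_prevalences()),
                             full_size = FALSE) {
  state_codes <- sprintf("D%03d", seq_len(60))
  marker_codes <- as.vector(t(outer(comorbidity_labels, 1:2,
                                    function(l, i) paste0("CM_", l, "_", i))))
  codes <- c(state_codes, marker_codes)
  if (full_size) {
    pad <- sprintf("PAD%04d", seq_len(1232 - length(codes)))
    codes <- c(codes, pad)
  }
  build_schema(
    codes,
    sprintf("MG%02d", seq_len(11)),
    data.frame(test_id = sprintf("LT%02d", seq_len(22)),
               ref_low = 10, ref_high = 20)
  )
}

#' Comorbidity prevalences emulated by the generator
#'
#' Ten heart-failure comorbidities with the prevalences of the emulated hospital cohort
#' (hypertension 0.694 down to valvular heart disease 0.008).
#'
#' @return named numeric vector of fractions.
#' @export
default_comorbidity_prevalences <- function() {
  c(hypertension = 0.694, diabetes = 0.359, coronary_artery = 0.496,
    atrial_fibrillation = 0.299, chronic_renal = 0.088, valvular = 0.008,
    dilated_cardiomyopathy = 0.031, hypertrophic_cardiomyopathy = 0.014,
    copd = 0.080, cerebral_infarction = 0.252)
}

#' Configuration of the synthetic cohort generator
#'
#' Patients follow a 3-state latent Markov chain (stable, worsening,
#' critical). Each admission emits diagnoses, medications and lab values
#' from state-conditional distributions; in-hospital death is drawn from a
#' logistic model on the final latent state and the trajectory slope, with
#' the intercept calibrated so the expected death rate matches
#' `target_death_rate`. Mortality depending on the slope as well as the
#' final state is what makes the outcome order-dependent: record-order
#' statistics (mean/sum/max) cannot see it, sequence encoders can.
#'
#' @param n_patients cohort size.
#' @param mean_records_per_patient mean admissions per patient (record count
#'   is `1 + Poisson(mean - 1)` truncated at `max_records`).
#' @param max_records truncation for the record count.
#' @param transition_matrix row-stochastic 3x3 latent transition matrix.
#' @param initial_probs initial state distribution.
#' @param mortality_final_weights logistic weights on the final state
#'   (stable, worsening, critical).
#' @param mortality_slope_weight logistic weight on the per-step state slope.
#' @param target_death_rate expected in-hospital death fraction.
#' @param comorbidity_prevalences named fractions; each comorbidity plants
#'   marker diagnosis codes into the carrier's records.
#' @param marker_rate per-record probability that a carrier's record shows a
#'   given marker code.
#' @param seed integer RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 4682,
                          mean_records_per_patient = 2.3,
                          max_records = 10,
                          transition_matrix = rbind(
                            c(0.70, 0.25, 0.05),
                            c(0.20, 0.60, 0.20),
                            c(0.05, 0.25, 0.70)),
                          initial_probs = c(0.55, 0.30, 0.15),
                          mortality_final_weights = c(0, 1.6, 3.2),
                          mortality_slope_weight = 3,
                          target_death_rate = 0.121,
                          comorbidity_prevalences = default_comorbidity_prevalences(),
                          marker_rate = 0.5,
                          seed = 1L) {
  tm <- as.matrix(transition_matrix)
  if (any(dim(tm) != 3) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8)) {
    stop("transition_matrix must be a row-stochastic 3x3 matrix")
  }
  if (any(initial_probs < 0) || abs(sum(initial_probs) - 1) > 1e-8) {
    stop("initial_probs must be a probability vector")
  }
  if (any(comorbidity_prevalences < 0 | comorbidity_prevalences > 1)) {
    stop("comorbidity prevalences must lie in [0, 1]")
  }
  if (target_death_rate <= 0 || target_death_rate >= 1) {
    stop("target_death_rate must lie in (0, 1)")
  }
  if (mean_records_per_patient < 1) stop("mean records must be >= 1")
  structure(list(
    n_patients = as.integer(n_patients),
    mean_records_per_patient = mean_records_per_patient,
    max_records = as.integer(max_records),
    transition_matrix = tm,
    initial_probs = initial_probs,
    mortality_final_weights = mortality_final_weights,
    mortality_slope_weight = mortality_slope_weight,
    target_death_rate = target_death_rate,
    comorbidity_prevalences = comorbidity_prevalences,
    marker_rate = marker_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Linear predictor of the death model, without intercept.
mortality_eta <- function(states, config) {
  n <- length(states)
  final <- states[n]
  slope <- if (n > 1) (states[n] - states[1]) / (n - 1) else 0
  config$mortality_final_weights[final] + config$mortality_slope_weight * slope
}

#' Generate a synthetic longitudinal cohort
#'
#' Deterministic given `config$seed`. Each patient carries its latent state
#' trajectory in `$states` (ground truth for diagnostics; no downstream
#' method sees it).
#'
#' @param config a [cohort_config()].
#' @param schema optional `ehr_schema`; defaults to [synthetic_schema()]
#'   for the configured comorbidity labels.
#' @return list with `patients` (list of `ehr_patient`), `schema`, `config`
#'   and the calibrated logistic `intercept`.
#' @export
generate_cohort <- function(config = cohort_config(), schema = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- names(config$comorbidity_prevalences)
  if (is.null(schema)) schema <- synthetic_schema(labels)
  with_seed(config$seed, {
    n <- config$n_patients
    # latent trajectories
    lens <- pmin(1L + stats::rpois(n, config$mean_records_per_patient - 1),
                 config$max_records)
    trajs <- lapply(lens, function(L) {
      s <- integer(L)
      s[1] <- sample.int(3L, 1, prob = config$initial_probs)
      if (L > 1) for (t in 2:L) {
        s[t] <- sample.int(3L, 1, prob = config$transition_matrix[s[t - 1], ])
      }
      s
    })
    # calibrate the intercept so E[death] hits the target
    eta <- vapply(trajs, mortality_eta, 0, config = config)
    f <- function(b0) mean(stats::plogis(b0 + eta)) - config$target_death_rate
    if (f(-30) > 0 || f(30) < 0) {
      stop("target death rate ", config$target_death_rate,
           " unreachable under the configured mortality weights")
    }
    intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    died <- stats::rbinom(n, 1, stats::plogis(intercept + eta))

    # comorbidities: independent Bernoulli draws at the configured prevalence
    comorb <- vapply(config$comorbidity_prevalences,
                     function(p) stats::rbinom(n, 1, p) == 1,
                     logical(n))
    if (n == 1) comorb <- matrix(comorb, nrow = 1, dimnames = list(NULL, labels))

    ages <- pmin(pmax(round(stats::rnorm(n, 70, 12)), 18), 100)
    genders <- stats::rbinom(n, 1, 0.5)
    state_groups <- list(1:20, 21:40, 41:60)

    patients <- vector("list", n)
    for (i in seq_len(n)) {
      st <- trajs[[i]]
      t0 <- as.Date("2010-01-01") + sample.int(2000, 1)
      gaps <- if (lens[i] > 1) round(stats::runif(lens[i] - 1, 10, 200)) else numeric()
      dates <- t0 + c(0, cumsum(gaps))
      my_cms <- labels[comorb[i, ]]
      recs <- vector("list", lens[i])
      for (t in seq_len(lens[i])) {
        s <- st[t]
        # diagnoses: mostly from the current state's code group, some leakage
        k <- 1L + stats::rpois(1, 4)
        grp <- ifelse(stats::runif(k) < 0.9, s, sample.int(3L, k, replace = TRUE))
        dxi <- vapply(grp, function(g) sample(state_groups[[g]], 1), 0L)
        dx <- sprintf("D%03d", unique(dxi))
        # comorbidity marker codes
        for (cm in my_cms) {
          for (j in 1:2) {
            if (stats::runif(1) < config$marker_rate) {
              dx <- c(dx, paste0("CM_", cm, "_", j))
            }
          }
        }
        # medications: higher-index groups used more in worse states
        nmed <- 1L + stats::rpois(1, 1.5)
        wmed <- stats::dnorm(seq_len(11), mean = 2 + 3.5 * (s - 1), sd = 2)
        med <- sprintf("MG%02d", unique(sample.int(11L, nmed, replace = TRUE,
                                                   prob = wmed)))
        # lab values: dispersion around the reference midpoint grows with state
        report <- which(stats::runif(22) < 0.5)
        lab <- stats::rnorm(length(report), 15, c(1, 3, 7)[s])
        names(lab) <- sprintf("LT%02d", report)
        recs[[t]] <- clinical_record(
          paste0("P", i, "R", t), dates[t],
          diagnoses = dx, medications = med, lab_results = lab)
      }
      p <- patient_history(paste0("P", i), ages[i], genders[i], recs,
                           died = died[i], comorbidities = my_cms)
      p$states <- st
      patients[[i]] <- p
    }
    list(patients = patients, schema = schema, config = config,
         intercept = intercept)
  })
}

#' Read / write a cohort configuration as YAML
#' @param path file path.
#' @return [read_cohort_config()]: a `cohort_config`;
#'   [write_cohort_config()]: `path`.
#' @export
read_cohort_config <- function(path) {
  o <- yaml::read_yaml(path)
  o$transition_matrix <- do.call(rbind, o$transition_matrix)
  o$comorbidity_prevalences <- unlist(o$comorbidity_prevalences)
  do.call(cohort_config, o)
}

#' @rdname read_cohort_config
#' @param config a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  o <- unclass(config)
  o$transition_matrix <- lapply(seq_len(nrow(o$transition_matrix)),
                                function(i) as.numeric(o$transition_matrix[i, ]))
  o$comorbidity_prevalences <- as.list(o$comorbidity_prevalences)
  yaml::write_yaml(o, path)
  invisible(path)
}

#' Probe order dependence of the synthetic outcome
#'
#' Compares death prevalence between multi-record patients whose latent
#' trajectory ascends (toward the critical state) and those whose descends,
#' within record-count strata, and returns the count-weighted mean gap.
#' A positive gap certifies that record order carries outcome information
#' that frequency statistics discard.
#'
#' @param cohort output of [generate_cohort()].
#' @return list with `gap`, `n_ascending`, `n_descending` and the per-stratum
#'   table.
#' @export
order_sensitivity_probe <- function(cohort) {
  ps <- cohort$patients
  multi <- Filter(function(p) length(p$records) >= 2, ps)
  if (!length(multi)) stop("cohort has no multi-record patients")
  slope <- vapply(multi, function(p) {
    s <- p$states
    (s[length(s)] - s[1]) / (length(s) - 1)
  }, 0)
  died <- vapply(multi, `[[`, 0L, "died")
  nrec <- vapply(multi, function(p) length(p$records), 0L)
  dir <- ifelse(slope > 0, "ascending", ifelse(slope < 0, "descending", "flat"))
  keep <- dir != "flat"
  if (!any(keep)) return(list(gap = 0, n_ascending = 0L, n_descending = 0L,
                              strata = NULL))
  tab <- stats::aggregate(died[keep],
                          by = list(n = nrec[keep], dir = dir[keep]),
                          FUN = mean)
  cnt <- stats::aggregate(died[keep],
                          by = list(n = nrec[keep], dir = dir[keep]),
                          FUN = length)
  tab$count <- cnt$x
  wide <- merge(tab[tab$dir == "ascending", c("n", "x", "count")],
                tab[tab$dir == "descending", c("n", "x", "count")],
                by = "n", suffixes = c("_asc", "_desc"))
  if (!nrow(wide)) return(list(gap = 0,
                               n_ascending = sum(dir == "ascending"),
                               n_descending = sum(dir == "descending"),
                               strata = tab))
  w <- wide$count_asc + wide$count_desc
  gap <- sum((wide$x_asc - wide$x_desc) * w) / sum(w)
  list(gap = gap,
       n_ascending = sum(dir == "ascending"),
       n_descending = sum(dir == "descending"),
       strata = wide)
}
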