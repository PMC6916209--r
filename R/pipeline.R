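#' Read and check a pipeline run configuration
#'
#' YAML with the keys `seed`, `output_dir`, and optional stage blocks
#' `input` (path to an existing patients file instead of simulating),
#' `simulate`, `train`, `evaluate`, `heatmap`. Unknown keys are rejected so
#' typos fail loudly; the file round-trips losslessly.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  as_run_config(o)
}

#' @rdname read_run_config
#' @param config a named list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  allowed <- c("seed", "output_dir", "input", "schema", "simulate", "train",
               "evaluate", "heatmap")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$output_dir)) stop("config is missing field: output_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = "run_config")
}

# Cheap structural fingerprint of a config (stamped into artifacts/logs).
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 100000000
}

log_stage <- function(logpath, stage, seconds, ...) {
  rec <- c(list(stage = stage, seconds = round(seconds, 3)), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logpath, append = TRUE, sep = "")
}

#' Run the whole pipeline
#'
#' Executes simulate (or load) -> encode -> train -> featurize (deep and
#' hand) -> evaluate mortality -> grid-mortality heatmap table, writing
#' every artifact plus a line-delimited JSON log (stage timings, record
#' counts, config hash) under `output_dir`. Each stage draws its seed from
#' the global seed through a fixed fan-out, so stages are independently
#' reproducible and a re-run with the same config is identical.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @return invisibly, a list of the main in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  config <- as_run_config(unclass(config))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  logpath <- out("pipeline_log.jsonl")
  if (file.exists(logpath)) unlink(logpath)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e) {
      log_stage(logpath, name, proc.time()[3] - t0, error = conditionMessage(e),
                config_hash = hash)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    r
  }

  # --- simulate / load
  t0 <- proc.time()[3]
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      stop("pipeline stage 'simulate' failed: input file not found: ",
           config$input)
    }
    patients <- stage("load", read_patients(config$input))
    schema <- if (!is.null(config$schema)) read_schema(config$schema) else
      synthetic_schema()
  } else {
    sim <- config$simulate %||% list()
    cc <- cohort_config(
      n_patients = sim$n_patients %||% 500,
      mean_records_per_patient = sim$mean_records_per_patient %||% 2.3,
      target_death_rate = sim$target_death_rate %||% 0.121,
      seed = stage_seed(config$seed, "simulate"))
    cohort <- stage("simulate", generate_cohort(cc))
    patients <- cohort$patients
    schema <- cohort$schema
    write_patients(patients, out("patients.jsonl"))
    write_schema(schema, out("schema.yaml"))
  }
  nrec <- sum(vapply(patients, function(p) length(p$records), 0L))
  log_stage(logpath, "simulate", proc.time()[3] - t0, config_hash = hash,
            patients = length(patients), records = nrec,
            death_rate = mean(vapply(patients, `[[`, 0L, "died")))

  # --- encode
  t0 <- proc.time()[3]
  es <- stage("encode", encode_samples(patients, schema))
  log_stage(logpath, "encode", proc.time()[3] - t0, samples = length(es$tensors),
            dim = schema_dim(schema))

  # --- train
  t0 <- proc.time()[3]
  tr <- config$train %||% list()
  model <- stage("train", train_rnn_dae(
    es$tensors,
    latent_dim = tr$latent_dim %||% 32,
    noise_var = tr$noise_var %||% 0.1,
    batch_size = tr$batch_size %||% 100,
    epochs = tr$epochs %||% 15,
    lr = tr$lr %||% 1e-3,
    seed = stage_seed(config$seed, "train"),
    schema = schema))
  save_model(model, out("model.json"))
  log_stage(logpath, "train", proc.time()[3] - t0,
            first_epoch_loss = model$training_log[1],
            final_epoch_loss = utils::tail(model$training_log, 1))

  # --- featurize
  t0 <- proc.time()[3]
  deep <- stage("featurize", deep_features(patients, model, schema))
  utils::write.csv(cbind(deep$labels[c("patient_id", "prefix_length")],
                         as.data.frame(deep$features)),
                   out("features_deep.csv"), row.names = FALSE)
  hand <- stage("featurize", baseline_features(
    patients, schema, method = "hand",
    window_days = (config$evaluate %||% list())$window_days %||% 180))
  utils::write.csv(cbind(hand$labels[c("patient_id", "prefix_length")],
                         as.data.frame(hand$features)),
                   out("features_hand.csv"), row.names = FALSE)
  log_stage(logpath, "featurize", proc.time()[3] - t0,
            deep_dim = ncol(deep$features), hand_dim = ncol(hand$features))

  # --- evaluate mortality (Deep vs Hand)
  t0 <- proc.time()[3]
  ev <- config$evaluate %||% list()
  cfg <- eval_config(classifier = ev$classifier %||% "svm",
                     threshold = ev$threshold %||% 0.8,
                     folds = ev$folds %||% 5,
                     seed = stage_seed(config$seed, "eval"))
  res <- stage("evaluate", {
    rbind(
      cbind(method = "deep", as.data.frame(
        evaluate_mortality(deep$features, deep$labels$died,
                           deep$labels$patient_id, cfg)[c("auc", "accuracy", "f1")])),
      cbind(method = "hand", as.data.frame(
        evaluate_mortality(hand$features, hand$labels$died,
                           hand$labels$patient_id, cfg)[c("auc", "accuracy", "f1")])))
  })
  utils::write.csv(res, out("eval_mortality.csv"), row.names = FALSE)
  log_stage(logpath, "evaluate", proc.time()[3] - t0,
            auc_deep = res$auc[res$method == "deep"],
            auc_hand = res$auc[res$method == "hand"])

  # --- heatmap table
  t0 <- proc.time()[3]
  hm <- config$heatmap %||% list()
  nmax <- hm$subsample %||% 1500
  idx <- if (nrow(deep$features) > nmax) {
    with_seed(stage_seed(config$seed, "heatmap"), sample.int(nrow(deep$features), nmax))
  } else seq_len(nrow(deep$features))
  grid <- stage("heatmap", {
    emb <- project_2d(deep$features[idx, , drop = FALSE],
                      deep$labels$died[idx],
                      seed = stage_seed(config$seed, "heatmap"),
                      perplexity = hm$perplexity %||% 30,
                      max_iter = hm$max_iter %||% 250)
    mortality_grid(grid_assign(emb, g = hm$grid %||% 30), emb$died,
                   g = hm$grid %||% 30, F = hm$smooth %||% 5)
  })
  utils::write.csv(as.data.frame(grid), out("heatmap_blocks.csv"),
                   row.names = FALSE)
  log_stage(logpath, "heatmap", proc.time()[3] - t0,
            blocks = nrow(grid), max_rate = max(grid$H))

  invisible(list(patients = patients, schema = schema, model = model,
                 deep = deep, hand = hand, mortality = res, grid = grid))
}

#' Validate a patients file and summarize the cohort
#'
#' Checks per-line structural invariants (parseable JSON, required fields,
#' ISO dates, chronologically sorted records) and reports cohort statistics:
#' patient/record counts, death rate and per-comorbidity prevalence.
#' Malformed lines are reported with their line numbers; validation
#' continues past them.
#'
#' @param path patients JSONL file.
#' @return list of class `validation_report` with `n_patients`, `n_records`,
#'   `death_rate`, `comorbidity_prevalence` (data.frame: label, count,
#'   percent), and `errors` (data.frame: line, message).
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  errors <- list()
  patients <- list()
  for (ln in seq_along(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    res <- tryCatch({
      o <- jsonlite::fromJSON(lines[ln], simplifyDataFrame = FALSE)
      for (f in c("patient_id", "age", "gender", "died", "records")) {
        if (is.null(o[[f]])) stop("missing field: ", f)
      }
      if (!length(o$records)) stop("no records")
      dates <- vapply(o$records, function(r) {
        d <- tryCatch(as.Date(r$admission_time), error = function(e) as.Date(NA))
        if (is.na(d)) stop("unparseable admission_time: ", r$admission_time)
        as.character(d)
      }, "")
      if (is.unsorted(as.Date(dates))) {
        stop("records not sorted by admission_time (auto-sortable)")
      }
      o
    }, error = function(e) {
      errors[[length(errors) + 1]] <<- data.frame(
        line = ln, message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) patients[[length(patients) + 1]] <- res
  }
  died <- vapply(patients, function(p) as.integer(p$died), 0L)
  nrec <- vapply(patients, function(p) length(p$records), 0L)
  cms <- unlist(lapply(patients, function(p) unlist(p$comorbidities)))
  cm_tab <- if (length(cms)) {
    t <- sort(table(cms), decreasing = TRUE)
    data.frame(label = names(t), count = as.integer(t),
               percent = round(as.integer(t) / length(patients), 3))
  } else data.frame(label = character(), count = integer(), percent = numeric())
  structure(list(
    n_patients = length(patients), n_records = sum(nrec),
    death_rate = if (length(died)) mean(died) else NA_real_,
    comorbidity_prevalence = cm_tab,
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(line = integer(), message = character())
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$n_patients, "patients,", x$n_records,
      "records, death rate", round(x$death_rate, 3), "\n")
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat("  line", x$errors$line[i], ":", x$errors$message[i], "\n")
    }
  } else cat("no errors\n")
  if (nrow(x$comorbidity_prevalence)) {
    print(x$comorbidity_prevalence, row.names = FALSE)
  }
  invisible(x)
}
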