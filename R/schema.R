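#' Build a clinical-event encoding schema
#'
#' The schema fixes the vocabulary that maps clinical events to positions of
#' a multi-hot vector. Positions are partitioned, in order, into diagnosis
#' codes (one dimension each), medication groups (one each) and lab tests
#' (three each: high / low / normal flags). The clinical dimension is
#' `d = |diagnoses| + |medications| + 3 * |lab tests|`; a raw record adds two
#' demographic dimensions (normalized age, gender) on top, giving `d + 2`.
#'
#' @param diagnosis_codes character vector of unique diagnosis code strings.
#' @param medication_groups character vector of unique medication group names
#'   (may be empty).
#' @param lab_tests `data.frame` with columns `test_id`, `ref_low`,
#'   `ref_high` (reference range; `ref_low < ref_high`), or `NULL` for none.
#' @param age_bounds numeric length-2, the age range (years) used for min-max
#'   age normalization. Default 0--120.
#' @return An object of class `ehr_schema`.
#' @examples
#' sch <- build_schema(c("I10", "I50"), "ACEI",
#'   data.frame(test_id = "K", ref_low = 3.5, ref_high = 5.5))
#' schema_dim(sch)  # 2 + 1 + 3
#' @export
build_schema <- function(diagnosis_codes, medication_groups = character(),
                         lab_tests = NULL, age_bounds = c(0, 120)) {
  diagnosis_codes <- as.character(diagnosis_codes)
  medication_groups <- as.character(medication_groups)
  if (length(diagnosis_codes) + length(medication_groups) == 0 &&
      (is.null(lab_tests) || nrow(lab_tests) == 0)) {
    stop("schema must contain at least one event dimension")
  }
  for (nm in list(c("diagnosis code", diagnosis_codes),
                  c("medication group", medication_groups))) {
    dup <- unique(nm[-1][duplicated(nm[-1])])
    if (length(dup)) stop("duplicate ", nm[1], "(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(lab_tests)) {
    lab_tests <- data.frame(test_id = character(), ref_low = numeric(),
                            ref_high = numeric())
  }
  lab_tests <- as.data.frame(lab_tests)[, c("test_id", "ref_low", "ref_high")]
  lab_tests$test_id <- as.character(lab_tests$test_id)
  dup <- unique(lab_tests$test_id[duplicated(lab_tests$test_id)])
  if (length(dup)) stop("duplicate lab test(s): ", paste(dup, collapse = ", "))
  bad <- lab_tests$test_id[lab_tests$ref_low >= lab_tests$ref_high]
  if (length(bad)) {
    stop("reference low >= high for lab test(s): ", paste(bad, collapse = ", "))
  }
  age_bounds <- as.numeric(age_bounds)
  if (length(age_bounds) != 2 || age_bounds[1] >= age_bounds[2]) {
    stop("age_bounds must be two increasing numbers")
  }
  sch <- structure(list(
    diagnosis_codes = diagnosis_codes,
    medication_groups = medication_groups,
    lab_tests = lab_tests,
    age_min = age_bounds[1],
    age_max = age_bounds[2]
  ), class = "ehr_schema")
  sch
}

#' Clinical dimension of a schema
#'
#' @param schema an `ehr_schema`.
#' @param raw if `TRUE`, return the raw-record dimension `d + 2`
#'   (demographics included) instead of the clinical dimension `d`.
#' @return integer dimension.
#' @export
schema_dim <- function(schema, raw = FALSE) {
  stopifnot(inherits(schema, "ehr_schema"))
  d <- length(schema$diagnosis_codes) + length(schema$medication_groups) +
    3L * nrow(schema$lab_tests)
  as.integer(d + if (raw) 2L else 0L)
}

#' @export
print.ehr_schema <- function(x, ...) {
  cat("<ehr_schema> ", length(x$diagnosis_codes), " diagnoses + ",
      length(x$medication_groups), " medication groups + ",
      nrow(x$lab_tests), " lab tests x 3 flags = ", schema_dim(x),
      " clinical dims (", schema_dim(x, raw = TRUE), " raw)\n", sep = "")
  invisible(x)
}

# Position offsets of the three blocks within the multi-hot vector.
schema_offsets <- function(schema) {
  nd <- length(schema$diagnosis_codes)
  nm <- length(schema$medication_groups)
  list(diag = 0L, med = nd, lab = nd + nm)
}

#' Names of every multi-hot dimension, in schema order
#' @param schema an `ehr_schema`.
#' @return character vector of length `schema_dim(schema)`.
#' @export
schema_dim_names <- function(schema) {
  labs <- schema$lab_tests$test_id
  c(paste0("dx:", schema$diagnosis_codes),
    paste0("med:", schema$medication_groups),
    if (length(labs)) paste0("lab:", rep(labs, each = 3), ":",
                             c("high", "low", "normal")))
}

#' Flag a numeric lab result against its reference range
#'
#' Values strictly above the reference high are `"high"`, strictly below the
#' low are `"low"`, and values inside the range -- including exactly at
#' either bound -- are `"normal"`. A missing value yields `NA` (no flag set
#' when encoding).
#'
#' @param value numeric lab result (may be `NA`).
#' @param ref_low,ref_high reference range, `ref_low < ref_high`.
#' @return `"high"`, `"low"`, `"normal"`, or `NA_character_`.
#' @export
flag_lab_result <- function(value, ref_low, ref_high) {
  stopifnot(ref_low < ref_high)
  ifelse(is.na(value), NA_character_,
         ifelse(value > ref_high, "high",
                ifelse(value < ref_low, "low", "normal")))
}

#' Min-max normalize an age against the schema's bounds
#'
#' Ages outside the bounds are clipped before scaling, so the result always
#' lies in `[0, 1]`.
#'
#' @param age age in years.
#' @param schema an `ehr_schema` carrying `age_min`/`age_max`.
#' @return numeric in `[0, 1]`.
#' @export
normalize_age <- function(age, schema) {
  stopifnot(inherits(schema, "ehr_schema"))
  a <- pmin(pmax(age, schema$age_min), schema$age_max)
  (a - schema$age_min) / (schema$age_max - schema$age_min)
}

#' Construct one inpatient record
#'
#' @param record_id unique record identifier.
#' @param admission_time admission date (`Date` or ISO-8601 string).
#' @param diagnoses character vector of diagnosis codes (set semantics;
#'   duplicates collapse).
#' @param medications character vector of medication group names.
#' @param lab_results named numeric vector/list, test id -> value.
#' @return object of class `ehr_record`.
#' @export
clinical_record <- function(record_id, admission_time, diagnoses = character(),
                            medications = character(), lab_results = numeric()) {
  adm <- as.Date(admission_time)
  if (is.na(adm)) stop("record ", record_id, ": unparseable admission_time")
  lr <- unlist(lab_results)
  if (length(lr) && is.null(names(lr))) stop("lab_results must be named by test id")
  structure(list(
    record_id = as.character(record_id),
    admission_time = adm,
    diagnoses = unique(as.character(diagnoses)),
    medications = unique(as.character(medications)),
    lab_results = lr
  ), class = "ehr_record")
}

#' Construct a patient history
#'
#' Records are sorted ascending by admission time (stable, so same-day
#' records keep their input order).
#'
#' @param patient_id unique patient identifier.
#' @param age age in years.
#' @param gender 0/1 coded gender.
#' @param records list of [clinical_record()] objects, at least one.
#' @param died 0/1 in-hospital death flag.
#' @param comorbidities character vector of comorbidity labels (optional,
#'   used by the evaluation tasks).
#' @return object of class `ehr_patient`.
#' @export
patient_history <- function(patient_id, age, gender, records, died = 0L,
                            comorbidities = character()) {
  if (length(records) < 1) stop("patient ", patient_id, ": needs >= 1 record")
  stopifnot(all(vapply(records, inherits, logical(1), "ehr_record")))
  times <- as.Date(vapply(records, function(r) as.character(r$admission_time), ""))
  records <- records[order(times)]  # order() is a stable sort
  structure(list(
    patient_id = as.character(patient_id),
    age = as.numeric(age),
    gender = as.integer(gender),
    records = records,
    died = as.integer(died),
    comorbidities = as.character(comorbidities)
  ), class = "ehr_patient")
}

#' Encode one record as a multi-hot vector
#'
#' One position per present diagnosis/medication; for each reported lab test
#' exactly one of its three flag positions (high/low/normal) is set, and all
#' three stay zero for unreported tests. Codes absent from the schema are
#' dropped with a warning by default, or rejected when `strict = TRUE`.
#'
#' @param record an `ehr_record`.
#' @param schema an `ehr_schema`.
#' @param strict reject unknown codes instead of warning.
#' @return binary numeric vector of length `schema_dim(schema)`.
#' @export
encode_record <- function(record, schema, strict = FALSE) {
  stopifnot(inherits(record, "ehr_record"), inherits(schema, "ehr_schema"))
  off <- schema_offsets(schema)
  d <- schema_dim(schema)
  v <- numeric(d)

  unknown <- character()
  i <- match(unique(record$diagnoses), schema$diagnosis_codes)
  unknown <- c(unknown, unique(record$diagnoses)[is.na(i)])
  v[off$diag + i[!is.na(i)]] <- 1

  i <- match(unique(record$medications), schema$medication_groups)
  unknown <- c(unknown, unique(record$medications)[is.na(i)])
  v[off$med + i[!is.na(i)]] <- 1

  if (length(record$lab_results)) {
    ids <- names(record$lab_results)
    i <- match(ids, schema$lab_tests$test_id)
    unknown <- c(unknown, ids[is.na(i)])
    keep <- which(!is.na(i))
    for (k in keep) {
      j <- i[k]
      fl <- flag_lab_result(record$lab_results[[k]],
                            schema$lab_tests$ref_low[j],
                            schema$lab_tests$ref_high[j])
      if (!is.na(fl)) {
        pos <- off$lab + 3L * (j - 1L) + match(fl, c("high", "low", "normal"))
        v[pos] <- 1
      }
    }
  }
  if (length(unknown)) {
    msg <- paste0("record ", record$record_id, ": unknown code(s): ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  v
}

#' Encode a patient as an n x d binary tensor
#'
#' Row `t` is the multi-hot encoding of the patient's `t`-th record in
#' admission-time order.
#'
#' @inheritParams encode_record
#' @param patient an `ehr_patient`.
#' @return numeric matrix, one row per record, `schema_dim(schema)` columns.
#' @export
encode_patient <- function(patient, schema, strict = FALSE) {
  stopifnot(inherits(patient, "ehr_patient"))
  m <- t(vapply(patient$records, encode_record, numeric(schema_dim(schema)),
                schema = schema, strict = strict))
  rownames(m) <- vapply(patient$records, `[[`, "", "record_id")
  m
}

#' Split a patient into prefix samples
#'
#' A patient with `n` admissions becomes `n` samples: the i-th sample holds
#' the first `i` records. Every prefix inherits the patient's final
#' in-hospital death flag and comorbidity set, so early admissions are
#' labelled with the eventual outcome.
#'
#' @param patient an `ehr_patient`.
#' @return list of `ehr_patient` objects with a `prefix_length` field.
#' @export
prefix_split <- function(patient) {
  stopifnot(inherits(patient, "ehr_patient"))
  lapply(seq_along(patient$records), function(i) {
    s <- patient
    s$records <- patient$records[seq_len(i)]
    s$prefix_length <- i
    s
  })
}

#' Encode a cohort's prefix samples
#'
#' Applies [prefix_split()] to every patient and encodes each sample,
#' returning the tensors together with a per-sample label table.
#'
#' @param patients list of `ehr_patient`.
#' @param schema an `ehr_schema`.
#' @param split if `FALSE`, encode each patient once (full history only).
#' @return list with `tensors` (list of matrices) and `labels` (data.frame
#'   with patient_id, prefix_length, age, gender, died and one logical
#'   column per comorbidity label seen in the cohort).
#' @export
encode_samples <- function(patients, schema, split = TRUE) {
  samples <- if (split) {
    unlist(lapply(patients, prefix_split), recursive = FALSE)
  } else {
    lapply(patients, function(p) { p$prefix_length <- length(p$records); p })
  }
  tensors <- lapply(samples, encode_patient, schema = schema)
  labels <- data.frame(
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    prefix_length = vapply(samples, `[[`, 0L, "prefix_length"),
    age = vapply(samples, `[[`, 0, "age"),
    gender = vapply(samples, `[[`, 0L, "gender"),
    died = vapply(samples, `[[`, 0L, "died"),
    stringsAsFactors = FALSE
  )
  comorb <- sort(unique(unlist(lapply(samples, `[[`, "comorbidities"))))
  for (cm in comorb) {
    labels[[cm]] <- vapply(samples, function(s) cm %in% s$comorbidities, NA)
  }
  list(tensors = tensors, labels = labels, comorbidities = comorb)
}

#' Read patients from line-delimited JSON
#'
#' One JSON object per line with keys `patient_id`, `age`, `gender`, `died`,
#' `comorbidities`, and `records` (each with `record_id`, `admission_time`
#' as an ISO-8601 date, `diagnoses`, `medications`, `lab_results`).
#'
#' @param path file path.
#' @return list of `ehr_patient`.
#' @export
read_patients <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    recs <- lapply(o$records, function(r) {
      clinical_record(r$record_id, r$admission_time,
                      diagnoses = unlist(r$diagnoses) %||% character(),
                      medications = unlist(r$medications) %||% character(),
                      lab_results = r$lab_results %||% numeric())
    })
    patient_history(o$patient_id, o$age, o$gender, recs,
                    died = o$died %||% 0L,
                    comorbidities = unlist(o$comorbidities) %||% character())
  })
}

#' Write patients as line-delimited JSON
#' @param patients list of `ehr_patient`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  lines <- vapply(patients, function(p) {
    o <- list(
      patient_id = p$patient_id, age = p$age, gender = p$gender,
      died = p$died, comorbidities = p$comorbidities,
      records = lapply(p$records, function(r) list(
        record_id = r$record_id,
        admission_time = format(r$admission_time, "%Y-%m-%d"),
        diagnoses = r$diagnoses, medications = r$medications,
        lab_results = as.list(r$lab_results)
      ))
    )
    jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a schema as YAML
#' @param path file path.
#' @return [read_schema()]: an `ehr_schema`; [write_schema()]: `path`.
#' @export
read_schema <- function(path) {
  o <- yaml::read_yaml(path)
  lt <- NULL
  if (length(o$lab_tests)) {
    lt <- do.call(rbind, lapply(o$lab_tests, function(t) {
      data.frame(test_id = t$test_id, ref_low = t$ref_low, ref_high = t$ref_high)
    }))
  }
  build_schema(o$diagnosis_codes, o$medication_groups %||% character(), lt,
               age_bounds = c(o$age_min %||% 0, o$age_max %||% 120))
}

#' @rdname read_schema
#' @param schema an `ehr_schema`.
#' @export
write_schema <- function(schema, path) {
  o <- list(
    diagnosis_codes = schema$diagnosis_codes,
    medication_groups = schema$medication_groups,
    lab_tests = lapply(seq_len(nrow(schema$lab_tests)), function(i) {
      as.list(schema$lab_tests[i, ])
    }),
    age_min = schema$age_min, age_max = schema$age_max
  )
  yaml::write_yaml(o, path)
  invisible(path)
}

#' Full-size default schema
#'
#' A schema with the dimensions of the full-scale heart-failure vocabulary:
#' 1232 diagnosis codes, 11 medication groups and 22 lab tests, giving a
#' 1309-dim clinical vector (1311 raw). Codes are synthetic placeholders
#' (`DX0001`...), since the hospital's curated vocabulary is private.
#'
#' @param n_diagnoses,n_medications,n_lab_tests vocabulary sizes.
#' @return an `ehr_schema`.
#' @export
default_schema <- function(n_diagnoses = 1232, n_medications = 11,
                           n_lab_tests = 22) {
  build_schema(
    sprintf("DX%04d", seq_len(n_diagnoses)),
    sprintf("MG%02d", seq_len(n_medications)),
    data.frame(test_id = sprintf("LT%02d", seq_len(n_lab_tests)),
               ref_low = 10, ref_high = 20)
  )
}
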