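test_that("schema dimension follows the partition rule", {
  expect_equal(schema_dim(default_schema()), 1309L)
  expect_equal(schema_dim(default_schema(), raw = TRUE), 1311L)

  expect_equal(schema_dim(build_schema("X")), 1L)
  expect_equal(schema_dim(tiny_schema()), 3 + 2 + 12)
})

test_that("schema construction rejects duplicates and bad ranges", {
  expect_error(build_schema(c("A", "A")), "duplicate")
  expect_error(build_schema("A", c("M", "M")), "duplicate")
  expect_error(
    build_schema("A", lab_tests = data.frame(test_id = "T", ref_low = 5,
                                             ref_high = 5)),
    "reference")
  expect_error(build_schema("A", age_bounds = c(50, 50)), "age_bounds")
})

test_that("lab flags use inclusive reference bounds", {
  expect_equal(flag_lab_result(1, 1, 2), "normal")   # exactly at low
  expect_equal(flag_lab_result(2, 1, 2), "normal")   # exactly at high
  expect_equal(flag_lab_result(2 + 1e-9, 1, 2), "high")
  expect_equal(flag_lab_result(1 - 1e-9, 1, 2), "low")
  expect_equal(flag_lab_result(1.5, 1, 2), "normal")
  expect_true(is.na(flag_lab_result(NA, 1, 2)))
})

test_that("encode_record sets one position per event and flags labs", {
  sch <- tiny_schema()
  empty <- tiny_record()
  expect_equal(encode_record(empty, sch), numeric(17))

  r <- tiny_record(dx = "A", med = "M2", lab = c(T2 = 25))
  v <- encode_record(r, sch)
  expect_equal(sum(v), 3)
  nm <- schema_dim_names(sch)
  expect_equal(nm[v == 1], c("dx:A", "med:M2", "lab:T2:high"))

  # set semantics: listing a diagnosis twice yields one 1
  r2 <- tiny_record(dx = c("B", "B"))
  expect_equal(sum(encode_record(r2, sch)), 1)

  # missing lab value sets no flag
  r3 <- tiny_record(lab = c(T1 = NA))
  expect_equal(sum(encode_record(r3, sch)), 0)
})

test_that("unknown codes warn by default and reject in strict mode", {
  sch <- tiny_schema()
  r <- tiny_record(dx = c("A", "ZZZ"))
  expect_warning(v <- encode_record(r, sch), "ZZZ")
  expect_equal(sum(v), 1)
  expect_error(encode_record(r, sch, strict = TRUE), "ZZZ")
})

test_that("multi-hot positions partition into diagnosis/medication/lab blocks", {
  sch <- tiny_schema()
  for (seed in 1:5) {
    set.seed(seed)
    dx <- sample(c("A", "B", "C"), sample(0:3, 1))
    med <- sample(c("M1", "M2"), sample(0:2, 1))
    labs <- c(T1 = 1.5, T3 = 2, T4 = 4)[sample(0:3, 1) |> seq_len()]
    r <- tiny_record(dx = dx, med = med, lab = labs)
    v <- encode_record(r, sch)
    expect_equal(sum(v), length(dx) + length(med) + length(labs))
    # round trip: 1-positions recover exactly the schema-known events
    nm <- schema_dim_names(sch)[v == 1]
    expect_setequal(grep("^dx:", nm, value = TRUE),
                    paste0("dx:", dx, recycle0 = TRUE))
    expect_setequal(grep("^med:", nm, value = TRUE),
                    paste0("med:", med, recycle0 = TRUE))
    expect_equal(sum(startsWith(nm, "lab:")), length(labs))
  }
})

test_that("encode_patient orders rows chronologically with stable ties", {
  sch <- tiny_schema()
  # deliberately unsorted input, including a same-day tie
  recs <- list(
    tiny_record("late", "2020-06-01", dx = "C"),
    tiny_record("tie_first", "2020-01-01", dx = "A"),
    tiny_record("tie_second", "2020-01-01", dx = "B")
  )
  p <- patient_history("p", 50, 0, recs)
  X <- encode_patient(p, sch)
  expect_equal(rownames(X), c("tie_first", "tie_second", "late"))
  expect_equal(dim(X), c(3L, 17L))

  p1 <- tiny_patient(1)
  expect_equal(dim(encode_patient(p1, sch)), c(1L, 17L))
})

test_that("age normalization is min-max with clipping", {
  sch <- tiny_schema()  # default bounds 0-120
  expect_equal(normalize_age(0, sch), 0)
  expect_equal(normalize_age(120, sch), 1)
  expect_equal(normalize_age(60, sch), 0.5)
  expect_equal(normalize_age(-5, sch), 0)
  expect_equal(normalize_age(200, sch), 1)
})

test_that("prefix_split yields one sample per record with final labels", {
  p <- tiny_patient(3, died = 1, comorbidities = "hypertension")
  s <- prefix_split(p)
  expect_length(s, 3)
  expect_equal(vapply(s, `[[`, 0L, "prefix_length"), 1:3)
  expect_equal(vapply(s, function(x) length(x$records), 0L), 1:3)
  # every prefix inherits the final outcome labels
  expect_true(all(vapply(s, `[[`, 0L, "died") == 1))
  expect_true(all(vapply(s, function(x) "hypertension" %in% x$comorbidities,
                         NA)))
  expect_length(prefix_split(tiny_patient(1)), 1)
})

test_that("cohort sample count equals the sum of record counts", {
  pats <- list(tiny_patient(2, id = "a"), tiny_patient(3, id = "b"),
               tiny_patient(5, id = "c"))
  es <- encode_samples(pats, tiny_schema())
  expect_length(es$tensors, 10)

  co <- small_cohort()
  es2 <- encode_samples(co$patients, co$schema)
  expect_length(es2$tensors,
                sum(vapply(co$patients, function(p) length(p$records), 0L)))
})

test_that("patients and schemas round-trip through their file formats", {
  co <- small_cohort()
  pats <- co$patients[1:10]
  f <- tempfile(fileext = ".jsonl")
  write_patients(pats, f)
  back <- read_patients(f)
  expect_length(back, 10)
  expect_equal(vapply(back, `[[`, "", "patient_id"),
               vapply(pats, `[[`, "", "patient_id"))
  expect_equal(encode_patient(back[[3]], co$schema),
               encode_patient(pats[[3]], co$schema))
  expect_equal(vapply(back, `[[`, 0L, "died"), vapply(pats, `[[`, 0L, "died"))

  fs <- tempfile(fileext = ".yaml")
  write_schema(co$schema, fs)
  sch2 <- read_schema(fs)
  expect_equal(schema_dim(sch2), schema_dim(co$schema))
  expect_equal(sch2$diagnosis_codes, co$schema$diagnosis_codes)
  expect_equal(sch2$lab_tests$ref_high, co$schema$lab_tests$ref_high)
})
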