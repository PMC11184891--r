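# Synthetic data generators and cohort-query semantics.

test_that("datamart generation is byte-deterministic under a fixed seed", {
  schema <- demo_patient_schema(seed = 11L)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  generate_datamart(schema, 50L, path = p1)
  generate_datamart(schema, 50L, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a different seed changes the bytes
  generate_datamart(demo_patient_schema(seed = 12L), 50L, path = p2)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p2, "raw", file.size(p2))))
})

test_that("zero rows yields a header-only table with the schema's fields", {
  df <- generate_datamart(demo_patient_schema(), 0L)
  expect_identical(nrow(df), 0L)
  expect_identical(names(df),
                   c("age", "sex", "biomarker", "diagnosis_date", "row_sentinel"))
  p <- tempfile(fileext = ".csv")
  generate_datamart(demo_patient_schema(), 0L, path = p)
  expect_identical(length(readLines(p)), 1L)
})

test_that("numeric fields track their stated distribution", {
  schema <- synthetic_schema("big", seed = 3L, fields = list(
    sy_num("x", mean = 50, sd = 10, digits = 6L)
  ))
  df <- generate_datamart(schema, 10000L, sentinel = FALSE)
  se <- 10 / sqrt(10000)
  expect_lt(abs(mean(df$x) - 50), 3 * se)
})

test_that("the OMOP-lite subset preserves referential integrity", {
  tabs <- generate_omop_lite(50L, seed = 9L)
  expect_true(all(tabs$condition_occurrence$person_id %in% tabs$person$person_id))
  empty <- generate_omop_lite(0L)
  expect_identical(nrow(empty$person), 0L)
  expect_identical(nrow(empty$condition_occurrence), 0L)
  expect_identical(names(empty$person), c("person_id", "gender", "year_of_birth"))
  # deterministic
  expect_identical(generate_omop_lite(25L, seed = 4L), generate_omop_lite(25L, seed = 4L))
})

test_that("join queries match a brute-force nested-loop count", {
  tabs <- generate_omop_lite(60L, seed = 21L)
  concept <- tabs$condition_occurrence$condition_concept_id[1]
  q <- cohort_query(pred("person.gender", "=", "F"),
                    pred("condition_occurrence.condition_concept_id", "=", concept))
  got <- apply_cohort_query(tabs, q)

  # independent nested-loop join oracle
  expected <- 0L
  for (i in seq_len(nrow(tabs$person))) {
    for (j in seq_len(nrow(tabs$condition_occurrence))) {
      if (tabs$person$person_id[i] == tabs$condition_occurrence$person_id[j] &&
          tabs$person$gender[i] == "F" &&
          tabs$condition_occurrence$condition_concept_id[j] == concept) {
        expected <- expected + 1L
      }
    }
  }
  expect_identical(nrow(got), expected)
  expect_gt(expected, 0L)
})

test_that("the empty conjunction is the identity and contradictions select nothing", {
  df <- generate_datamart(demo_patient_schema(), 30L)
  expect_identical(apply_cohort_query(df, cohort_query()), df)
  none <- apply_cohort_query(df, cohort_query(pred("age", "<", 1), pred("age", ">", 2)))
  expect_identical(nrow(none), 0L)
})

test_that("unknown fields and non-numeric literals raise query errors", {
  df <- generate_datamart(demo_patient_schema(), 10L)
  expect_error(apply_cohort_query(df, cohort_query(pred("agee", ">", 1))),
               regexp = "agee", class = "sandbox_query_error")
  expect_error(apply_cohort_query(df, cohort_query(pred("age", ">", "old"))),
               class = "sandbox_query_error")
})

test_that("cohort filtering matches the brute-force row scan on random queries", {
  set.seed(404)
  for (trial in 1:60) {
    schema <- synthetic_schema(sprintf("t%d", trial), seed = trial, fields = list(
      sy_num("a", mean = 10, sd = 4, digits = 2L),
      sy_num("b", mean = 0, sd = 1, digits = 3L),
      sy_cat("g", c("x", "y", "z"))
    ))
    df <- generate_datamart(schema, 200L, sentinel = FALSE)
    q <- random_query(df, n_preds = sample(1:3, 1))
    got <- apply_cohort_query(df, q)
    want <- oracle_scan(df, q)
    expect_identical(got, want, info = sprintf("trial %d", trial))
  }
})

test_that("the toy algorithm catalog ships three runnable aggregate-only fixtures", {
  repo <- new_root("cat-")
  entries <- toy_algorithm_catalog(repo)
  expect_setequal(names(entries), c("row_counter", "column_summariser", "sleeper"))
  for (e in entries) expect_true(file.exists(e$locator))

  # row counter counts payload rows
  pr <- processor_agent(processor_config("pcat", root = new_root("proc-"),
                                         timeout = 20))
  df <- generate_datamart(demo_patient_schema(), 37L)
  con <- textConnection(NULL, "w")
  utils::write.csv(df, con, row.names = FALSE)
  csv <- paste0(paste(textConnectionValue(con), collapse = "\n"), "\n")
  close(con)
  d <- token_descriptor("jcount", "t", algo_script("algo/run.sh"),
                        datamart_ref = dm_payload("data/datamart.csv"))
  tok <- build_token(d, list(
    "data/datamart.csv" = csv,
    "algo/run.sh" = paste(readLines(entries$row_counter$locator), collapse = "\n")
  ))
  out <- pr$execute_token(tok)
  expect_identical(out$status, "success")
  expect_identical(trimws(rawToChar(out$payload[["results/row_count.txt"]])), "37")
})

test_that("the column summariser emits aggregates only, never sentinel values", {
  repo <- new_root("cat-")
  entries <- toy_algorithm_catalog(repo)
  pr <- processor_agent(processor_config("psum", root = new_root("proc-"),
                                         timeout = 20))
  schema <- synthetic_schema("const", seed = 1L, fields = list(
    sy_num("k", mean = 7, sd = 0, digits = 0L),
    sy_cat("g", c("a", "b"))
  ))
  df <- generate_datamart(schema, 25L)
  con <- textConnection(NULL, "w")
  utils::write.csv(df, con, row.names = FALSE)
  csv <- paste0(paste(textConnectionValue(con), collapse = "\n"), "\n")
  close(con)
  d <- token_descriptor("jsum", "t", algo_script("algo/run.R"))
  tok <- build_token(d, list(
    "data/datamart.csv" = csv,
    "algo/run.R" = paste(readLines(entries$column_summariser$locator), collapse = "\n")
  ))
  out <- pr$execute_token(tok)
  expect_identical(out$status, "success")
  summary_text <- rawToChar(out$payload[["results/summary.txt"]])
  expect_match(summary_text, "k mean 7")          # constant column mean
  expect_no_match(summary_text, "SENTINEL_")      # aggregates only
})
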