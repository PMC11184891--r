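# Token archive format: build/parse round-trips, path safety, hashing.

test_that("an empty-payload token archives exactly the descriptor member", {
  d <- token_descriptor("j1", "alice", algo_script("algo/run.sh"))
  tok <- build_token(d)
  expect_identical(tok$manifest, "descriptor.xml")
  parsed <- parse_token(tok)
  expect_identical(parsed$manifest, "descriptor.xml")
  expect_length(parsed$payload, 0)
})

test_that("build then parse reproduces descriptor and payload exactly", {
  d <- token_descriptor(
    "j2", "alice", algo_image("toy-image"),
    datamart_ref = dm_payload("data/datamart.csv"),
    column_roles = c(age = "input", outcome = "target"),
    run_settings = list(alpha = "0.05", iterations = "100"),
    notarise = TRUE, sign = TRUE,
    schedule = cadence_interval(60, anchor = "2024-01-01T00:00:00.000000Z")
  )
  payload <- list(
    "data/datamart.csv" = "a,b\n1,2\n",
    "notes.txt" = as.raw(c(0x00, 0xff, 0x10))
  )
  tok <- build_token(d, payload)
  expect_length(tok$manifest, 3)
  parsed <- parse_token(tok)
  expect_equal(parsed$descriptor, d)
  expect_identical(parsed$payload[["notes.txt"]], payload[["notes.txt"]])
  expect_identical(rawToChar(parsed$payload[["data/datamart.csv"]]),
                   payload[["data/datamart.csv"]])
})

test_that("unsafe payload paths are rejected", {
  d <- token_descriptor("j3", "alice", algo_script("run.sh"))
  expect_error(build_token(d, list("../x" = "boom")), class = "sandbox_path_error")
  expect_error(build_token(d, list("/etc/passwd" = "boom")), class = "sandbox_path_error")
  expect_error(build_token(d, list("a/../../x" = "boom")), class = "sandbox_path_error")
  expect_error(build_token(d, list("descriptor.xml" = "boom")), class = "sandbox_path_error")
  p <- list("x.txt" = "a", "x.txt" = "b")
  expect_error(build_token(d, p), class = "sandbox_path_error")
})

test_that("archives without a descriptor or with invalid XML are rejected", {
  staging <- tempfile(); dir.create(staging)
  writeLines("not a descriptor", file.path(staging, "other.txt"))
  zp <- file.path(tempdir(), "nodesc.zip")
  zip::zip(zp, "other.txt", root = staging, mode = "mirror")
  expect_error(parse_token(zp), class = "sandbox_missing_descriptor")

  # descriptor lacking job_id -> schema error
  writeLines("<token_descriptor><user_id>u</user_id></token_descriptor>",
             file.path(staging, "descriptor.xml"))
  zp2 <- file.path(tempdir(), "nojob.zip")
  zip::zip(zp2, c("other.txt", "descriptor.xml"), root = staging, mode = "mirror")
  expect_error(parse_token(zp2), class = "sandbox_schema_error")

  # not a zip at all
  expect_error(parse_token(charToRaw("garbage")), class = "sandbox_parse_error")
})

test_that("descriptor build/parse is the identity on random descriptors", {
  set.seed(42)
  for (i in 1:60) {
    d <- random_descriptor(i)
    payload <- random_payload()
    tok <- build_token(d, payload)
    parsed <- parse_token(tok)
    expect_equal(parsed$descriptor, d, info = sprintf("descriptor %d", i))
    expect_setequal(parsed$manifest, c("descriptor.xml", names(payload)))
    for (nm in names(payload)) {
      expect_identical(parsed$payload[[nm]], payload[[nm]],
                       info = sprintf("member %s of descriptor %d", nm, i))
    }
  }
})

test_that("digests are deterministic and match an independent implementation", {
  skip_if_not_installed("digest")
  # known empty-input digest, via the independent implementation
  expect_identical(hash_artifact(raw(0))$hex,
                   digest::digest(raw(0), algo = "sha256", serialize = FALSE))
  expect_identical(hash_artifact(raw(0))$algorithm_id, "sha256")
  set.seed(7)
  for (i in 1:20) {
    payload <- as.raw(sample(0:255, sample(1:2048, 1), replace = TRUE))
    h1 <- hash_artifact(payload)$hex
    expect_identical(h1, hash_artifact(payload)$hex)
    expect_identical(h1, digest::digest(payload, algo = "sha256", serialize = FALSE))
    expect_identical(nchar(h1), 64L)
  }
})

test_that("any single-bit flip changes the digest", {
  set.seed(11)
  payload <- as.raw(sample(0:255, 4096, replace = TRUE))
  base <- hash_artifact(payload)$hex
  for (i in 1:100) {
    pos <- sample(length(payload), 1)
    bit <- as.raw(bitwShiftL(1L, sample(0:7, 1)))
    mutated <- payload
    mutated[pos] <- as.raw(bitwXor(as.integer(mutated[pos]), as.integer(bit)))
    expect_false(identical(hash_artifact(mutated)$hex, base))
  }
})

test_that("output tokens round-trip and enforce the failure-needs-logs contract", {
  out <- build_output_token("j1", "success",
                            results = list("report.txt" = "ok"),
                            logs = list("run.log" = "started\nfinished\n"))
  expect_length(out$archive, length(out$archive))
  parsed <- parse_output_token(out)
  expect_identical(parsed$job_id, "j1")
  expect_identical(parsed$status, "success")
  expect_setequal(parsed$manifest, c("result.xml", "results/report.txt", "logs/run.log"))

  fail <- parse_output_token(build_output_token("j1", "failure",
                                                logs = list("err.log" = "boom")))
  expect_identical(fail$status, "failure")
  expect_identical(fail$logs, "logs/err.log")

  expect_error(build_output_token("j1", "failure", logs = list()),
               class = "sandbox_contract_error")
})
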