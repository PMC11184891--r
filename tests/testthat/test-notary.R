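# Hash-chained ledger, off-chain store, dual signature workflow.

new_notary <- function(clock = fake_clock()) notary_agent(new_root("notary-"), clock = clock)

test_that("the ledger starts at a zero-digest genesis and chains entries", {
  ny <- new_notary()
  r1 <- ny$notarize("payload-one", "j1", "request", user = "alice")
  expect_identical(r1$entry$index, 0L)
  expect_identical(r1$entry$prev_entry_digest, strrep("0", 64))

  r2 <- ny$notarize("payload-two", "j1", "result", user = "alice")
  expect_identical(r2$entry$index, 1L)
  expect_identical(r2$entry$prev_entry_digest, r1$entry$entry_digest)
  expect_true(ny$verify_ledger()$ok)

  # off-chain record precedes the ledger entry and matches the blob
  expect_true(ny$verify_offchain()$ok)
  expect_identical(ny$record_for("j1", "request")$payload_digest,
                   hash_artifact("payload-one")$hex)
})

test_that("duplicate (job, role) notarisation is refused without growing the ledger", {
  ny <- new_notary()
  ny$notarize("x", "j1", "request")
  n <- ny$ledger_length()
  expect_error(ny$notarize("y", "j1", "request"), class = "sandbox_duplicate_error")
  expect_identical(ny$ledger_length(), n)
})

test_that("verify_ledger localises the earliest tampered entry", {
  ny <- new_notary()
  for (i in 1:10) ny$notarize(sprintf("payload %d", i), sprintf("j%d", i), "request")
  expect_true(ny$verify_ledger()$ok)

  path <- file.path(ny$dir, "ledger.jsonl")
  lines <- readLines(path)
  e <- jsonlite::fromJSON(lines[5])
  d <- e$payload_digest
  substr(d, 1, 1) <- if (substr(d, 1, 1) == "0") "1" else "0"
  e$payload_digest <- d
  lines[5] <- sprintf(
    '{"index":%d,"timestamp":"%s","payload_digest":"%s","prev_entry_digest":"%s","entry_digest":"%s"}',
    e$index, e$timestamp, e$payload_digest, e$prev_entry_digest, e$entry_digest)
  writeLines(lines, path)
  v <- ny$verify_ledger()
  expect_false(v$ok)
  expect_identical(v$first_bad_index, 4L)

  # truncation leaves a valid prefix (append-only model; head digest is the
  # exposed anchor against tail loss)
  writeLines(readLines(path)[1:3], path)
  ny2 <- notary_agent(ny$dir)
  expect_true(ny2$verify_ledger()$ok)
})

test_that("proof of existence returns the earliest matching entry", {
  ny <- new_notary()
  ny$notarize("shared-bytes", "j1", "request")
  ny$notarize("other", "j2", "request")
  ny$notarize("shared-bytes", "j2", "result")
  p <- ny$proof_of_existence(hash_artifact("shared-bytes"))
  expect_true(p$found)
  expect_identical(p$index, 0L)
  expect_false(ny$proof_of_existence(strrep("a", 64))$found)
})

test_that("sandbox signatures verify and reject any modification", {
  ny <- new_notary()
  report <- charToRaw("final aggregate report")
  rep <- ny$sign_report("j1", report)
  expect_identical(rep$state, "sandbox_signed")
  expect_true(ny$verify_signature(report, rep$sandbox_signature))

  mutated <- report
  mutated[3] <- as.raw(bitwXor(as.integer(mutated[3]), 1L))
  expect_false(ny$verify_signature(mutated, rep$sandbox_signature))

  other <- openssl::ed25519_keygen()
  expect_false(ny$verify_signature(report, rep$sandbox_signature,
                                   as.list(other)$pubkey))
})

test_that("countersigning stores and notarises exactly three report artefacts", {
  ny <- new_notary()
  key <- openssl::ed25519_keygen()
  ny$register_user_key("alice", as.list(key)$pubkey)

  ny$notarize("request-meta", "j1", "request", user = "alice")
  ny$notarize("result-bytes", "j1", "result", user = "alice")
  ny$sign_report("j1", "the report", user = "alice")

  sig <- user_countersign(ny$signed_envelope("j1"), key,
                          sandbox_pubkey = ny$sandbox_pubkey())
  rep <- ny$countersign("j1", sig, "alice")
  expect_identical(rep$state, "countersigned")

  roles <- c("report-initial", "report-sandbox-signed", "report-countersigned")
  recs <- lapply(roles, ny$record_for, job_id = "j1")
  expect_true(all(!vapply(recs, is.null, TRUE)))
  for (r in recs) {
    expect_true(file.exists(file.path(ny$dir, "offchain", r$blob)))
    expect_true(ny$proof_of_existence(r$payload_digest)$found)
    expect_identical(r$user, "alice")
  }
  # accountability chain: 1 request + 1 result + 3 reports
  expect_identical(ny$ledger_length(), 5L)
  expect_true(ny$verify_ledger()$ok)
})

test_that("the signing state machine rejects out-of-order and forged steps", {
  ny <- new_notary()
  key <- openssl::ed25519_keygen()
  forger <- openssl::ed25519_keygen()
  ny$register_user_key("alice", as.list(key)$pubkey)

  # countersign before any sandbox signing
  expect_error(ny$countersign("jX", raw(64), "alice"), class = "sandbox_state_error")

  ny$sign_report("j1", "report")
  forged <- openssl::ed25519_sign(ny$signed_envelope("j1"), forger)
  expect_error(ny$countersign("j1", forged, "alice"),
               class = "sandbox_signature_error")
  expect_identical(ny$report_state("j1"), "sandbox_signed")

  # unregistered user key
  ny$sign_report("j2", "report2")
  sig2 <- openssl::ed25519_sign(ny$signed_envelope("j2"), key)
  expect_error(ny$countersign("j2", sig2, "mallory"), class = "sandbox_config_error")
})

test_that("signature soundness holds over random messages", {
  ny <- new_notary()
  set.seed(33)
  for (i in 1:25) {
    m <- as.raw(sample(0:255, sample(1:256, 1), replace = TRUE))
    rep <- ny$sign_report(sprintf("jr%d", i), m)
    expect_true(ny$verify_signature(m, rep$sandbox_signature))
    m2 <- m
    pos <- sample(length(m2), 1)
    m2[pos] <- as.raw(bitwXor(as.integer(m2[pos]), 1L))
    expect_false(ny$verify_signature(m2, rep$sandbox_signature))
  }
})

test_that("random single-byte mutations of entries or blobs are detected", {
  ny <- new_notary()
  for (i in 1:12) ny$notarize(sprintf("blob %d", i), sprintf("jm%d", i), "request")
  ledger_path <- file.path(ny$dir, "ledger.jsonl")
  pristine_ledger <- readBin(ledger_path, "raw", file.size(ledger_path))
  blobs <- list.files(file.path(ny$dir, "offchain"), full.names = TRUE)

  set.seed(99)
  detected <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    if (i %% 2 == 0) {
      bytes <- pristine_ledger
      pos <- sample(length(bytes), 1)
      repeat {
        new_byte <- as.raw(sample(c(48:57, 97:102), 1))  # stay in hex alphabet
        if (new_byte != bytes[pos]) break
      }
      bytes[pos] <- new_byte
      writeBin(bytes, ledger_path)
      ok <- ny$verify_ledger()$ok
      writeBin(pristine_ledger, ledger_path)
    } else {
      blob <- sample(blobs, 1)
      orig <- readBin(blob, "raw", file.size(blob))
      bytes <- orig
      pos <- sample(length(bytes), 1)
      bytes[pos] <- as.raw(bitwXor(as.integer(bytes[pos]), 0x01L))
      writeBin(bytes, blob)
      ok <- ny$verify_offchain()$ok
      writeBin(orig, blob)
    }
    if (!ok) detected <- detected + 1L
  }
  expect_identical(detected, n_trials)
})
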