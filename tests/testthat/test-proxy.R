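# Proxy coordination: polling, authorisation, resolution, load balancing,
# output routing, platform info.

test_that("polling consumes each MMT entry exactly once with an ACK", {
  sb <- test_sandbox()
  s <- sb$login("alice", "pw")
  sb$submit(job_request("j1", s$ticket, "alice", "patients", "row_counter"))
  sb$submit(job_request("j2", s$ticket, "alice", "patients", "row_counter"))
  got <- sb$proxy$poll_channels()
  expect_length(got, 2)
  st <- sb$channel$read_status()
  expect_identical(sum(st$payload == "queued"), 2L)
  # idempotent re-poll
  expect_length(sb$proxy$poll_channels(), 0)
})

test_that("a missing detail file produces an error for that entry only", {
  sb <- test_sandbox()
  s <- sb$login("alice", "pw")
  sb$submit(job_request("j1", s$ticket, "alice", "patients", "row_counter"))
  sb$submit(job_request("j2", s$ticket, "alice", "patients", "row_counter"))
  unlink(file.path(sb$channel$dir, "jobs", "job_j1.xml"))
  got <- sb$proxy$poll_channels()
  expect_length(got, 1)
  expect_identical(got[[1]]$job_id, "j2")
  st <- sb$channel$read_status()
  expect_identical(st$code[st$job_id == "j1"], "error.request")
})

test_that("denied requests never become tokens; expired sessions ask to re-authenticate", {
  sb <- test_sandbox(users = c(alice = "pw", mallory = "pw"))
  sb$perm$revoke_grant("mallory", "patients")
  s <- sb$login("mallory", "pw")
  sb$submit(job_request("jden", s$ticket, "mallory", "patients", "row_counter"))
  sb$run()
  expect_identical(sb$proxy$job_state("jden"), "denied")
  st <- sb$channel$read_status()
  expect_true(any(st$code == "error.denied" & st$job_id == "jden"))
  inputs <- unlist(lapply(sb$processors, function(p) {
    c(list.files(p$config$input_folders[[1]]), list.files(p$config$done_folder))
  }))
  expect_false(any(grepl("jden", inputs)))
  expect_identical(sb$notary$ledger_length(), 0L)

  # dead ticket: auth-required, not deny
  sb2 <- test_sandbox()
  sb2$login("alice", "pw")
  sb2$submit(job_request("jexp", "stale-ticket", "alice", "patients", "row_counter"))
  sb2$run()
  expect_identical(sb2$proxy$job_state("jexp"), "auth-required")
  expect_true(any(sb2$channel$read_status()$code == "error.auth"))
})

test_that("datamart resolution applies cohort queries exactly", {
  sb <- test_sandbox()
  full <- sb$proxy$resolve_datamart("patients")
  expect_identical(nrow(full$df), 100L)
  q <- cohort_query(pred("age", ">=", 60))
  sub <- sb$proxy$resolve_datamart("patients", q)
  # brute-force oracle over the registered CSV
  df <- utils::read.csv(file.path(sb$root, "repo", "datamarts", "patients.csv"),
                        check.names = FALSE)
  expect_identical(nrow(sub$df), sum(df$age >= 60))
  expect_error(sb$proxy$resolve_datamart("patients", cohort_query(pred("agee", ">", 1))),
               regexp = "agee", class = "sandbox_query_error")
  expect_error(
    connector_fetch(connector_spec("oracledb", path = "x")),
    class = "sandbox_config_error"
  )
})

test_that("processor selection is least-ongoing with deterministic tie-breaks", {
  sb <- test_sandbox(n_processors = 2L)
  # both idle: lexically first
  expect_identical(sb$proxy$select_processor(), "proc01")
  s <- sb$login("alice", "pw")
  sb$submit(job_request("jlb1", s$ticket, "alice", "patients", "sleeper",
                        run_settings = list(duration = "0.5")))
  sb$proxy$cycle()  # dispatches to proc01, which now has ongoing 1
  expect_identical(sb$proxy$select_processor(), "proc02")
  sb$run()
})

test_that("equal-duration jobs over two idle processors balance to within one", {
  sb <- test_sandbox(n_processors = 2L, max_parallel = 4L)
  s <- sb$login("alice", "pw")
  for (i in 1:8) {
    sb$submit(job_request(sprintf("jb%02d", i), s$ticket, "alice", "patients",
                          "sleeper", run_settings = list(duration = "0.1")))
  }
  sb$run(max_wait = 120)
  st <- sb$proxy$processor_states()
  expect_identical(sum(st$forwarded), 8L)
  expect_lte(abs(diff(st$forwarded)), 1L)
  expect_identical(sum(st$completed), 8L)
  # counter invariant after every event
  for (snap in sb$proxy$counter_log()) expect_gte(snap$ongoing, 0L)
})

test_that("orphan output tokens are quarantined, never forwarded", {
  sb <- test_sandbox()
  out <- build_output_token("zzz", "success", results = list("r.txt" = "x"),
                            logs = list("l.log" = "y"))
  write_token(out, file.path(sb$processors[[1]]$config$output_folder, "out_zzz.zip"))
  sb$proxy$monitor_outputs()
  expect_identical(list.files(file.path(sb$proxy$dir, "quarantine")), "out_zzz.zip")
  expect_match(sb$proxy$operator_logs(), "orphan", all = FALSE)
  expect_false(any(grepl("zzz", sb$channel$transcript_text())))
})

test_that("platform info reports live processors and a monotone catalog version", {
  sb <- test_sandbox(n_processors = 2L)
  info <- sb$proxy$platform_info("processor-count")
  expect_identical(info$count, 2L)
  expect_false(info$degraded)

  v1 <- sb$proxy$platform_info("catalog-update")$version
  register_datamart_fixture(sb, synthetic_schema("extra", seed = 5L, fields = list(
    sy_num("v", 0, 1)
  )), 10L)
  cat2 <- sb$proxy$platform_info("catalog-update")
  expect_gt(cat2$version, v1)
  expect_true("extra" %in% names(cat2$datamarts))

  # no processors: degraded state
  sb0 <- sandbox_local(new_root(), n_processors = 0L, with_fixtures = FALSE)
  info0 <- sb0$proxy$platform_info("processor-count")
  expect_identical(info0$count, 0L)
  expect_true(info0$degraded)
})

test_that("jobs wait with a warning when no processor is live, then recover", {
  sb <- test_sandbox(n_processors = 0L, with_fixtures = TRUE)
  s <- sb$login("alice", "pw")
  sb$submit(job_request("jwait", s$ticket, "alice", "patients", "row_counter"))
  sb$proxy$cycle()
  expect_identical(sb$proxy$job_state("jwait"), "waiting-processor")
  st <- sb$channel$read_status()
  expect_true(any(grepl("no live processor", st$payload)))

  cfg <- processor_config("latep", root = file.path(sb$root, "processors", "latep"),
                          algorithm_repo = sb$algorithm_repo, timeout = 30)
  pr <- processor_agent(cfg)
  sb$proxy$register_processor(cfg)
  pr$step()
  deadline <- Sys.time() + 30
  repeat {
    sb$proxy$cycle()
    pr$step()
    if (identical(sb$proxy$job_state("jwait"), "completed")) break
    stopifnot(Sys.time() < deadline)
    Sys.sleep(0.02)
  }
  expect_identical(sb$proxy$job_state("jwait"), "completed")
})

test_that("a notarisation outage holds the job; it is never executed un-notarised", {
  sb <- test_sandbox()
  s <- sb$login("alice", "pw")
  broken <- TRUE
  real_notarize <- sb$notary$notarize
  shim <- list(
    notarize = function(...) {
      if (broken) stop("ledger unavailable")
      real_notarize(...)
    },
    sign_report = sb$notary$sign_report,
    signed_envelope = sb$notary$signed_envelope
  )
  sb$proxy$notary <- shim
  sb$submit(job_request("jheld", s$ticket, "alice", "patients", "row_counter"))
  sb$proxy$cycle()
  expect_identical(sb$proxy$job_state("jheld"), "held")
  inputs <- list.files(sb$processors[[1]]$config$input_folders[[1]])
  expect_length(inputs, 0)

  broken <- FALSE
  sb$run()
  expect_identical(sb$proxy$job_state("jheld"), "completed")
  ev <- sb$proxy$events()
  expect_true("notarise-request-failed" %in% ev$event)
  # request entry precedes deposit once the outage clears
  seqs <- ev$seq[ev$event %in% c("notarise-request", "token-deposited")]
  expect_identical(ev$event[ev$seq %in% seqs][1], "notarise-request")
})

test_that("scheduling requests are routed to the scheduler, not executed at once", {
  sb <- test_sandbox()
  s <- sb$login("alice", "pw")
  sb$submit(job_request("jsched", s$ticket, "alice", "patients", "row_counter",
                        schedule = cadence_interval(3600)))
  sb$run()
  expect_identical(sb$proxy$job_state("jsched"), "scheduled")
  expect_identical(nrow(sb$scheduler$tasks()), 1L)
  outs <- list.files(sb$processors[[1]]$config$done_folder)
  expect_false(any(grepl("jsched", outs)))
  st <- sb$channel$read_status()
  expect_true(any(grepl("scheduled as", st$payload)))
})
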