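# Black-box executor: claiming, backends, failure handling, conservation.

make_processor <- function(max_parallel = 2L, ...) {
  cfg <- processor_config(paste0("p", substr(rand_id(), 1, 6)),
                          root = new_root("proc-"),
                          max_parallel = max_parallel, timeout = 20, ...)
  processor_agent(cfg)
}

rand_id <- function() paste(sample(c(letters, 0:9), 8, replace = TRUE), collapse = "")

script_token <- function(job_id, code, settings = list()) {
  d <- token_descriptor(job_id, "tester", algo_script("algo/run.sh"),
                        run_settings = settings)
  build_token(d, list("algo/run.sh" = code))
}

test_that("a claimed token leaves the input folder and yields one output token", {
  pr <- make_processor()
  tok <- script_token("jslow", "sleep 0.4\necho done > results/out.txt")
  input <- pr$config$input_folders[[1]]
  write_token(tok, file.path(input, "token_jslow.zip"))

  pr$step()
  # while processed, the token is gone from the input folder
  expect_length(list.files(input), 0)
  expect_identical(pr$n_active(), 1L)
  expect_length(list.files(pr$config$output_folder), 0)

  pr$run_until_idle()
  outs <- list.files(pr$config$output_folder)
  expect_identical(outs, "out_jslow.zip")
  out <- parse_output_token(file.path(pr$config$output_folder, outs))
  expect_identical(out$status, "success")
  expect_identical(rawToChar(out$payload[["results/out.txt"]]), "done\n")
  # consumed input token archived, not lost
  expect_identical(list.files(pr$config$done_folder), "token_jslow.zip")
})

test_that("failing scripts produce failure tokens that carry the captured log", {
  pr <- make_processor()
  tok <- script_token("jbad", "echo diagnostics-before-crash >&2\nexit 3")
  write_token(tok, file.path(pr$config$input_folders[[1]], "token_jbad.zip"))
  pr$run_until_idle()
  out <- parse_output_token(file.path(pr$config$output_folder, "out_jbad.zip"))
  expect_identical(out$status, "failure")
  expect_gt(length(out$logs), 0)
  log_text <- rawToChar(out$payload[[out$logs[1]]])
  expect_match(log_text, "diagnostics-before-crash")
  rec <- pr$records()
  expect_identical(rec$exit_status[rec$job_id == "jbad"], 3L)
})

test_that("corrupt archives yield a failure token with a parse-error log", {
  pr <- make_processor()
  writeBin(charToRaw("this is not a zip"),
           file.path(pr$config$input_folders[[1]], "token_jcorrupt.zip"))
  pr$run_until_idle()
  out <- parse_output_token(file.path(pr$config$output_folder, "out_jcorrupt.zip"))
  expect_identical(out$status, "failure")
  expect_match(rawToChar(out$payload[[out$logs[1]]]), "parse error")
})

test_that("unknown backends and unresolvable references fail cleanly", {
  pr <- make_processor()
  d <- token_descriptor("jmissing", "t", algo_script("algo/nowhere.sh"))
  write_token(build_token(d), file.path(pr$config$input_folders[[1]], "token_jmissing.zip"))
  d2 <- token_descriptor("jext", "t", algo_script("algo/run.jvm"))
  write_token(build_token(d2, list("algo/run.jvm" = "x")),
              file.path(pr$config$input_folders[[1]], "token_jext.zip"))
  pr$run_until_idle()
  for (j in c("jmissing", "jext")) {
    out <- parse_output_token(file.path(pr$config$output_folder, paste0("out_", j, ".zip")))
    expect_identical(out$status, "failure")
    expect_gt(length(out$logs), 0)
  }
  out <- parse_output_token(file.path(pr$config$output_folder, "out_jext.zip"))
  expect_match(rawToChar(out$payload[[out$logs[1]]]), "no interpreter")
})

test_that("container images run only from the local store; absent images are refused", {
  store <- new_root("imgs-")
  entry <- tempfile(fileext = ".sh")
  writeLines("echo from-image > results/img.txt", entry)
  image_store_add(store, "toy-image", entry)

  pr <- make_processor(image_store = store)
  d <- token_descriptor("jimg", "t", algo_image("toy-image"))
  write_token(build_token(d), file.path(pr$config$input_folders[[1]], "token_jimg.zip"))
  d2 <- token_descriptor("jpull", "t", algo_image("not-loaded"))
  write_token(build_token(d2), file.path(pr$config$input_folders[[1]], "token_jpull.zip"))
  pr$run_until_idle()

  ok <- parse_output_token(file.path(pr$config$output_folder, "out_jimg.zip"))
  expect_identical(ok$status, "success")
  expect_identical(rawToChar(ok$payload[["results/img.txt"]]), "from-image\n")
  rec <- pr$records()
  expect_identical(rec$backend[rec$job_id == "jimg"], "container")

  refused <- parse_output_token(file.path(pr$config$output_folder, "out_jpull.zip"))
  expect_identical(refused$status, "failure")
  expect_match(rawToChar(refused$payload[[refused$logs[1]]]),
               "not enabled")
})

test_that("locator references resolve against the local algorithm repository", {
  repo <- new_root("repo-")
  writeLines("echo via-locator > results/loc.txt", file.path(repo, "myalg.sh"))
  pr <- make_processor(algorithm_repo = repo)
  d <- token_descriptor("jloc", "t", algo_locator("myalg"))
  write_token(build_token(d), file.path(pr$config$input_folders[[1]], "token_jloc.zip"))
  pr$run_until_idle()
  out <- parse_output_token(file.path(pr$config$output_folder, "out_jloc.zip"))
  expect_identical(out$status, "success")
})

test_that("at most max_parallel jobs run concurrently and all complete", {
  pr <- make_processor(max_parallel = 2L)
  for (i in 1:5) {
    tok <- script_token(sprintf("jp%d", i), "sleep 0.3\necho ok > results/r.txt")
    write_token(tok, file.path(pr$config$input_folders[[1]],
                               sprintf("token_jp%d.zip", i)))
  }
  deadline <- Sys.time() + 30
  repeat {
    pr$step()
    expect_lte(pr$n_active(), 2L)
    if (pr$n_active() == 0L && pr$n_queued() == 0L &&
        length(list.files(pr$config$input_folders[[1]])) == 0L) break
    stopifnot(Sys.time() < deadline)
    Sys.sleep(0.02)
  }
  expect_identical(sort(list.files(pr$config$output_folder)),
                   sprintf("out_jp%d.zip", 1:5))
})

test_that("claimed tokens and output tokens stay in one-to-one correspondence", {
  set.seed(5)
  pr <- make_processor(max_parallel = 4L)
  input <- pr$config$input_folders[[1]]
  n <- 20L
  for (i in seq_len(n)) {
    jid <- sprintf("jc%02d", i)
    kind <- sample(c("ok", "fail", "corrupt"), 1, prob = c(0.5, 0.3, 0.2))
    if (kind == "corrupt") {
      writeBin(as.raw(sample(0:255, 80, replace = TRUE)),
               file.path(input, sprintf("token_%s.zip", jid)))
    } else {
      code <- if (kind == "ok") "echo fine > results/r.txt" else "exit 1"
      write_token(script_token(jid, code), file.path(input, sprintf("token_%s.zip", jid)))
    }
  }
  pr$run_until_idle(timeout = 60)
  outs <- list.files(pr$config$output_folder)
  expect_identical(length(outs), n)
  expect_identical(length(list.files(input)), 0L)
  # every failure token carries a non-empty log
  for (f in outs) {
    out <- parse_output_token(file.path(pr$config$output_folder, f))
    if (out$status == "failure") {
      expect_gt(length(out$logs), 0)
      expect_gt(length(out$payload[[out$logs[1]]]), 0)
    }
  }
})

test_that("concurrent jobs write disjoint per-job log files", {
  pr <- make_processor(max_parallel = 3L)
  for (i in 1:3) {
    code <- sprintf("echo marker-job-%d\nsleep 0.2", i)
    write_token(script_token(sprintf("jl%d", i), code),
                file.path(pr$config$input_folders[[1]], sprintf("token_jl%d.zip", i)))
  }
  pr$run_until_idle()
  rec <- pr$records()
  expect_identical(anyDuplicated(rec$log_path), 0L)
  for (i in 1:3) {
    log <- readLines(rec$log_path[rec$job_id == sprintf("jl%d", i)])
    expect_true(any(grepl(sprintf("marker-job-%d", i), log)))
    expect_false(any(grepl(sprintf("marker-job-%d", (i %% 3) + 1), log)))
  }
})

test_that("runaway jobs are killed at the configured timeout and flagged", {
  cfg <- processor_config("ptimeout", root = new_root("proc-"),
                          max_parallel = 1L, timeout = 1)
  pr <- processor_agent(cfg)
  write_token(script_token("jhang", "sleep 30"),
              file.path(cfg$input_folders[[1]], "token_jhang.zip"))
  pr$run_until_idle(timeout = 30)
  out <- parse_output_token(file.path(cfg$output_folder, "out_jhang.zip"))
  expect_identical(out$status, "failure")
  expect_match(rawToChar(out$payload[[out$logs[1]]]), "timeout")
})
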