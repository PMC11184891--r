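#' Wire up a complete local sandbox
#'
#' Convenience constructor for a fully assembled single-host deployment:
#' permission agent, notary, scheduler, one or more processors, the proxy,
#' and one GUI channel, all rooted under one directory. Users get a local
#' password profile, an Ed25519 keypair registered with the notary, and
#' (optionally) grants on everything in the catalog.
#'
#' @param root deployment directory (created).
#' @param users named character vector `user_id = password`.
#' @param n_processors number of processor instances.
#' @param max_parallel per-processor concurrency bound.
#' @param clock shared [sandbox_clock()].
#' @param grant_all grant every user every registered fixture item.
#' @param with_fixtures register the demo patient datamart (100 rows) and
#'   the toy algorithm catalog.
#' @param channel_max_duration GUI channel session lifetime (seconds).
#' @param processor_timeout backend timeout (seconds).
#' @return a `sandbox_deployment` list: `proxy`, `perm`, `notary`,
#'   `scheduler`, `processors`, `channel`, `user_keys`, plus the helpers
#'   documented in [sandbox_submit()].
#' @examples
#' \donttest{
#' sb <- sandbox_local(tempfile("sb-"), users = c(alice = "pw"))
#' s <- sb$login("alice", "pw")
#' sb$submit(job_request("j1", s$ticket, "alice", "patients", "row_counter"))
#' sb$run()
#' sb$channel$read_status()
#' }
#' @export
sandbox_local <- function(root, users = c(alice = "alice-pw"),
                          n_processors = 1L, max_parallel = 2L,
                          clock = sandbox_clock(), grant_all = TRUE,
                          with_fixtures = TRUE, channel_max_duration = 3600,
                          processor_timeout = 60) {
  dir_create(root)
  perm <- perm_agent(clock = clock,
                     store_path = file.path(root, "perm_store.json"))
  notary <- notary_agent(file.path(root, "notary"), clock = clock)
  scheduler <- scheduler_agent(clock = clock,
                               journal_path = file.path(root, "scheduler.json"))
  proxy <- proxy_agent(perm, notary, scheduler = scheduler, clock = clock,
                       dir = file.path(root, "proxy"))
  repo <- dir_create(file.path(root, "repo", "algorithms"))
  image_store <- dir_create(file.path(root, "repo", "images"))

  processors <- list()
  for (i in seq_len(n_processors)) {
    pid <- sprintf("proc%02d", i)
    cfg <- processor_config(pid, root = file.path(root, "processors", pid),
                            max_parallel = max_parallel,
                            timeout = processor_timeout,
                            algorithm_repo = repo, image_store = image_store)
    processors[[pid]] <- processor_agent(cfg, clock = clock)
    proxy$register_processor(cfg)
    processors[[pid]]$step()  # initial heartbeat so the proxy sees it live
  }

  channel <- gui_channel(file.path(root, "channels", "ch1"), "ch1", clock = clock)
  proxy$register_channel(channel, max_duration = channel_max_duration)

  user_keys <- list()
  for (u in names(users)) {
    perm$add_principal(u)
    perm$add_local_profile(u, users[[u]])
    key <- openssl::ed25519_keygen()
    user_keys[[u]] <- key
    notary$register_user_key(u, as.list(key)$pubkey)
  }

  if (with_fixtures) {
    dm_dir <- dir_create(file.path(root, "repo", "datamarts"))
    schema <- demo_patient_schema()
    csv_path <- file.path(dm_dir, "patients.csv")
    generate_datamart(schema, 100L, path = csv_path)
    proxy$register_datamart(datamart_entry("patients", "Demo patient datamart",
                                           source = csv_path))
    algos <- toy_algorithm_catalog(repo)
    for (a in algos) proxy$register_algorithm(a)
    if (grant_all) {
      for (u in names(users)) {
        perm$grant(u, "patients")
        for (a in algos) perm$grant(u, a$item_id)
      }
    }
  }

  sb <- list(
    root = root, clock = clock, perm = perm, notary = notary,
    scheduler = scheduler, proxy = proxy, processors = processors,
    channel = channel, user_keys = user_keys,
    algorithm_repo = repo, image_store = image_store
  )
  sb$login <- function(user_id, password) {
    proxy$authenticate(channel, user_id, password)
  }
  sb$submit <- function(request) channel$write_job(request)
  sb$run <- function(max_wait = 60) sandbox_run_until_idle(sb, max_wait)
  sb$countersign <- function(job_id, user_id) {
    sig <- user_countersign(notary$signed_envelope(job_id), user_keys[[user_id]],
                            sandbox_pubkey = notary$sandbox_pubkey())
    notary$countersign(job_id, sig, user_id)
    channel$deliver("info.status.job", job_id, "officially issued (countersigned)")
    invisible(notary$report_state(job_id))
  }
  class(sb) <- "sandbox_deployment"
  sb
}

#' Run a deployment until all submitted jobs reach a terminal state
#'
#' Alternates proxy cycles and processor steps until no job is pending
#' (or `max_wait` wall-clock seconds pass). Terminal job states are
#' `completed`, `signed`, `failed`, `denied`, `auth-required`, `scheduled`.
#'
#' @param sb a [sandbox_local()] deployment.
#' @param max_wait wall-clock bound in seconds.
#' @return invisible `NULL`.
#' @export
sandbox_run_until_idle <- function(sb, max_wait = 60) {
  terminal <- c("completed", "signed", "failed", "denied", "auth-required",
                "scheduled")
  deadline <- Sys.time() + max_wait
  repeat {
    sb$proxy$cycle()
    for (p in sb$processors) p$step()
    sb$proxy$monitor_outputs()
    jobs <- sb$proxy$jobs()
    busy_proc <- any(vapply(sb$processors,
                            function(p) p$n_active() + p$n_queued() > 0L, TRUE))
    pending <- nrow(jobs) > 0L && !all(jobs$state %in% terminal)
    if (!busy_proc && !pending) break
    if (Sys.time() > deadline) {
      stop_sandbox("sandbox_timeout_error",
                   "deployment did not go idle within %ss", max_wait)
    }
    Sys.sleep(0.02)
  }
  invisible(NULL)
}

#' @rdname sandbox_local
#' @param sb deployment (for the helper form `sandbox_submit(sb, request)`).
#' @param request a [job_request()].
#' @export
sandbox_submit <- function(sb, request) sb$submit(request)

#' Generate, register and grant a synthetic datamart in one call
#'
#' Writes the generated CSV under the deployment's datamart repository,
#' registers it in the proxy catalog (which registers the permission item),
#' and optionally grants it to users.
#'
#' @param sb a [sandbox_local()] deployment.
#' @param schema a [synthetic_schema()].
#' @param n_rows rows to generate.
#' @param grant_to user/group ids to grant the new item to.
#' @return the catalog item id.
#' @export
register_datamart_fixture <- function(sb, schema, n_rows, grant_to = character()) {
  dm_dir <- dir_create(file.path(sb$root, "repo", "datamarts"))
  path <- file.path(dm_dir, paste0(schema$name, ".csv"))
  generate_datamart(schema, n_rows, path = path)
  sb$proxy$register_datamart(datamart_entry(schema$name, schema$name, source = path))
  for (s in grant_to) sb$perm$grant(s, schema$name)
  schema$name
}

#' Scripted scenario runner for the fixture GUI
#'
#' Plays an ordered list of submissions against a deployment, runs it to
#' quiescence, and checks each job's expected terminal state; on violation
#' it fails with the channel transcript attached. Used by the protocol
#' conformance tests.
#'
#' @param sb a [sandbox_local()] deployment.
#' @param steps list of steps: each a list with `request` (a
#'   [job_request()]) and `expect` (a terminal proxy job state).
#' @return data frame of job_id, expected and observed states.
#' @export
run_scenario <- function(sb, steps) {
  for (s in steps) sb$submit(s$request)
  sb$run()
  jobs <- sb$proxy$jobs()
  out <- do.call(rbind, lapply(steps, function(s) {
    observed <- jobs$state[jobs$job_id == s$request$job_id]
    data.frame(job_id = s$request$job_id, expected = s$expect,
               observed = if (length(observed)) observed else NA_character_,
               stringsAsFactors = FALSE)
  }))
  bad <- out[is.na(out$observed) | out$expected != out$observed, , drop = FALSE]
  if (nrow(bad)) {
    stop_sandbox("sandbox_scenario_error",
                 "scenario violation for job(s) %s; transcript:\n%s",
                 paste(bad$job_id, collapse = ", "),
                 substr(sb$channel$transcript_text(), 1L, 4000L))
  }
  out
}
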