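# The proxy: central coordinator of the platform. It polls GUI channels for
# job requests, checks permissions with the permission agent, resolves data
# and algorithms from certified local repositories, prepares and dispatches
# tokens with load balancing across processors, monitors their output
# folders, and routes every request and result through notarisation. It is
# the only component that touches both the outside channel and the data.

#' Catalog entries
#'
#' Datamarts and algorithms offered by the platform are
#' certified-by-configuration: only entries registered in the proxy catalog
#' (programmatically or via a YAML registry file) are offered. Registering an
#' entry also registers the corresponding permission item.
#'
#' @param item_id catalog / permission item id.
#' @param name display name.
#' @param source data source: a CSV file path, or a [connector_spec()].
#' @param description free-text metadata.
#' @return a `datamart_entry` / `algorithm_entry` object.
#' @export
datamart_entry <- function(item_id, name = item_id, source, description = "") {
  assert_safe_id(item_id, "item_id")
  if (is.character(source)) source <- connector_spec("csv", path = source)
  if (!inherits(source, "connector_spec")) {
    stop_sandbox("sandbox_config_error", "source must be a path or connector_spec")
  }
  fields <- tryCatch(names(connector_fetch(source, query = NULL, peek = TRUE)),
                     error = function(e) character())
  structure(list(item_id = item_id, name = name, source = source,
                 description = description, fields = fields),
            class = "datamart_entry")
}

#' @rdname datamart_entry
#' @param kind `"script"` or `"image"`.
#' @param locator script path in the local repository, or local image name.
#' @param input_hints free-form schema hints (e.g. required target type).
#' @export
algorithm_entry <- function(item_id, name = item_id, kind = c("script", "image"),
                            locator, input_hints = NULL) {
  assert_safe_id(item_id, "item_id")
  kind <- match.arg(kind)
  assert_scalar_string(locator, "locator")
  structure(list(item_id = item_id, name = name, kind = kind,
                 locator = locator, input_hints = input_hints),
            class = "algorithm_entry")
}

#' Relational connector contract
#'
#' Datamarts can live in the proxy as CSV files or be fetched on demand
#' through a registered connector. A connector is a function
#' `function(spec, query) -> data.frame`; only the `csv` connector ships,
#' SQL dialects (mysql, sqlserver, sasviya) are documented extension points
#' registered with [register_connector()].
#'
#' @param dialect dialect tag, e.g. `"csv"`.
#' @param ... connection parameters (for csv: `path`).
#' @return a `connector_spec`.
#' @export
connector_spec <- function(dialect, ...) {
  assert_scalar_string(dialect, "dialect")
  structure(list(dialect = dialect, params = list(...)), class = "connector_spec")
}

connector_env <- new.env(parent = emptyenv())

#' @rdname connector_spec
#' @param fetch `function(spec, query)` returning a data frame.
#' @export
register_connector <- function(dialect, fetch) {
  assign(dialect, fetch, envir = connector_env)
  invisible(dialect)
}

#' @rdname connector_spec
#' @param spec a `connector_spec`.
#' @param query optional [cohort_query()] applied to the fetched table.
#' @param peek internal: header-only fetch for metadata.
#' @export
connector_fetch <- function(spec, query = NULL, peek = FALSE) {
  fetch <- if (exists(spec$dialect, envir = connector_env)) {
    get(spec$dialect, envir = connector_env)
  } else {
    stop_sandbox("sandbox_config_error",
                 "no connector registered for dialect '%s'", spec$dialect)
  }
  fetch(spec, query = query, peek = peek)
}

csv_connector <- function(spec, query = NULL, peek = FALSE) {
  path <- spec$params$path
  if (is.null(path) || !file.exists(path)) {
    stop_sandbox("sandbox_config_error", "csv source '%s' not found", path %||% "<missing>")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        nrows = if (peek) 1L else -1L)
  if (peek) return(df)
  apply_cohort_query(df, query)
}

#' Proxy agent
#'
#' See [proxy_agent()] for construction. Drive it with `$cycle()` (scheduler
#' tick, channel poll, pending dispatches, output monitoring) while stepping
#' the processors, or use the [sandbox_local()] wiring which loops both.
#'
#' @param perm a [perm_agent()].
#' @param notary a [notary_agent()] (anything with the same surface).
#' @param scheduler optional [scheduler_agent()]; scheduling requests are
#'   refused if absent.
#' @param clock a [sandbox_clock()].
#' @param dir proxy working directory (quarantine, consumed outputs).
#' @param heartbeat_max_age seconds before a processor heartbeat counts as
#'   stale and the processor as not live.
#' @return `proxy_agent()` returns a `Proxy` R6 object.
#' @export
proxy_agent <- function(perm, notary, scheduler = NULL,
                        clock = sandbox_clock(), dir = tempfile("proxy-"),
                        heartbeat_max_age = 60) {
  Proxy$new(perm = perm, notary = notary, scheduler = scheduler,
            clock = clock, dir = dir, heartbeat_max_age = heartbeat_max_age)
}

#' @rdname proxy_agent
#' @export
Proxy <- R6::R6Class("Proxy",
  public = list(
    #' @field perm the permission agent.
    perm = NULL,
    #' @field notary the notarisation agent.
    notary = NULL,
    #' @field scheduler the scheduler agent (or NULL).
    scheduler = NULL,
    #' @field clock injected clock.
    clock = NULL,
    #' @field dir proxy working directory.
    dir = NULL,

    #' @description Create the proxy.
    #' @param perm,notary,scheduler,clock,dir,heartbeat_max_age
    #'   see [proxy_agent()].
    initialize = function(perm, notary, scheduler = NULL,
                          clock = sandbox_clock(), dir = tempfile("proxy-"),
                          heartbeat_max_age = 60) {
      self$perm <- perm
      self$notary <- notary
      self$scheduler <- scheduler
      self$clock <- clock
      self$dir <- dir_create(dir)
      dir_create(file.path(dir, "quarantine"))
      dir_create(file.path(dir, "consumed"))
      private$hb_max_age <- heartbeat_max_age
      if (!is.null(scheduler) && is.null(scheduler$submit)) {
        scheduler$submit <- function(request) {
          ch_id <- request$channel_id
          request$channel_id <- NULL
          private$enqueue(do.call(job_request, request), channel_id = ch_id)
          TRUE
        }
      }
    },

    # -- catalog ------------------------------------------------------------

    #' @description Register a datamart; also registers the permission item.
    #' @param entry a [datamart_entry()].
    register_datamart = function(entry) {
      if (!inherits(entry, "datamart_entry")) {
        stop_sandbox("sandbox_config_error", "entry must be a datamart_entry")
      }
      if (!self$perm$has_item(entry$item_id)) self$perm$add_item(entry$item_id, "datamart")
      private$datamarts[[entry$item_id]] <- entry
      private$catalog_version <- private$catalog_version + 1L
      invisible(entry$item_id)
    },

    #' @description Register an algorithm; also registers the permission
    #'   item. Locators always point into the local repository.
    #' @param entry an [algorithm_entry()].
    register_algorithm = function(entry) {
      if (!inherits(entry, "algorithm_entry")) {
        stop_sandbox("sandbox_config_error", "entry must be an algorithm_entry")
      }
      if (!self$perm$has_item(entry$item_id)) self$perm$add_item(entry$item_id, "algorithm")
      private$algorithms[[entry$item_id]] <- entry
      private$catalog_version <- private$catalog_version + 1L
      invisible(entry$item_id)
    },

    #' @description Load a YAML registry of datamarts/algorithms.
    #' @param path registry file with top-level `datamarts:` and
    #'   `algorithms:` lists.
    load_registry = function(path) {
      reg <- yaml::read_yaml(path)
      for (d in reg$datamarts %||% list()) {
        src <- if (!is.null(d$connector)) {
          do.call(connector_spec, c(list(d$connector$dialect), d$connector$params))
        } else d$path
        self$register_datamart(datamart_entry(
          d$item_id, name = d$name %||% d$item_id, source = src,
          description = d$description %||% ""
        ))
      }
      for (a in reg$algorithms %||% list()) {
        self$register_algorithm(algorithm_entry(
          a$item_id, name = a$name %||% a$item_id,
          kind = a$kind %||% "script", locator = a$locator
        ))
      }
      invisible(NULL)
    },

    # -- processors and channels --------------------------------------------

    #' @description Register a processor by its folder contract.
    #' @param config the processor's [processor_config()].
    register_processor = function(config) {
      private$processors[[config$processor_id]] <- list(
        config = config, forwarded = 0L, completed = 0L, failed = 0L
      )
      invisible(config$processor_id)
    },

    #' @description Register (and establish) a GUI channel.
    #' @param channel a [gui_channel()].
    #' @param max_duration channel session lifetime in seconds.
    register_channel = function(channel, max_duration = 3600) {
      channel$establish(max_duration)
      private$channels[[channel$channel_id]] <- channel
      invisible(channel$channel_id)
    },

    #' @description Authenticate a user on a channel; on success the ticket
    #'   is attached to the channel's nested session.
    #' @param channel a registered channel.
    #' @param user_id,credentials,profile forwarded to the permission agent.
    #' @return the session, or `NULL` on failure.
    authenticate = function(channel, user_id, credentials, profile = "local") {
      s <- self$perm$authenticate(user_id, credentials, profile)
      if (!is.null(s)) channel$set_session(s$ticket, user_id)
      s
    },

    # -- operations ---------------------------------------------------------

    #' @description Poll every live channel: read each unconsumed MMT entry's
    #'   detail file, acknowledge it, and queue the request. An unreadable
    #'   detail file yields an error message on that channel only.
    #' @return list of newly consumed job requests.
    poll_channels = function() {
      consumed <- list()
      for (ch in private$channels) {
        if (!ch$live()) next
        for (e in ch$unconsumed_entries()) {
          req <- tryCatch(ch$read_job(e$detail_file), error = function(err) err)
          ch$mark_consumed(e$entry_id)
          if (inherits(req, "error")) {
            ch$deliver("error.request", e$job_id,
                       paste0("unreadable job detail: ", conditionMessage(req)))
            private$log_event("request-error", e$job_id)
            next
          }
          private$log_event("request-consumed", req$job_id)
          ch$deliver("info.status.job", req$job_id, "queued")
          private$log_event("ack-queued", req$job_id)
          private$enqueue(req, channel_id = ch$channel_id)
          consumed[[length(consumed) + 1L]] <- req
        }
      }
      consumed
    },

    #' @description Permission decision for a request's (datamart,
    #'   algorithm) pair, delegated to the permission agent.
    #' @param req a [job_request()].
    authorize = function(req) {
      self$perm$check_pair(req$ticket, req$datamart, req$algorithm)
    },

    #' @description Resolve a datamart to its tabular payload, applying an
    #'   optional cohort query, serialised as CSV text for the token.
    #' @param item_id catalog datamart.
    #' @param query optional [cohort_query()].
    #' @return list: `df` and `csv` (single string).
    resolve_datamart = function(item_id, query = NULL) {
      entry <- private$datamarts[[item_id]]
      if (is.null(entry)) {
        stop_sandbox("sandbox_config_error", "datamart '%s' not in catalog", item_id)
      }
      df <- connector_fetch(entry$source, query = query)
      con <- textConnection(NULL, "w")
      utils::write.csv(df, con, row.names = FALSE)
      csv <- paste(textConnectionValue(con), collapse = "\n")
      close(con)
      list(df = df, csv = paste0(csv, "\n"))
    },

    #' @description Pick the processor for the next token: minimum ongoing
    #'   count, ties broken by least forwarded, then lexical id; only
    #'   processors with a fresh heartbeat are considered.
    #' @return processor id, or `NULL` when none is live.
    select_processor = function() {
      live <- Filter(private$processor_live, names(private$processors))
      if (!length(live)) return(NULL)
      st <- lapply(live, function(id) private$processors[[id]])
      ongoing <- vapply(st, function(s) s$forwarded - s$completed - s$failed, 0L)
      forwarded <- vapply(st, function(s) s$forwarded, 0L)
      live[order(ongoing, forwarded, live)][1]
    },

    #' @description Processor load counters (forwarded / completed / failed /
    #'   ongoing) as a data frame.
    processor_states = function() {
      do.call(rbind, lapply(names(private$processors), function(id) {
        s <- private$processors[[id]]
        data.frame(processor_id = id, forwarded = s$forwarded,
                   completed = s$completed, failed = s$failed,
                   ongoing = s$forwarded - s$completed - s$failed,
                   stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description History of counter snapshots, one per counter event
    #'   (for invariant checking).
    counter_log = function() private$counters_log,

    #' @description Run one full proxy cycle: scheduler tick, channel poll,
    #'   handling of queued/held jobs, output monitoring.
    cycle = function() {
      if (!is.null(self$scheduler)) self$scheduler$tick()
      self$poll_channels()
      for (jid in names(private$job_table)) {
        j <- private$job_table[[jid]]
        if (j$state %in% c("queued", "held", "waiting-processor")) private$handle(jid)
      }
      self$monitor_outputs()
      invisible(NULL)
    },

    #' @description Match every deposited output token to its request,
    #'   notarise the result, route success through report signing, and
    #'   forward artefacts and logs to the originating channel. Orphan
    #'   outputs are quarantined and logged, never forwarded.
    monitor_outputs = function() {
      for (pid in names(private$processors)) {
        out_dir <- private$processors[[pid]]$config$output_folder
        for (f in list.files(out_dir, pattern = "^out_.*\\.zip$", full.names = TRUE)) {
          jid <- sub("^out_(.*)\\.zip$", "\\1", basename(f))
          j <- private$job_table[[jid]]
          if (is.null(j) || !identical(j$processor_id, pid) ||
              !j$state %in% c("dispatched")) {
            file.rename(f, file.path(self$dir, "quarantine", basename(f)))
            private$operator_log <- c(private$operator_log,
                                      sprintf("quarantined orphan output %s from %s",
                                              basename(f), pid))
            next
          }
          private$ingest_output(jid, pid, f)
        }
      }
      invisible(NULL)
    },

    #' @description Platform information for GUIs.
    #' @param kind `"processor-count"` or `"catalog-update"`.
    platform_info = function(kind = c("processor-count", "catalog-update")) {
      kind <- match.arg(kind)
      if (kind == "processor-count") {
        n <- length(Filter(private$processor_live, names(private$processors)))
        list(count = n, degraded = n == 0L)
      } else {
        list(
          version = private$catalog_version,
          datamarts = lapply(private$datamarts, function(d) {
            list(item_id = d$item_id, name = d$name, description = d$description,
                 fields = d$fields)
          }),
          algorithms = lapply(private$algorithms, function(a) {
            list(item_id = a$item_id, name = a$name, kind = a$kind)
          })
        )
      }
    },

    #' @description Job lifecycle state (`NULL` if unknown).
    #' @param job_id job id.
    job_state = function(job_id) private$job_table[[job_id]]$state,

    #' @description All job states as a data frame.
    jobs = function() {
      do.call(rbind, lapply(names(private$job_table), function(jid) {
        j <- private$job_table[[jid]]
        data.frame(job_id = jid, state = j$state,
                   processor_id = j$processor_id %||% NA_character_,
                   channel_id = j$channel_id %||% NA_character_,
                   stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description Ordered event log (seq, event, job_id, time).
    events = function() {
      do.call(rbind, lapply(private$event_log, function(e) {
        data.frame(seq = e$seq, event = e$event, job_id = e$job_id,
                   time = e$time, stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description Operator log lines (quarantine notices etc.).
    operator_logs = function() private$operator_log
  ),
  private = list(
    datamarts = list(), algorithms = list(), processors = list(),
    channels = list(), job_table = list(), event_log = list(), counters_log = list(),
    operator_log = character(), catalog_version = 0L, hb_max_age = 60,
    seq = 0L,

    log_event = function(event, job_id) {
      private$seq <- private$seq + 1L
      private$event_log[[length(private$event_log) + 1L]] <- list(
        seq = private$seq, event = event, job_id = job_id,
        time = self$clock$now_iso()
      )
    },

    bump = function(pid, field) {
      private$processors[[pid]][[field]] <- private$processors[[pid]][[field]] + 1L
      s <- private$processors[[pid]]
      private$counters_log[[length(private$counters_log) + 1L]] <- list(
        processor_id = pid, forwarded = s$forwarded, completed = s$completed,
        failed = s$failed, ongoing = s$forwarded - s$completed - s$failed
      )
    },

    enqueue = function(req, channel_id) {
      if (!is.null(private$job_table[[req$job_id]])) {
        private$channel_deliver(channel_id, "error.request", req$job_id,
                                "duplicate job id")
        return(invisible(NULL))
      }
      private$job_table[[req$job_id]] <- list(
        request = req, channel_id = channel_id, state = "queued",
        processor_id = NULL, notarised = FALSE, warned_no_processor = FALSE
      )
      invisible(NULL)
    },

    channel_deliver = function(channel_id, code, job_id, payload = "", files = NULL) {
      ch <- private$channels[[channel_id %||% ""]]
      if (is.null(ch) || !ch$live()) return(invisible(NULL))
      ch$deliver(code, job_id, payload, files = files)
      invisible(NULL)
    },

    handle = function(jid) {
      j <- private$job_table[[jid]]
      req <- j$request
      if (j$state == "queued") {
        decision <- self$authorize(req)
        private$log_event("perm-check", jid)
        if (decision == "auth-required") {
          private$channel_deliver(j$channel_id, "error.auth", jid,
                                  "authentication required: session ticket not live")
          private$job_table[[jid]]$state <- "auth-required"
          private$log_event("auth-required", jid)
          return(invisible(NULL))
        }
        if (decision == "deny") {
          private$channel_deliver(
            j$channel_id, "error.denied", jid,
            sprintf("permission denied for pair (%s, %s)", req$datamart, req$algorithm)
          )
          private$job_table[[jid]]$state <- "denied"
          private$log_event("denied", jid)
          return(invisible(NULL))
        }
        if (!is.null(req$schedule)) {
          if (is.null(self$scheduler)) {
            private$channel_deliver(j$channel_id, "error.request", jid,
                                    "scheduling requested but no scheduler is configured")
            private$job_table[[jid]]$state <- "failed"
            return(invisible(NULL))
          }
          template <- unclass(req)
          template$schedule <- NULL
          template$channel_id <- j$channel_id
          task_id <- self$scheduler$add_task(template, req$schedule)
          private$channel_deliver(j$channel_id, "info.status.job", jid,
                                  paste0("scheduled as ", task_id))
          private$job_table[[jid]]$state <- "scheduled"
          private$log_event("scheduled", jid)
          return(invisible(NULL))
        }
        private$job_table[[jid]]$state <- "held"  # authorized, awaiting notarisation
      }
      private$dispatch(jid)
    },

    # Notarise the request (metadata only, devoid of data) BEFORE any token
    # is built or deposited; a notarisation failure holds the job for retry,
    # it is never executed un-notarised.
    dispatch = function(jid) {
      j <- private$job_table[[jid]]
      req <- j$request
      if (req$notarise && !j$notarised) {
        meta <- jsonlite::toJSON(list(
          user_id = req$user_id, datamart = req$datamart,
          algorithm = req$algorithm, timestamp = self$clock$now_iso()
        ), auto_unbox = TRUE)
        res <- tryCatch(
          self$notary$notarize(charToRaw(as.character(meta)), job_id = jid,
                               role = "request", user = req$user_id),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          private$job_table[[jid]]$state <- "held"
          private$log_event("notarise-request-failed", jid)
          return(invisible(NULL))
        }
        private$job_table[[jid]]$notarised <- TRUE
        private$log_event("notarise-request", jid)
      }
      prepared <- tryCatch(private$prepare_token(req), error = function(e) e)
      if (inherits(prepared, "error")) {
        private$channel_deliver(j$channel_id, "error.request", jid,
                                conditionMessage(prepared))
        private$job_table[[jid]]$state <- "failed"
        private$log_event("prepare-failed", jid)
        return(invisible(NULL))
      }
      pid <- self$select_processor()
      if (is.null(pid)) {
        if (!isTRUE(private$job_table[[jid]]$warned_no_processor)) {
          private$channel_deliver(j$channel_id, "info.status.job", jid,
                                  "queued: no live processor, will retry")
          private$job_table[[jid]]$warned_no_processor <- TRUE
          private$log_event("no-processor-warning", jid)
        }
        private$job_table[[jid]]$state <- "waiting-processor"
        return(invisible(NULL))
      }
      input_dir <- private$processors[[pid]]$config$input_folders[[1]]
      write_token(prepared, file.path(input_dir, paste0("token_", jid, ".zip")))
      private$bump(pid, "forwarded")
      private$job_table[[jid]]$processor_id <- pid
      private$job_table[[jid]]$state <- "dispatched"
      private$log_event("token-deposited", jid)
      private$channel_deliver(j$channel_id, "info.assigned.proc", jid, pid)
      private$log_event("assigned-msg", jid)
      private$channel_deliver(j$channel_id, "info.status.job", jid, "running")
      private$log_event("status-running-msg", jid)
      invisible(NULL)
    },

    prepare_token = function(req) {
      alg <- private$algorithms[[req$algorithm]]
      if (is.null(alg)) {
        stop_sandbox("sandbox_config_error", "algorithm '%s' not in catalog", req$algorithm)
      }
      resolved <- self$resolve_datamart(req$datamart, req$query)
      payload <- list("data/datamart.csv" = resolved$csv)
      if (alg$kind == "script") {
        script_name <- paste0("algo/run.", tools::file_ext(alg$locator))
        payload[[script_name]] <- read_file_raw(alg$locator)
        aref <- algo_script(script_name)
      } else {
        aref <- algo_image(alg$locator)
      }
      d <- token_descriptor(
        job_id = req$job_id, user_id = req$user_id, algorithm_ref = aref,
        datamart_ref = dm_payload("data/datamart.csv"),
        column_roles = req$column_roles, run_settings = req$run_settings,
        notarise = req$notarise, sign = req$sign,
        created_at = self$clock$now_iso()
      )
      build_token(d, payload)
    },

    processor_live = function(pid) {
      cfg <- private$processors[[pid]]$config
      hb <- file.path(cfg$sync_folder, paste0("heartbeat_", pid))
      if (!file.exists(hb)) return(FALSE)
      ts <- parse_iso8601(readLines(hb, warn = FALSE)[1])
      is.finite(as.numeric(ts)) &&
        as.numeric(difftime(self$clock$now(), ts, units = "secs")) <= private$hb_max_age
    },

    ingest_output = function(jid, pid, path) {
      bytes <- read_file_raw(path)
      out <- tryCatch(parse_output_token(bytes), error = function(e) e)
      file.rename(path, file.path(self$dir, "consumed", basename(path)))
      j <- private$job_table[[jid]]
      req <- j$request
      private$log_event("output-seen", jid)
      if (inherits(out, "error")) {
        private$bump(pid, "failed")
        private$channel_deliver(j$channel_id, "error.job", jid,
                                paste0("unreadable output token: ", conditionMessage(out)))
        private$job_table[[jid]]$state <- "failed"
        return(invisible(NULL))
      }
      if (req$notarise) {
        tryCatch({
          self$notary$notarize(bytes, job_id = jid, role = "result", user = req$user_id)
          private$log_event("notarise-result", jid)
        }, error = function(e) NULL)
      }
      log_text <- paste(vapply(out$payload[out$logs], rawToChar, ""), collapse = "\n")
      if (out$status == "failure") {
        private$bump(pid, "failed")
        private$channel_deliver(j$channel_id, "error.job", jid,
                                paste0("job failed; log excerpt:\n",
                                       substr(log_text, 1L, 2000L)))
        private$job_table[[jid]]$state <- "failed"
        private$log_event("failure-delivered", jid)
        return(invisible(NULL))
      }
      private$bump(pid, "completed")
      result_members <- out$payload[out$results]
      names(result_members) <- basename(names(result_members) %||% character())
      if (req$sign) {
        report <- private$render_report(jid, out)
        self$notary$sign_report(jid, report, user = req$user_id)
        private$log_event("report-signed", jid)
        files <- c(result_members, stats::setNames(
          list(self$notary$signed_envelope(jid)),
          paste0("report_", jid, ".signed.json")
        ))
        private$channel_deliver(j$channel_id, "info.status.job", jid,
                                "done: result signed, awaiting countersignature",
                                files = files)
        private$job_table[[jid]]$state <- "signed"
      } else {
        private$channel_deliver(j$channel_id, "info.status.job", jid, "done",
                                files = result_members)
        private$job_table[[jid]]$state <- "completed"
      }
      private$log_event("result-delivered", jid)
      invisible(NULL)
    },

    # The report the dual-signature workflow covers: every result member,
    # framed, as one text artefact.
    render_report = function(jid, out) {
      parts <- vapply(out$results, function(m) {
        paste0("== ", m, " ==\n", rawToChar(out$payload[[m]]))
      }, "")
      charToRaw(paste0("report for job ", jid, "\n", paste(parts, collapse = "\n")))
    }
  )
)
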