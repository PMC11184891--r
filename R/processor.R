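#' Processor configuration
#'
#' A processor watches one or more input folders for token archives, executes
#' the described task, and reports the outcome into its output folder as a
#' new (output) token, while heart-beating into a sync folder the proxy
#' reads. The folder layout is
#' `<input>/token_<jobid>.zip` -> claimed into `<processing>/` -> archived in
#' `<done>/`, with `<output>/out_<jobid>.zip` and `<sync>/<jobid>.status`.
#'
#' @param processor_id identifier, used in heartbeat/status files.
#' @param root convenience: create the standard sub-folders under this
#'   directory (`input/`, `processing/`, `done/`, `output/`, `sync/`,
#'   `work/`, `logs/`). Individual paths can be overridden.
#' @param input_folders,processing_folder,done_folder,output_folder,sync_folder,work_root,log_folder explicit folder paths.
#' @param poll_interval seconds between polls when free-running.
#' @param max_parallel maximum number of concurrent executions (>= 1);
#'   surplus claimed tokens queue in claim order.
#' @param timeout backend wall-clock timeout in seconds (default 1 hour);
#'   a timed-out job yields a failure token flagged as timeout.
#' @param algorithm_repo optional directory of locally certified algorithm
#'   scripts resolved by locator references.
#' @param image_store optional local container image store directory (see
#'   [image_store_add()]); images absent from it are refused, never pulled.
#' @return a `processor_config` list.
#' @export
processor_config <- function(processor_id, root = NULL,
                             input_folders = NULL, processing_folder = NULL,
                             done_folder = NULL, output_folder = NULL,
                             sync_folder = NULL, work_root = NULL,
                             log_folder = NULL,
                             poll_interval = 2, max_parallel = 1L,
                             timeout = 3600, algorithm_repo = NULL,
                             image_store = NULL) {
  assert_safe_id(processor_id, "processor_id")
  if (!is.null(root)) {
    dir_create(root)
    input_folders <- input_folders %||% file.path(root, "input")
    processing_folder <- processing_folder %||% file.path(root, "processing")
    done_folder <- done_folder %||% file.path(root, "done")
    output_folder <- output_folder %||% file.path(root, "output")
    sync_folder <- sync_folder %||% file.path(root, "sync")
    work_root <- work_root %||% file.path(root, "work")
    log_folder <- log_folder %||% file.path(root, "logs")
  }
  folders <- c(input_folders, processing_folder, done_folder, output_folder,
               sync_folder, work_root, log_folder)
  if (anyDuplicated(folders)) {
    stop_sandbox("sandbox_config_error", "processor folders must be distinct")
  }
  for (f in folders) dir_create(f)
  if (!is.numeric(max_parallel) || max_parallel < 1) {
    stop_sandbox("sandbox_config_error", "max_parallel must be >= 1")
  }
  structure(list(
    processor_id = processor_id, input_folders = input_folders,
    processing_folder = processing_folder, done_folder = done_folder,
    output_folder = output_folder, sync_folder = sync_folder,
    work_root = work_root, log_folder = log_folder,
    poll_interval = poll_interval, max_parallel = as.integer(max_parallel),
    timeout = timeout, algorithm_repo = algorithm_repo,
    image_store = image_store
  ), class = "processor_config")
}

#' Local container image store
#'
#' The container backend only runs images that have been loaded into the
#' local store by the infrastructure manager; pulling from external
#' registries is not enabled, so an absent image is refused outright. The
#' built-in store is a directory of loaded images, each mapping the image
#' name to its entrypoint script, executed in the job's working directory
#' (a simulated OCI runner; a real container engine can be substituted
#' behind the same layout).
#'
#' @param store store directory.
#' @param image image name (filesystem-safe).
#' @param entrypoint path to the entrypoint script to load.
#' @return the image directory, invisibly.
#' @export
image_store_add <- function(store, image, entrypoint) {
  assert_safe_id(image, "image name")
  img_dir <- dir_create(file.path(store, image))
  dest <- file.path(img_dir, paste0("entrypoint.", tools::file_ext(entrypoint)))
  file.copy(entrypoint, dest, overwrite = TRUE)
  invisible(img_dir)
}

interpreter_for <- function(path) {
  switch(tolower(tools::file_ext(path)),
    "r" = "Rscript",
    "py" = "python",
    "sh" = "sh",
    stop_sandbox("sandbox_backend_error",
                 "no interpreter registered for script '%s'", basename(path))
  )
}

#' Black-box task executor
#'
#' The processor claims tokens from its input folders (atomic rename into a
#' per-processor `processing/` directory, so the token disappears from the
#' input folder while processed and is never double-claimed), executes each
#' task in an isolated working directory through a pluggable backend (script
#' interpreter or local container image), and deposits an output token. It
#' never crashes on bad input: unreadable or corrupt tokens yield a failure
#' output token whose log carries the parse error. Executions run in
#' background subprocesses, at most `max_parallel` at a time, each with its
#' own log file.
#'
#' Drive it with `$step()` (one poll cycle: heartbeat, reap finished jobs,
#' claim new tokens, start queued jobs) or `$run_until_idle()`.
#'
#' @param config a [processor_config()].
#' @param clock a [sandbox_clock()].
#' @return `processor_agent()` returns a `Processor` R6 object.
#' @export
processor_agent <- function(config, clock = sandbox_clock()) {
  Processor$new(config = config, clock = clock)
}

#' @rdname processor_agent
#' @export
Processor <- R6::R6Class("Processor",
  public = list(
    #' @field config the [processor_config()].
    config = NULL,
    #' @field clock the injected clock.
    clock = NULL,

    #' @description Create the processor.
    #' @param config,clock see [processor_agent()].
    initialize = function(config, clock = sandbox_clock()) {
      if (!inherits(config, "processor_config")) {
        stop_sandbox("sandbox_config_error", "config must be a processor_config")
      }
      self$config <- config
      self$clock <- clock
    },

    #' @description One poll cycle. Returns (invisibly) a list with counts
    #'   of claimed, started and finished jobs in this cycle.
    step = function() {
      private$heartbeat()
      finished <- private$reap()
      claimed <- private$claim()
      started <- private$start_queued()
      invisible(list(claimed = claimed, started = started, finished = finished))
    },

    #' @description Step until no work remains (or `timeout` seconds pass).
    #' @param timeout wall-clock bound in seconds.
    run_until_idle = function(timeout = 60) {
      deadline <- Sys.time() + timeout
      repeat {
        self$step()
        if (!private$busy()) break
        if (Sys.time() > deadline) {
          stop_sandbox("sandbox_timeout_error", "processor did not go idle in %ss", timeout)
        }
        Sys.sleep(0.02)
      }
      invisible(NULL)
    },

    #' @description Number of currently running executions.
    n_active = function() length(private$active),

    #' @description Number of claimed-but-not-started tokens.
    n_queued = function() length(private$queue),

    #' @description Completed execution records as a data frame (one row per
    #'   job: backend, timestamps, exit status, log path).
    records = function() {
      do.call(rbind, lapply(private$done_records, function(r) {
        data.frame(job_id = r$job_id, backend = r$backend,
                   started_at = r$started_at, finished_at = r$finished_at,
                   exit_status = r$exit_status, status = r$status,
                   log_path = r$log_path, stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description Execute one already-parsed token synchronously (start +
    #'   wait). Exposed for direct use and tests; the watch loop goes through
    #'   `$step()`.
    #' @param token a `sandbox_token` or raw archive bytes.
    #' @return the deposited `sandbox_output_token`.
    execute_token = function(token) {
      src <- if (inherits(token, "sandbox_token")) token$archive else token
      tmp <- file.path(self$config$processing_folder,
                       paste0("direct-", rand_hex(4L), ".zip"))
      writeBin(as_raw_bytes(src), tmp)
      private$launch(tmp)
      self$run_until_idle(timeout = self$config$timeout + 30)
      rec <- private$done_records[[length(private$done_records)]]
      parse_output_token(file.path(self$config$output_folder,
                                   paste0("out_", rec$job_id, ".zip")))
    }
  ),
  private = list(
    active = list(), queue = list(), done_records = list(),

    heartbeat = function() {
      hb <- file.path(self$config$sync_folder,
                      paste0("heartbeat_", self$config$processor_id))
      atomic_write_lines(self$clock$now_iso(), hb)
    },

    busy = function() {
      length(private$active) > 0L || length(private$queue) > 0L ||
        length(private$pending_inputs()) > 0L
    },

    pending_inputs = function() {
      unlist(lapply(self$config$input_folders, function(f) {
        list.files(f, pattern = "^token_.*\\.zip$", full.names = TRUE)
      })) %||% character()
    },

    # Claim order: modification time, then name, across all input folders.
    claim = function() {
      files <- private$pending_inputs()
      if (!length(files)) return(0L)
      info <- file.info(files)
      files <- files[order(info$mtime, basename(files))]
      n <- 0L
      for (f in files) {
        dest <- file.path(self$config$processing_folder, basename(f))
        if (suppressWarnings(file.rename(f, dest))) {
          private$queue[[length(private$queue) + 1L]] <- dest
          n <- n + 1L
        }
      }
      n
    },

    start_queued = function() {
      n <- 0L
      while (length(private$active) < self$config$max_parallel &&
             length(private$queue) > 0L) {
        claimed <- private$queue[[1L]]
        private$queue <- private$queue[-1L]
        private$launch(claimed)
        n <- n + 1L
      }
      n
    },

    job_id_from_claim = function(path) {
      m <- regmatches(basename(path), regexec("^token_(.+)\\.zip$", basename(path)))[[1]]
      if (length(m) == 2L && grepl("^[A-Za-z0-9][A-Za-z0-9._-]*$", m[2])) m[2]
      else paste0("unknown-", rand_hex(4L))
    },

    launch = function(claimed) {
      parsed <- tryCatch(parse_token(claimed), error = function(e) e)
      if (inherits(parsed, "error")) {
        jid <- private$job_id_from_claim(claimed)
        private$deposit_failure(jid, claimed, backend = "script",
                                reason = paste0("token parse error: ", conditionMessage(parsed)))
        return(invisible(NULL))
      }
      d <- parsed$descriptor
      workdir <- dir_create(file.path(self$config$work_root, d$job_id))
      zip::unzip(claimed, exdir = workdir)
      dir_create(file.path(workdir, "results"))
      log_path <- file.path(self$config$log_folder, paste0(d$job_id, ".log"))

      entry <- tryCatch(private$resolve_entrypoint(d, workdir),
                        error = function(e) e)
      if (inherits(entry, "error")) {
        private$deposit_failure(d$job_id, claimed, backend = d$algorithm_ref$kind,
                                reason = conditionMessage(entry), log_path = log_path)
        return(invisible(NULL))
      }
      env_vars <- c(SANDBOX_JOB_ID = d$job_id)
      if (length(d$run_settings)) {
        env_vars <- c(env_vars, stats::setNames(
          vapply(d$run_settings, as.character, ""),
          paste0("SANDBOX_SETTING_", toupper(names(d$run_settings)))
        ))
      }
      px <- tryCatch(
        processx::process$new(
          entry$command, entry$args, wd = workdir,
          stdout = log_path, stderr = "2>&1",
          env = c("current", env_vars)
        ),
        error = function(e) e
      )
      if (inherits(px, "error")) {
        private$deposit_failure(d$job_id, claimed, backend = entry$backend,
                                reason = paste0("backend launch error: ", conditionMessage(px)),
                                log_path = log_path)
        return(invisible(NULL))
      }
      private$active[[d$job_id]] <- list(
        job_id = d$job_id, backend = entry$backend, px = px,
        claimed = claimed, workdir = workdir, log_path = log_path,
        started_at = self$clock$now_iso(),
        deadline = Sys.time() + self$config$timeout
      )
      private$write_status(d$job_id, "running")
      invisible(NULL)
    },

    # algorithm_ref -> backend command. script: member inside the archive;
    # locator: script in the local algorithm repository; image: entrypoint of
    # a locally loaded container image (remote pulls are refused).
    resolve_entrypoint = function(d, workdir) {
      ref <- d$algorithm_ref
      if (ref$kind == "script") {
        path <- file.path(workdir, ref$value)
        if (!file.exists(path)) {
          stop_sandbox("sandbox_backend_error", "script member '%s' missing from token", ref$value)
        }
        list(backend = "script", command = interpreter_for(path), args = ref$value)
      } else if (ref$kind == "locator") {
        repo <- self$config$algorithm_repo
        hits <- if (!is.null(repo)) {
          list.files(repo, pattern = paste0("^", ref$value, "\\.(R|r|py|sh)$"),
                     full.names = TRUE)
        } else character()
        if (!length(hits)) {
          stop_sandbox("sandbox_backend_error",
                       "locator '%s' not found in local algorithm repository", ref$value)
        }
        local <- file.path(workdir, basename(hits[[1]]))
        file.copy(hits[[1]], local)
        list(backend = "script", command = interpreter_for(local), args = basename(local))
      } else if (ref$kind == "image") {
        store <- self$config$image_store
        img_dir <- if (!is.null(store)) file.path(store, ref$value) else ""
        if (!nzchar(img_dir) || !dir.exists(img_dir)) {
          stop_sandbox("sandbox_backend_error",
                       paste0("image '%s' not present in the local image store; ",
                              "pulling from external repositories is not enabled"),
                       ref$value)
        }
        entry <- list.files(img_dir, pattern = "^entrypoint\\.", full.names = TRUE)[1]
        local <- file.path(workdir, basename(entry))
        file.copy(entry, local)
        list(backend = "container", command = interpreter_for(local), args = basename(local))
      } else {
        stop_sandbox("sandbox_backend_error", "unknown backend kind '%s'", ref$kind)
      }
    },

    reap = function() {
      n <- 0L
      for (jid in names(private$active)) {
        a <- private$active[[jid]]
        if (a$px$is_alive()) {
          if (Sys.time() > a$deadline) {
            a$px$kill()
            cat(sprintf("job %s killed: backend timeout after %ss\n", jid, self$config$timeout),
                file = a$log_path, append = TRUE)
            private$finish_job(a, exit_status = -1L, timeout = TRUE)
            private$active[[jid]] <- NULL
            n <- n + 1L
          }
          next
        }
        private$finish_job(a, exit_status = a$px$get_exit_status())
        private$active[[jid]] <- NULL
        n <- n + 1L
      }
      n
    },

    finish_job = function(a, exit_status, timeout = FALSE) {
      status <- if (!timeout && identical(exit_status, 0L)) "success" else "failure"
      res_dir <- file.path(a$workdir, "results")
      res_files <- list.files(res_dir, recursive = TRUE)
      results <- stats::setNames(
        lapply(res_files, function(f) read_file_raw(file.path(res_dir, f))),
        res_files
      )
      if (status == "failure") results <- list()  # never forward partial results
      if (!file.exists(a$log_path) || file.size(a$log_path) == 0L) {
        cat(sprintf("job %s exit status %s\n", a$job_id, exit_status),
            file = a$log_path, append = TRUE)
      }
      if (timeout) {
        cat("failure flagged: timeout\n", file = a$log_path, append = TRUE)
      }
      logs <- stats::setNames(list(read_file_raw(a$log_path)),
                              paste0(a$job_id, ".log"))
      out <- build_output_token(a$job_id, status, results = results, logs = logs,
                                finished_at = self$clock$now_iso())
      write_token(out, file.path(self$config$output_folder,
                                 paste0("out_", a$job_id, ".zip")))
      private$write_status(a$job_id, if (status == "success") "done" else "failed")
      file.rename(a$claimed, file.path(self$config$done_folder, basename(a$claimed)))
      unlink(a$workdir, recursive = TRUE)
      private$done_records[[length(private$done_records) + 1L]] <- list(
        job_id = a$job_id, backend = a$backend, started_at = a$started_at,
        finished_at = self$clock$now_iso(),
        exit_status = if (is.null(exit_status)) NA_integer_ else as.integer(exit_status),
        status = status, log_path = a$log_path
      )
      invisible(NULL)
    },

    # Unparseable/unresolvable token: deposit a failure token immediately so
    # claimed tokens and output tokens stay in one-to-one correspondence.
    deposit_failure = function(job_id, claimed, backend, reason, log_path = NULL) {
      log_path <- log_path %||% file.path(self$config$log_folder, paste0(job_id, ".log"))
      cat(reason, "\n", sep = "", file = log_path, append = TRUE)
      out <- build_output_token(
        job_id, "failure",
        logs = stats::setNames(list(read_file_raw(log_path)), paste0(job_id, ".log")),
        finished_at = self$clock$now_iso()
      )
      write_token(out, file.path(self$config$output_folder, paste0("out_", job_id, ".zip")))
      private$write_status(job_id, "failed")
      file.rename(claimed, file.path(self$config$done_folder, basename(claimed)))
      private$done_records[[length(private$done_records) + 1L]] <- list(
        job_id = job_id, backend = backend, started_at = self$clock$now_iso(),
        finished_at = self$clock$now_iso(), exit_status = NA_integer_,
        status = "failure", log_path = log_path
      )
      invisible(NULL)
    },

    write_status = function(job_id, state) {
      atomic_write_lines(
        sprintf("%s %s %s", job_id, state, self$clock$now_iso()),
        file.path(self$config$sync_folder, paste0(job_id, ".status"))
      )
    }
  )
)
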