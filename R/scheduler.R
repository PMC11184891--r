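#' Cadence specifications for periodic tasks
#'
#' `cadence_interval()` fires every `seconds` seconds from an anchor instant;
#' `cadence_daily()` fires once a day at a fixed UTC wall time. Missed
#' instants are never back-filled: after a clock jump over several due
#' instants a task fires once and resumes from the next cadence point.
#'
#' @param seconds positive interval length in seconds.
#' @param anchor optional ISO-8601 UTC string anchoring the grid; defaults to
#'   the time the task is added.
#' @return a `cadence_spec` list.
#' @export
cadence_interval <- function(seconds, anchor = NULL) {
  if (!is.numeric(seconds) || length(seconds) != 1L || is.na(seconds) || seconds <= 0) {
    stop_sandbox("sandbox_contract_error", "cadence interval must be a positive number of seconds")
  }
  structure(list(kind = "interval", seconds = as.numeric(seconds), anchor = anchor),
            class = "cadence_spec")
}

#' @rdname cadence_interval
#' @param time daily UTC wall time as `"HH:MM"`.
#' @export
cadence_daily <- function(time = "02:00") {
  if (!grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", time)) {
    stop_sandbox("sandbox_contract_error", "daily cadence time must be 'HH:MM' (got '%s')", time)
  }
  structure(list(kind = "daily", time = time), class = "cadence_spec")
}

validate_cadence <- function(cadence) {
  if (!inherits(cadence, "cadence_spec")) {
    stop_sandbox("sandbox_contract_error", "schedule must be a cadence_spec")
  }
  invisible(cadence)
}

# First due instant strictly after `after` (POSIXct).
next_fire_after <- function(cadence, after) {
  if (cadence$kind == "interval") {
    anchor <- if (is.null(cadence$anchor)) after else parse_iso8601(cadence$anchor)
    gap <- as.numeric(difftime(after, anchor, units = "secs"))
    k <- if (gap < 0) 0 else floor(gap / cadence$seconds) + 1
    anchor + k * cadence$seconds
  } else {
    day <- as.POSIXct(format(after, "%Y-%m-%d", tz = "UTC"), tz = "UTC")
    hm <- as.numeric(strsplit(cadence$time, ":")[[1]])
    candidate <- day + hm[1] * 3600 + hm[2] * 60
    if (candidate > after) candidate else candidate + 86400
  }
}

#' Periodic task scheduler
#'
#' Maintains the periodic task list and fires job triggers at fixed instants.
#' Tasks hold a job template (a [job_request()] minus its `job_id`) plus a
#' cadence, and move through a fixed state machine:
#' `active <-> frozen`, `{active, frozen} -> removed` (terminal). Frozen
#' tasks never fire; `tick(now)` fires every active task due at or before
#' `now` exactly once per due instant, each trigger being a fresh job request
#' with a new job id. If a submit callback is configured and fails, the
#' trigger is retried on the next tick, duplicate-suppressed by
#' (task id, due instant). The task list is journaled to disk so restarts do
#' not lose schedules.
#'
#' @param clock a [sandbox_clock()] (tests inject a [fake_clock()]).
#' @param journal_path optional JSON journal file.
#' @param submit optional `function(request) -> logical` delivering triggers
#'   (e.g. into the proxy); `TRUE` means delivered.
#' @return `scheduler_agent()` returns a `Scheduler` R6 object.
#' @examples
#' cl <- fake_clock()
#' sch <- scheduler_agent(clock = cl)
#' tid <- sch$add_task(list(user_id = "alice"), cadence_interval(1))
#' cl$advance(1); length(sch$tick())
#' @export
scheduler_agent <- function(clock = sandbox_clock(), journal_path = NULL, submit = NULL) {
  Scheduler$new(clock = clock, journal_path = journal_path, submit = submit)
}

#' @rdname scheduler_agent
#' @export
Scheduler <- R6::R6Class("Scheduler",
  public = list(
    #' @field clock the injected clock.
    clock = NULL,
    #' @field submit optional trigger delivery callback.
    submit = NULL,

    #' @description Create the scheduler; see [scheduler_agent()].
    #' @param clock,journal_path,submit see [scheduler_agent()].
    initialize = function(clock = sandbox_clock(), journal_path = NULL, submit = NULL) {
      self$clock <- clock
      self$submit <- submit
      private$journal_path <- journal_path
      if (!is.null(journal_path) && file.exists(journal_path)) private$load()
    },

    #' @description Add a task; it becomes active with its first due instant
    #'   computed from the cadence anchor.
    #' @param template job-request fields minus `job_id` (list).
    #' @param cadence a [cadence_interval()] or [cadence_daily()].
    #' @return the new task id.
    add_task = function(template, cadence) {
      validate_cadence(cadence)
      if (!is.list(template)) {
        stop_sandbox("sandbox_contract_error", "task template must be a list")
      }
      template$job_id <- NULL
      template$schedule <- NULL
      private$counter <- private$counter + 1L
      task_id <- sprintf("task-%04d", private$counter)
      now <- self$clock$now()
      if (cadence$kind == "interval" && is.null(cadence$anchor)) {
        cadence$anchor <- iso8601(now)  # pin the grid to the add instant
      }
      private$task_table[[task_id]] <- list(
        task_id = task_id, template = template, cadence = cadence,
        next_fire_at = next_fire_after(cadence, now),
        state = "active", fires = 0L
      )
      private$persist()
      task_id
    },

    #' @description Freeze, resume or remove a task. Any action on a removed
    #'   task is a terminal-state error; resuming schedules the next cadence
    #'   point after now (no catch-up backlog).
    #' @param task_id task id.
    #' @param action `"freeze"`, `"resume"` or `"remove"`.
    #' @return the new state.
    control_task = function(task_id, action = c("freeze", "resume", "remove")) {
      action <- match.arg(action)
      t <- private$task_table[[task_id]]
      if (is.null(t)) stop_sandbox("sandbox_contract_error", "unknown task '%s'", task_id)
      if (t$state == "removed") {
        stop_sandbox("sandbox_state_error", "task '%s' is removed (terminal state)", task_id)
      }
      t$state <- switch(action, freeze = "frozen", resume = "active", remove = "removed")
      if (action == "resume") {
        t$next_fire_at <- next_fire_after(t$cadence, self$clock$now())
      }
      private$task_table[[task_id]] <- t
      private$persist()
      t$state
    },

    #' @description Task list snapshot as a data frame.
    tasks = function() {
      do.call(rbind, lapply(private$task_table, function(t) {
        data.frame(task_id = t$task_id, state = t$state,
                   next_fire_at = iso8601(t$next_fire_at), fires = t$fires,
                   stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description Fire all due triggers. Each (task, due instant) fires at
    #'   most once; undelivered triggers (failed submit callback) are retried
    #'   first on the following tick.
    #' @param now optional POSIXct override of the clock.
    #' @return list of fired job requests (including retried deliveries).
    tick = function(now = NULL) {
      now <- now %||% self$clock$now()
      delivered <- list()
      # retry undelivered triggers first
      still <- list()
      for (p in private$pending) {
        if (private$deliver(p$request)) delivered[[length(delivered) + 1L]] <- p$request
        else still[[length(still) + 1L]] <- p
      }
      private$pending <- still
      for (task_id in sort(names(private$task_table))) {
        t <- private$task_table[[task_id]]
        if (t$state != "active" || t$next_fire_at > now) next
        due <- t$next_fire_at
        key <- paste0(task_id, "@", iso8601(due))
        if (is.null(private$fired[[key]])) {
          private$fired[[key]] <- TRUE
          t$fires <- t$fires + 1L
          req <- t$template
          req$job_id <- sprintf("%s-f%04d", task_id, t$fires)
          req$created_at <- iso8601(now)
          if (private$deliver(req)) {
            delivered[[length(delivered) + 1L]] <- req
          } else {
            private$pending[[length(private$pending) + 1L]] <-
              list(key = key, request = req)
          }
        }
        # no catch-up: skip any backlog, resume at the next instant after now
        t$next_fire_at <- next_fire_after(t$cadence, now)
        private$task_table[[task_id]] <- t
      }
      private$persist()
      delivered
    }
  ),
  private = list(
    task_table = list(), fired = list(), pending = list(),
    counter = 0L, journal_path = NULL,

    deliver = function(request) {
      if (is.null(self$submit)) return(TRUE)
      isTRUE(tryCatch(self$submit(request), error = function(e) FALSE))
    },

    persist = function() {
      if (is.null(private$journal_path)) return(invisible(NULL))
      snapshot <- list(
        counter = private$counter,
        fired = names(private$fired),
        tasks = lapply(private$task_table, function(t) {
          t$next_fire_at <- iso8601(t$next_fire_at)
          t$cadence <- unclass(t$cadence)
          t
        })
      )
      atomic_write(private$journal_path, function(tmp) {
        jsonlite::write_json(snapshot, tmp, auto_unbox = TRUE, null = "null")
      })
      invisible(NULL)
    },

    load = function() {
      snapshot <- jsonlite::read_json(private$journal_path)
      private$counter <- as.integer(snapshot$counter %||% 0L)
      private$fired <- stats::setNames(
        as.list(rep(TRUE, length(snapshot$fired))),
        unlist(snapshot$fired) %||% character()
      )
      private$task_table <- lapply(snapshot$tasks, function(t) {
        t$next_fire_at <- parse_iso8601(t$next_fire_at)
        t$cadence <- structure(
          list(kind = t$cadence$kind,
               seconds = if (!is.null(t$cadence$seconds)) as.numeric(t$cadence$seconds),
               time = t$cadence$time,
               anchor = t$cadence$anchor),
          class = "cadence_spec"
        )
        t$template <- as.list(t$template)
        t$fires <- as.integer(t$fires)
        t
      })
      invisible(NULL)
    }
  )
)
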