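# The message protocol between a GUI and the proxy: a Message Master Table
# (MessageMasterTable.xml) listing submitted jobs, one detail file
# job_<jobID>.xml per job, and an outbox of status messages the proxy
# delivers. The channel endpoint is a directory; every byte the proxy sends
# outward passes through $deliver() and is recorded in a transcript, which is
# what the mediation property is asserted on.

MMT_FILE <- "MessageMasterTable.xml"
STATUS_CODES_FIXED <- c("info.assigned.proc", "info.status.job")

valid_status_code <- function(code) {
  code %in% STATUS_CODES_FIXED || grepl("^error\\.[a-z0-9_.]+$", code)
}

#' Job request
#'
#' What a GUI writes into a job detail file: the job identity, the user's
#' session ticket, the (datamart, algorithm) catalog pair, an optional cohort
#' query and schedule, column roles, run settings and the
#' notarisation/signature flags.
#'
#' @param job_id unique job id (filesystem-safe).
#' @param ticket session ticket from authentication.
#' @param user_id submitting user.
#' @param datamart,algorithm catalog item ids.
#' @param query optional [cohort_query()].
#' @param column_roles named character vector field -> role (input/target).
#' @param run_settings named list of scalar settings.
#' @param schedule optional [cadence_interval()] / [cadence_daily()].
#' @param notarise,sign workflow flags.
#' @param created_at ISO-8601 UTC timestamp (defaults to now).
#' @return a `job_request` object.
#' @export
job_request <- function(job_id, ticket, user_id, datamart, algorithm,
                        query = NULL, column_roles = character(),
                        run_settings = list(), schedule = NULL,
                        notarise = TRUE, sign = FALSE, created_at = NULL) {
  assert_safe_id(job_id, "job_id")
  assert_scalar_string(ticket, "ticket")
  assert_scalar_string(user_id, "user_id")
  assert_safe_id(datamart, "datamart item id")
  assert_safe_id(algorithm, "algorithm item id")
  if (!is.null(query) && !inherits(query, "cohort_query")) {
    stop_sandbox("sandbox_contract_error", "query must be a cohort_query")
  }
  if (!is.null(schedule)) validate_cadence(schedule)
  structure(list(
    job_id = job_id, ticket = ticket, user_id = user_id,
    datamart = datamart, algorithm = algorithm, query = query,
    column_roles = validate_column_roles(column_roles),
    run_settings = validate_run_settings(run_settings),
    schedule = schedule, notarise = isTRUE(notarise), sign = isTRUE(sign),
    created_at = created_at %||% iso8601(Sys.time())
  ), class = "job_request")
}

job_request_to_xml <- function(req) {
  doc <- xml2::xml_new_root("job_request", format_version = TOKEN_FORMAT_VERSION)
  xml2::xml_add_child(doc, "job_id", req$job_id)
  xml2::xml_add_child(doc, "ticket", req$ticket)
  xml2::xml_add_child(doc, "user_id", req$user_id)
  xml2::xml_add_child(doc, "datamart", req$datamart)
  xml2::xml_add_child(doc, "algorithm", req$algorithm)
  if (!is.null(req$query)) {
    qn <- xml2::xml_add_child(doc, "cohort_query")
    for (p in req$query$predicates) {
      xml2::xml_add_child(qn, "predicate", field = p$field, op = p$op,
                          value = paste(as.character(p$value), collapse = ","),
                          type = class(p$value)[1])
    }
  }
  roles <- xml2::xml_add_child(doc, "column_roles")
  for (nm in names(req$column_roles)) {
    xml2::xml_add_child(roles, "field", name = nm, role = req$column_roles[[nm]])
  }
  settings <- xml2::xml_add_child(doc, "run_settings")
  for (nm in names(req$run_settings)) {
    xml2::xml_add_child(settings, "setting", req$run_settings[[nm]], key = nm)
  }
  if (!is.null(req$schedule)) add_cadence_xml(doc, req$schedule)
  xml2::xml_add_child(doc, "notarise", if (req$notarise) "true" else "false")
  xml2::xml_add_child(doc, "sign", if (req$sign) "true" else "false")
  xml2::xml_add_child(doc, "created_at", req$created_at)
  doc
}

job_request_from_xml <- function(doc) {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "job_request") {
    stop_sandbox("sandbox_schema_error", "root element must be <job_request>")
  }
  pnodes <- xml2::xml_find_all(root, "./cohort_query/predicate")
  query <- if (length(pnodes)) {
    preds <- lapply(pnodes, function(n) {
      raw_val <- strsplit(xml2::xml_attr(n, "value"), ",", fixed = TRUE)[[1]]
      val <- if (identical(xml2::xml_attr(n, "type"), "numeric")) as.numeric(raw_val) else raw_val
      pred(xml2::xml_attr(n, "field"), xml2::xml_attr(n, "op"), val)
    })
    do.call(cohort_query, preds)
  }
  role_nodes <- xml2::xml_find_all(root, "./column_roles/field")
  setting_nodes <- xml2::xml_find_all(root, "./run_settings/setting")
  sched_node <- xml2::xml_find_first(root, "./schedule")
  job_request(
    job_id = xml_text1(root, "./job_id"),
    ticket = xml_text1(root, "./ticket"),
    user_id = xml_text1(root, "./user_id"),
    datamart = xml_text1(root, "./datamart"),
    algorithm = xml_text1(root, "./algorithm"),
    query = query,
    column_roles = stats::setNames(
      as.character(xml2::xml_attr(role_nodes, "role")),
      as.character(xml2::xml_attr(role_nodes, "name"))
    ),
    run_settings = stats::setNames(
      as.list(as.character(xml2::xml_text(setting_nodes))),
      as.character(xml2::xml_attr(setting_nodes, "key"))
    ),
    schedule = if (!inherits(sched_node, "xml_missing")) cadence_from_xml(sched_node),
    notarise = identical(xml_text1(root, "./notarise"), "true"),
    sign = identical(xml_text1(root, "./sign"), "true"),
    created_at = xml_text1(root, "./created_at")
  )
}

#' GUI channel endpoint
#'
#' The fixture GUI server and reference client in one object: a
#' directory-backed channel speaking the polled MMT/MMD protocol. The GUI
#' side appends MMT entries and writes job detail files; the proxy side polls
#' the MMT, reads detail files, marks entries consumed, and delivers status
#' messages and result artefacts into the channel outbox. All proxy-to-GUI
#' bytes are recorded in a transcript for the mediation assertion.
#'
#' The channel session is established by the proxy with a maximum duration;
#' traffic after expiry is refused with a `sandbox_channel_expired` error.
#'
#' @param dir channel directory.
#' @param channel_id identifier.
#' @param clock a [sandbox_clock()].
#' @return `gui_channel()` returns a `GuiChannel` R6 object.
#' @export
gui_channel <- function(dir, channel_id = "ch1", clock = sandbox_clock()) {
  GuiChannel$new(dir = dir, channel_id = channel_id, clock = clock)
}

#' @rdname gui_channel
#' @export
GuiChannel <- R6::R6Class("GuiChannel",
  public = list(
    #' @field dir channel directory.
    dir = NULL,
    #' @field channel_id identifier.
    channel_id = NULL,
    #' @field clock injected clock.
    clock = NULL,
    #' @field ticket the nested user session ticket, once logged in.
    ticket = NULL,
    #' @field user_id the logged-in user.
    user_id = NULL,

    #' @description Create the endpoint (directory, empty MMT, outbox).
    #' @param dir,channel_id,clock see [gui_channel()].
    initialize = function(dir, channel_id = "ch1", clock = sandbox_clock()) {
      self$dir <- dir_create(dir)
      self$channel_id <- channel_id
      self$clock <- clock
      dir_create(file.path(dir, "jobs"))
      dir_create(file.path(dir, "outbox"))
      dir_create(file.path(dir, "outbox", "files"))
      if (!file.exists(private$mmt_path())) private$write_mmt(list())
    },

    #' @description Establish the channel session (proxy side) with a
    #'   maximum duration in seconds.
    #' @param max_duration channel lifetime in seconds.
    establish = function(max_duration = 3600) {
      private$established_at <- self$clock$now()
      private$max_duration <- max_duration
      invisible(self)
    },

    #' @description Is the channel session live?
    live = function() {
      !is.null(private$established_at) &&
        self$clock$now() <= private$established_at + private$max_duration
    },

    #' @description Record the user session after authentication.
    #' @param ticket,user_id nested user session.
    set_session = function(ticket, user_id) {
      self$ticket <- ticket
      self$user_id <- user_id
      invisible(self)
    },

    #' @description GUI side: publish a job request. Appends one MMT entry
    #'   atomically and writes `jobs/job_<jobID>.xml`. Duplicate job ids and
    #'   expired channels are refused.
    #' @param request a [job_request()].
    #' @return the new MMT entry (list), invisibly.
    write_job = function(request) {
      private$require_live()
      if (!inherits(request, "job_request")) {
        stop_sandbox("sandbox_contract_error", "request must be a job_request")
      }
      entries <- private$read_mmt()
      if (request$job_id %in% vapply(entries, `[[`, "", "job_id")) {
        stop_sandbox("sandbox_duplicate_error",
                     "job '%s' already submitted on this channel", request$job_id)
      }
      detail_file <- paste0("job_", request$job_id, ".xml")
      xml2::write_xml(job_request_to_xml(request),
                      file.path(self$dir, "jobs", detail_file))
      entry <- list(
        entry_id = sprintf("e%04d", length(entries) + 1L),
        job_id = request$job_id, type = "job-request",
        detail_file = detail_file, created_at = self$clock$now_iso(),
        consumed = FALSE
      )
      private$write_mmt(c(entries, list(entry)))
      invisible(entry)
    },

    #' @description Proxy side: all MMT entries (list of lists).
    mmt_entries = function() private$read_mmt(),

    #' @description Proxy side: entries not yet consumed.
    unconsumed_entries = function() {
      Filter(function(e) !isTRUE(e$consumed), private$read_mmt())
    },

    #' @description Proxy side: read and parse a job detail file.
    #' @param detail_file file name from the MMT entry.
    read_job = function(detail_file) {
      path <- file.path(self$dir, "jobs", detail_file)
      if (!file.exists(path)) {
        stop_sandbox("sandbox_parse_error", "detail file '%s' missing", detail_file)
      }
      job_request_from_xml(xml2::read_xml(path))
    },

    #' @description Proxy side: mark an MMT entry consumed (exactly once).
    #' @param entry_id the entry.
    mark_consumed = function(entry_id) {
      entries <- private$read_mmt()
      for (i in seq_along(entries)) {
        if (entries[[i]]$entry_id == entry_id) entries[[i]]$consumed <- TRUE
      }
      private$write_mmt(entries)
      invisible(NULL)
    },

    #' @description Proxy side: deliver a status message (and optional
    #'   artefact files) to the channel outbox. Codes come from the closed
    #'   enumeration `info.assigned.proc`, `info.status.job`, `error.*`.
    #'   Every delivered byte is appended to the transcript.
    #' @param code status code.
    #' @param job_id related job.
    #' @param payload message payload text.
    #' @param files optional named list of raw/character artefact contents.
    deliver = function(code, job_id, payload = "", files = NULL) {
      private$require_live()
      if (!valid_status_code(code)) {
        stop_sandbox("sandbox_contract_error", "invalid status code '%s'", code)
      }
      private$seq <- private$seq + 1L
      doc <- xml2::xml_new_root("status_message", code = code, job_id = job_id,
                                seq = as.character(private$seq),
                                timestamp = self$clock$now_iso())
      xml2::xml_add_child(doc, "payload", payload)
      file_names <- character()
      if (length(files)) {
        out_dir <- dir_create(file.path(self$dir, "outbox", "files", job_id))
        for (nm in names(files)) {
          bytes <- as_raw_bytes(files[[nm]])
          writeBin(bytes, file.path(out_dir, nm))
          private$transcript[[length(private$transcript) + 1L]] <- bytes
          file_names <- c(file_names, nm)
        }
        fl <- xml2::xml_add_child(doc, "artefacts")
        for (nm in file_names) xml2::xml_add_child(fl, "file", nm)
      }
      msg_path <- file.path(self$dir, "outbox", sprintf("msg_%06d.xml", private$seq))
      xml2::write_xml(doc, msg_path)
      private$transcript[[length(private$transcript) + 1L]] <- read_file_raw(msg_path)
      invisible(msg_path)
    },

    #' @description GUI side: read all delivered status messages, in
    #'   delivery (per-job causal) order.
    #' @return data frame: seq, code, job_id, timestamp, payload, artefacts.
    read_status = function() {
      private$require_live()
      msgs <- sort(list.files(file.path(self$dir, "outbox"),
                              pattern = "^msg_\\d+\\.xml$", full.names = TRUE))
      rows <- lapply(msgs, function(m) {
        doc <- xml2::read_xml(m)
        data.frame(
          seq = as.integer(xml2::xml_attr(doc, "seq")),
          code = xml2::xml_attr(doc, "code"),
          job_id = xml2::xml_attr(doc, "job_id"),
          timestamp = xml2::xml_attr(doc, "timestamp"),
          payload = xml_text1(doc, "./payload") %||% "",
          artefacts = paste(xml2::xml_text(xml2::xml_find_all(doc, "./artefacts/file")),
                            collapse = ";"),
          stringsAsFactors = FALSE
        )
      })
      out <- do.call(rbind, rows) %||%
        data.frame(seq = integer(), code = character(), job_id = character(),
                   timestamp = character(), payload = character(),
                   artefacts = character(), stringsAsFactors = FALSE)
      out[order(out$seq), , drop = FALSE]
    },

    #' @description Read a delivered artefact's bytes.
    #' @param job_id job the artefact belongs to.
    #' @param name artefact file name.
    artefact = function(job_id, name) {
      read_file_raw(file.path(self$dir, "outbox", "files", job_id, name))
    },

    #' @description Full transcript of every byte the proxy has delivered on
    #'   this channel, as one character string (for mediation scans).
    transcript_text = function() {
      paste(vapply(private$transcript, rawToChar, ""), collapse = "\n")
    }
  ),
  private = list(
    established_at = NULL, max_duration = Inf, seq = 0L, transcript = list(),

    mmt_path = function() file.path(self$dir, MMT_FILE),

    require_live = function() {
      if (!self$live()) {
        stop_sandbox("sandbox_channel_expired",
                     "channel '%s' session is not live", self$channel_id)
      }
    },

    read_mmt = function() {
      doc <- xml2::read_xml(private$mmt_path())
      lapply(xml2::xml_find_all(doc, "./entry"), function(n) {
        list(
          entry_id = xml2::xml_attr(n, "entry_id"),
          job_id = xml2::xml_attr(n, "job_id"),
          type = xml2::xml_attr(n, "type"),
          detail_file = xml2::xml_attr(n, "detail_file"),
          created_at = xml2::xml_attr(n, "created_at"),
          consumed = identical(xml2::xml_attr(n, "consumed"), "true")
        )
      })
    },

    write_mmt = function(entries) {
      doc <- xml2::xml_new_root("message_master_table",
                                format_version = TOKEN_FORMAT_VERSION)
      for (e in entries) {
        xml2::xml_add_child(doc, "entry", entry_id = e$entry_id, job_id = e$job_id,
                            type = e$type, detail_file = e$detail_file,
                            created_at = e$created_at,
                            consumed = if (isTRUE(e$consumed)) "true" else "false")
      }
      atomic_write(private$mmt_path(), function(tmp) xml2::write_xml(doc, tmp))
      invisible(NULL)
    }
  )
)
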