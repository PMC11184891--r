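# Token archive format: the unit of execution passed from the proxy to a
# processor. A token is a zip archive holding a descriptor XML (always named
# descriptor.xml) plus optional data/script payload members. Output tokens
# carry a result descriptor (result.xml) plus result and log members.

TOKEN_FORMAT_VERSION <- "1.0"
DESCRIPTOR_MEMBER <- "descriptor.xml"
RESULT_MEMBER <- "result.xml"

#' Reference to the algorithm a token should run
#'
#' Exactly one of the three reference kinds is set: a script member inside the
#' token archive, a container image name in the local image store, or a
#' locator resolved against the processor's local algorithm repository.
#'
#' @param value the path / image name / repository locator.
#' @return an `algorithm_ref` object.
#' @export
algo_script <- function(value) new_algorithm_ref("script", value)

#' @rdname algo_script
#' @export
algo_image <- function(value) new_algorithm_ref("image", value)

#' @rdname algo_script
#' @export
algo_locator <- function(value) new_algorithm_ref("locator", value)

new_algorithm_ref <- function(kind, value) {
  kind <- match.arg(kind, c("script", "image", "locator"))
  assert_scalar_string(value, "algorithm_ref value")
  structure(list(kind = kind, value = value), class = "algorithm_ref")
}

#' Reference to the datamart payload of a token
#'
#' Either a CSV member shipped inside the archive (`dm_payload`) or a locator
#' resolved against the proxy's datamart repository (`dm_locator`).
#' @param value member path or repository locator.
#' @return a `datamart_ref` object.
#' @export
dm_payload <- function(value) new_datamart_ref("payload", value)

#' @rdname dm_payload
#' @export
dm_locator <- function(value) new_datamart_ref("locator", value)

new_datamart_ref <- function(kind, value) {
  kind <- match.arg(kind, c("payload", "locator"))
  assert_scalar_string(value, "datamart_ref value")
  structure(list(kind = kind, value = value), class = "datamart_ref")
}

#' Build a token descriptor
#'
#' The descriptor characterises one task run: its identity, the algorithm and
#' datamart references, which datamart fields are algorithm inputs or targets,
#' free-form run settings, and the notarisation/signature flags. It
#' serialises losslessly to and from the descriptor XML member of a token.
#'
#' @param job_id unique job identifier (filesystem-safe).
#' @param user_id submitting user.
#' @param algorithm_ref an [algo_script()], [algo_image()] or [algo_locator()].
#' @param datamart_ref optional [dm_payload()] or [dm_locator()].
#' @param column_roles named character vector mapping field name to role
#'   (`"input"` or `"target"`).
#' @param run_settings named list of scalar settings (stored as strings).
#' @param notarise,sign logical flags for the notarisation / dual-signature
#'   workflow.
#' @param schedule optional cadence, see [cadence_interval()].
#' @param created_at ISO-8601 UTC timestamp string; defaults to now.
#' @return a `token_descriptor` object.
#' @export
token_descriptor <- function(job_id, user_id, algorithm_ref,
                             datamart_ref = NULL,
                             column_roles = character(),
                             run_settings = list(),
                             notarise = TRUE, sign = FALSE,
                             schedule = NULL,
                             created_at = NULL) {
  assert_safe_id(job_id, "job_id")
  assert_scalar_string(user_id, "user_id")
  if (!inherits(algorithm_ref, "algorithm_ref")) {
    stop_sandbox("sandbox_contract_error", "algorithm_ref must be an algorithm_ref")
  }
  if (!is.null(datamart_ref) && !inherits(datamart_ref, "datamart_ref")) {
    stop_sandbox("sandbox_contract_error", "datamart_ref must be a datamart_ref or NULL")
  }
  column_roles <- validate_column_roles(column_roles)
  run_settings <- validate_run_settings(run_settings)
  if (!is.null(schedule)) validate_cadence(schedule)
  d <- structure(list(
    job_id = job_id,
    user_id = user_id,
    algorithm_ref = algorithm_ref,
    datamart_ref = datamart_ref,
    column_roles = column_roles,
    run_settings = run_settings,
    notarise = isTRUE(notarise),
    sign = isTRUE(sign),
    schedule = schedule,
    created_at = created_at %||% iso8601(Sys.time())
  ), class = "token_descriptor")
  d
}

validate_column_roles <- function(column_roles) {
  if (length(column_roles) == 0L) return(stats::setNames(character(), character()))
  column_roles <- unlist(column_roles)
  if (is.null(names(column_roles)) || any(!nzchar(names(column_roles)))) {
    stop_sandbox("sandbox_contract_error", "column_roles must be named")
  }
  bad <- setdiff(unique(column_roles), c("input", "target"))
  if (length(bad)) {
    stop_sandbox("sandbox_contract_error", "column role must be 'input' or 'target' (got '%s')", bad[1])
  }
  column_roles
}

validate_run_settings <- function(run_settings) {
  if (length(run_settings) == 0L) return(stats::setNames(list(), character()))
  if (is.null(names(run_settings)) || any(!nzchar(names(run_settings)))) {
    stop_sandbox("sandbox_contract_error", "run_settings must be named")
  }
  lapply(stats::setNames(run_settings, names(run_settings)), function(v) as.character(v)[1])
}

# -- descriptor <-> XML ------------------------------------------------------

descriptor_to_xml <- function(d) {
  doc <- xml2::xml_new_root("token_descriptor", format_version = TOKEN_FORMAT_VERSION)
  xml2::xml_add_child(doc, "job_id", d$job_id)
  xml2::xml_add_child(doc, "user_id", d$user_id)
  xml2::xml_add_child(doc, "algorithm_ref", d$algorithm_ref$value, kind = d$algorithm_ref$kind)
  if (!is.null(d$datamart_ref)) {
    xml2::xml_add_child(doc, "datamart_ref", d$datamart_ref$value, kind = d$datamart_ref$kind)
  }
  roles <- xml2::xml_add_child(doc, "column_roles")
  for (nm in names(d$column_roles)) {
    xml2::xml_add_child(roles, "field", name = nm, role = d$column_roles[[nm]])
  }
  settings <- xml2::xml_add_child(doc, "run_settings")
  for (nm in names(d$run_settings)) {
    xml2::xml_add_child(settings, "setting", d$run_settings[[nm]], key = nm)
  }
  xml2::xml_add_child(doc, "notarise", if (d$notarise) "true" else "false")
  xml2::xml_add_child(doc, "sign", if (d$sign) "true" else "false")
  if (!is.null(d$schedule)) {
    add_cadence_xml(doc, d$schedule)
  }
  xml2::xml_add_child(doc, "created_at", d$created_at)
  doc
}

add_cadence_xml <- function(doc, cadence) {
  if (cadence$kind == "interval") {
    attrs <- list(kind = "interval", seconds = format(cadence$seconds, scientific = FALSE))
    if (!is.null(cadence$anchor)) attrs$anchor <- cadence$anchor
    do.call(xml2::xml_add_child, c(list(doc, "schedule"), attrs))
  } else {
    xml2::xml_add_child(doc, "schedule", kind = "daily", time = cadence$time)
  }
}

cadence_from_xml <- function(node) {
  kind <- xml2::xml_attr(node, "kind")
  if (identical(kind, "interval")) {
    anchor <- xml2::xml_attr(node, "anchor")
    cadence_interval(
      seconds = as.numeric(xml2::xml_attr(node, "seconds")),
      anchor = if (is.na(anchor)) NULL else anchor
    )
  } else if (identical(kind, "daily")) {
    cadence_daily(xml2::xml_attr(node, "time"))
  } else {
    stop_sandbox("sandbox_schema_error", "unknown schedule kind '%s'", kind)
  }
}

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NULL)
  xml2::xml_text(node)
}

descriptor_from_xml <- function(doc) {
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "token_descriptor") {
    stop_sandbox("sandbox_schema_error", "root element must be <token_descriptor>")
  }
  job_id <- xml_text1(root, "./job_id")
  if (is.null(job_id) || !nzchar(job_id)) {
    stop_sandbox("sandbox_schema_error", "descriptor lacks a non-empty <job_id>")
  }
  algo_node <- xml2::xml_find_first(root, "./algorithm_ref")
  if (inherits(algo_node, "xml_missing")) {
    stop_sandbox("sandbox_schema_error", "descriptor lacks <algorithm_ref>")
  }
  algorithm_ref <- new_algorithm_ref(xml2::xml_attr(algo_node, "kind"), xml2::xml_text(algo_node))
  dm_node <- xml2::xml_find_first(root, "./datamart_ref")
  datamart_ref <- if (!inherits(dm_node, "xml_missing")) {
    new_datamart_ref(xml2::xml_attr(dm_node, "kind"), xml2::xml_text(dm_node))
  }
  role_nodes <- xml2::xml_find_all(root, "./column_roles/field")
  column_roles <- stats::setNames(
    as.character(xml2::xml_attr(role_nodes, "role")),
    as.character(xml2::xml_attr(role_nodes, "name"))
  )
  setting_nodes <- xml2::xml_find_all(root, "./run_settings/setting")
  run_settings <- stats::setNames(
    as.list(as.character(xml2::xml_text(setting_nodes))),
    as.character(xml2::xml_attr(setting_nodes, "key"))
  )
  sched_node <- xml2::xml_find_first(root, "./schedule")
  schedule <- if (!inherits(sched_node, "xml_missing")) cadence_from_xml(sched_node)
  token_descriptor(
    job_id = job_id,
    user_id = xml_text1(root, "./user_id") %||% "",
    algorithm_ref = algorithm_ref,
    datamart_ref = datamart_ref,
    column_roles = column_roles,
    run_settings = run_settings,
    notarise = identical(xml_text1(root, "./notarise"), "true"),
    sign = identical(xml_text1(root, "./sign"), "true"),
    schedule = schedule,
    created_at = xml_text1(root, "./created_at")
  )
}

# -- archive building / parsing ---------------------------------------------

validate_member_path <- function(path) {
  assert_scalar_string(path, "payload member path")
  if (grepl("^([A-Za-z]:)?[/\\\\]", path)) {
    stop_sandbox("sandbox_path_error", "absolute payload path not allowed: '%s'", path)
  }
  parts <- strsplit(path, "[/\\\\]")[[1]]
  if (any(parts == "..")) {
    stop_sandbox("sandbox_path_error", "path traversal not allowed: '%s'", path)
  }
  if (any(!nzchar(parts))) {
    stop_sandbox("sandbox_path_error", "empty path component in '%s'", path)
  }
  if (path %in% c(DESCRIPTOR_MEMBER, RESULT_MEMBER)) {
    stop_sandbox("sandbox_path_error", "member name '%s' is reserved", path)
  }
  invisible(path)
}

write_members <- function(root_dir, members) {
  for (path in names(members)) {
    full <- file.path(root_dir, path)
    dir_create(dirname(full))
    writeBin(as_raw_bytes(members[[path]]), full)
  }
}

zip_members <- function(root_dir, member_paths) {
  zipfile <- tempfile(fileext = ".zip")
  zip::zip(zipfile, files = member_paths, root = root_dir,
           mode = "mirror", include_directories = FALSE)
  on.exit(unlink(zipfile))
  read_file_raw(zipfile)
}

#' Build a token archive
#'
#' Serialises the descriptor to `descriptor.xml` and packs it with the payload
#' members into a zip archive. Payload paths must be unique, relative and free
#' of traversal components; violations raise a `sandbox_path_error`.
#'
#' @param descriptor a [token_descriptor()].
#' @param payload named list: member path -> raw vector or single string.
#' @return a `sandbox_token` list with fields `archive` (raw zip bytes),
#'   `descriptor`, and `manifest` (member paths).
#' @seealso [parse_token()], [write_token()]
#' @export
build_token <- function(descriptor, payload = list()) {
  if (!inherits(descriptor, "token_descriptor")) {
    stop_sandbox("sandbox_contract_error", "descriptor must be a token_descriptor")
  }
  paths <- names(payload) %||% character()
  if (length(payload) && (is.null(names(payload)) || any(!nzchar(paths)))) {
    stop_sandbox("sandbox_path_error", "payload must be a named list of member paths")
  }
  if (anyDuplicated(paths)) {
    stop_sandbox("sandbox_path_error", "duplicate payload path '%s'", paths[duplicated(paths)][1])
  }
  for (p in paths) validate_member_path(p)

  staging <- tempfile("token-")
  dir_create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  xml2::write_xml(descriptor_to_xml(descriptor), file.path(staging, DESCRIPTOR_MEMBER))
  write_members(staging, payload)
  members <- c(DESCRIPTOR_MEMBER, paths)
  archive <- zip_members(staging, members)
  structure(
    list(archive = archive, descriptor = descriptor, manifest = members),
    class = "sandbox_token"
  )
}

#' Write a token archive to disk
#' @param token a `sandbox_token` (or `sandbox_output_token`).
#' @param path destination file; written atomically.
#' @return `path`, invisibly.
#' @export
write_token <- function(token, path) {
  atomic_write(path, function(tmp) writeBin(token$archive, tmp))
}

archive_to_path <- function(x) {
  if (is.raw(x)) {
    tmp <- tempfile(fileext = ".zip")
    writeBin(x, tmp)
    return(list(path = tmp, cleanup = TRUE))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(list(path = x, cleanup = FALSE))
  }
  if (inherits(x, "sandbox_token") || inherits(x, "sandbox_output_token")) {
    return(archive_to_path(x$archive))
  }
  stop_sandbox("sandbox_parse_error", "expected raw zip bytes or a path to a zip file")
}

list_archive <- function(path) {
  info <- tryCatch(zip::zip_list(path), error = function(e) {
    stop_sandbox("sandbox_parse_error", "unreadable zip archive: %s", conditionMessage(e))
  })
  members <- info$filename
  members[!endsWith(members, "/")]
}

extract_archive <- function(path, members) {
  exdir <- tempfile("tok-ex-")
  dir_create(exdir)
  zip::unzip(path, exdir = exdir)
  payload <- lapply(members, function(m) read_file_raw(file.path(exdir, m)))
  names(payload) <- members
  unlink(exdir, recursive = TRUE)
  payload
}

#' Parse a token archive
#'
#' Inverse of [build_token()]: recovers the descriptor, the full member
#' manifest, and the payload bytes. A zip without a `descriptor.xml` member
#' raises `sandbox_missing_descriptor`; malformed or invalid descriptor XML
#' raises `sandbox_schema_error`.
#'
#' @param x raw zip bytes, a file path, or a `sandbox_token`.
#' @return list with `descriptor`, `manifest`, `payload` (named list of raw).
#' @export
parse_token <- function(x) {
  src <- archive_to_path(x)
  if (src$cleanup) on.exit(unlink(src$path), add = TRUE)
  members <- list_archive(src$path)
  if (!(DESCRIPTOR_MEMBER %in% members)) {
    stop_sandbox("sandbox_missing_descriptor",
                 "archive has no '%s' member", DESCRIPTOR_MEMBER)
  }
  bytes <- extract_archive(src$path, members)
  doc <- tryCatch(xml2::read_xml(bytes[[DESCRIPTOR_MEMBER]]), error = function(e) {
    stop_sandbox("sandbox_schema_error", "malformed descriptor XML: %s", conditionMessage(e))
  })
  descriptor <- descriptor_from_xml(doc)
  list(
    descriptor = descriptor,
    manifest = members,
    payload = bytes[setdiff(members, DESCRIPTOR_MEMBER)]
  )
}

# -- hashing -----------------------------------------------------------------

HASH_ALGORITHM <- "sha256"
ZERO_DIGEST <- strrep("0", 64L)

#' Hash an artifact with the platform digest algorithm
#'
#' SHA-256 over the exact bytes; the algorithm identifier travels with the
#' digest so ledger records are self-describing.
#'
#' @param data raw vector (or single string, hashed as UTF-8 bytes).
#' @return a `sandbox_digest`: list with `algorithm_id` and lowercase `hex`.
#' @export
hash_artifact <- function(data) {
  h <- openssl::sha256(as_raw_bytes(data))
  structure(
    list(algorithm_id = HASH_ALGORITHM, hex = paste(sprintf("%02x", as.integer(h)), collapse = "")),
    class = "sandbox_digest"
  )
}

#' @rdname hash_artifact
#' @param path file whose contents are hashed.
#' @export
hash_file <- function(path) hash_artifact(read_file_raw(path))

# -- output tokens -----------------------------------------------------------

#' Build an output token
#'
#' The processor reports each task's outcome to the output folder as a new
#' token: a zip with a `result.xml` member plus the result and log members. A
#' failure must carry at least one log member (`sandbox_contract_error`
#' otherwise), so failures are always diagnosable upstream.
#'
#' @param job_id the triggering token's job id.
#' @param status `"success"` or `"failure"`.
#' @param results named list: file name -> bytes/string; stored under
#'   `results/` in the archive.
#' @param logs named list: file name -> bytes/string; stored under `logs/`.
#' @param finished_at ISO-8601 UTC timestamp; defaults to now.
#' @return a `sandbox_output_token` with fields `archive`, `job_id`, `status`,
#'   `results`, `logs`, `finished_at`.
#' @export
build_output_token <- function(job_id, status = c("success", "failure"),
                               results = list(), logs = list(),
                               finished_at = NULL) {
  assert_safe_id(job_id, "job_id")
  status <- match.arg(status)
  if (status == "failure" && length(logs) == 0L) {
    stop_sandbox("sandbox_contract_error",
                 "a failure output token must carry at least one log member")
  }
  finished_at <- finished_at %||% iso8601(Sys.time())
  member_name <- function(prefix, nm) paste0(prefix, "/", nm)
  result_paths <- vapply(names(results) %||% character(), member_name, "", prefix = "results")
  log_paths <- vapply(names(logs) %||% character(), member_name, "", prefix = "logs")
  for (p in c(result_paths, log_paths)) validate_member_path(p)

  doc <- xml2::xml_new_root("result_descriptor", format_version = TOKEN_FORMAT_VERSION)
  xml2::xml_add_child(doc, "job_id", job_id)
  xml2::xml_add_child(doc, "status", status)
  xml2::xml_add_child(doc, "finished_at", finished_at)
  rs <- xml2::xml_add_child(doc, "results")
  for (p in result_paths) xml2::xml_add_child(rs, "member", p)
  ls_ <- xml2::xml_add_child(doc, "logs")
  for (p in log_paths) xml2::xml_add_child(ls_, "member", p)

  staging <- tempfile("outtok-")
  dir_create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  xml2::write_xml(doc, file.path(staging, RESULT_MEMBER))
  members <- stats::setNames(c(results, logs), c(result_paths, log_paths))
  write_members(staging, members)
  archive <- zip_members(staging, c(RESULT_MEMBER, result_paths, log_paths))
  structure(
    list(archive = archive, job_id = job_id, status = status,
         results = unname(result_paths), logs = unname(log_paths),
         finished_at = finished_at),
    class = "sandbox_output_token"
  )
}

#' Parse an output token archive
#' @param x raw zip bytes, file path, or `sandbox_output_token`.
#' @return list with `job_id`, `status`, `results`, `logs`, `finished_at`,
#'   `payload` (named list of raw member bytes), `manifest`.
#' @export
parse_output_token <- function(x) {
  src <- archive_to_path(x)
  if (src$cleanup) on.exit(unlink(src$path), add = TRUE)
  members <- list_archive(src$path)
  if (!(RESULT_MEMBER %in% members)) {
    stop_sandbox("sandbox_missing_descriptor", "archive has no '%s' member", RESULT_MEMBER)
  }
  bytes <- extract_archive(src$path, members)
  doc <- tryCatch(xml2::read_xml(bytes[[RESULT_MEMBER]]), error = function(e) {
    stop_sandbox("sandbox_schema_error", "malformed result XML: %s", conditionMessage(e))
  })
  root <- xml2::xml_root(doc)
  status <- xml_text1(root, "./status")
  if (!status %in% c("success", "failure")) {
    stop_sandbox("sandbox_schema_error", "invalid status '%s'", status %||% "")
  }
  list(
    job_id = xml_text1(root, "./job_id"),
    status = status,
    results = as.character(xml2::xml_text(xml2::xml_find_all(root, "./results/member"))),
    logs = as.character(xml2::xml_text(xml2::xml_find_all(root, "./logs/member"))),
    finished_at = xml_text1(root, "./finished_at"),
    payload = bytes[setdiff(members, RESULT_MEMBER)],
    manifest = members
  )
}
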