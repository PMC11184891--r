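# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a time as ISO-8601 UTC with microseconds
#' @param t a POSIXct time
#' @return character scalar, e.g. "2024-01-01T00:00:00.000000Z"
#' @keywords internal
iso8601 <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
}

parse_iso8601 <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}

# Random hex string (not seed-controlled; used for tickets and temp names).
rand_hex <- function(n_bytes = 8L) {
  paste(sprintf("%02x", as.integer(openssl::rand_bytes(n_bytes))), collapse = "")
}

# URL-safe base64 of n random bytes (session tickets).
rand_token <- function(n_bytes = 32L) {
  b64 <- openssl::base64_encode(openssl::rand_bytes(n_bytes))
  gsub("=+$", "", chartr("+/", "-_", b64))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Write a file atomically: write to a sibling temp path, then rename.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp-", rand_hex(4L))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop(sandbox_error("sandbox_io_error", sprintf("cannot write '%s'", path)))
  }
  invisible(path)
}

atomic_write_lines <- function(lines, path) {
  atomic_write(path, function(tmp) writeLines(lines, tmp, useBytes = TRUE))
}

# Condition constructor used for all package errors; `class` is the subclass.
sandbox_error <- function(class, message, ...) {
  structure(
    class = c(class, "sandbox_error", "error", "condition"),
    list(message = message, ...)
  )
}

stop_sandbox <- function(class, fmt, ...) {
  stop(sandbox_error(class, sprintf(fmt, ...)))
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_sandbox("sandbox_contract_error", "%s must be a non-empty string", what)
  }
  invisible(x)
}

# Identifiers that become file names (job ids, item ids, processor ids).
assert_safe_id <- function(x, what) {
  assert_scalar_string(x, what)
  if (!grepl("^[A-Za-z0-9][A-Za-z0-9._-]*$", x)) {
    stop_sandbox(
      "sandbox_contract_error",
      "%s must match [A-Za-z0-9][A-Za-z0-9._-]* (got '%s')", what, x
    )
  }
  invisible(x)
}

dir_create <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
  invisible(path)
}

read_file_raw <- function(path) {
  readBin(path, what = "raw", n = file.size(path))
}

as_raw_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(charToRaw(enc2utf8(x)))
  stop_sandbox("sandbox_contract_error", "expected raw bytes or a single string")
}
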