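#' Notarisation and certification agent
#'
#' Implements tamper-evident notarisation of request/result hashes plus the
#' dual digital-signature workflow over reports. Artefacts are hashed
#' (SHA-256), the blob is stored off-chain first in a content-addressed
#' directory, and the digest is then appended to a hash-chained append-only
#' ledger (JSON-lines, one entry per line, fixed field order so entry digests
#' are reproducible). The chain gives verifiable proof of existence and makes
#' any in-place mutation detectable; truncation of the tail is out of the
#' single-file model's reach, so the chain head digest is exposed for
#' external anchoring.
#'
#' Report signing follows a three-state machine per job:
#' `issued -> sandbox_signed -> countersigned`. The sandbox signs the report
#' with its Ed25519 private key; the user verifies, countersigns the
#' sandbox-signed envelope with their own key, and uploads the signature.
#' A valid countersignature stores and notarises all three report artefacts
#' (initial, sandbox-signed, countersigned), so a completed signed job
#' contributes exactly five ledger entries: one request, one result, three
#' reports.
#'
#' @param dir directory for the ledger file, off-chain store and keys.
#' @param clock a [sandbox_clock()].
#' @return `notary_agent()` returns a `Notary` R6 object.
#' @examples
#' ny <- notary_agent(tempfile("notary-"))
#' rec <- ny$notarize(charToRaw("hello"), job_id = "j1", role = "request", user = "alice")
#' ny$verify_ledger()$ok
#' ny$proof_of_existence(rec$record$payload_digest)
#' @export
notary_agent <- function(dir, clock = sandbox_clock()) {
  Notary$new(dir = dir, clock = clock)
}

NOTARY_ROLES <- c("request", "result",
                  "report-initial", "report-sandbox-signed", "report-countersigned")

entry_digest_hex <- function(index, timestamp, payload_hex, prev_hex) {
  canonical <- sprintf("%d|%s|%s|%s", index, timestamp, payload_hex, prev_hex)
  hash_artifact(charToRaw(canonical))$hex
}

ledger_entry_json <- function(e) {
  # fixed field order: digests must recompute from the serialised form
  sprintf(
    '{"index":%d,"timestamp":"%s","payload_digest":"%s","prev_entry_digest":"%s","entry_digest":"%s"}',
    e$index, e$timestamp, e$payload_digest, e$prev_entry_digest, e$entry_digest
  )
}

#' @rdname notary_agent
#' @export
Notary <- R6::R6Class("Notary",
  public = list(
    #' @field dir agent root directory.
    dir = NULL,
    #' @field clock the injected clock.
    clock = NULL,

    #' @description Create the agent; generates the sandbox Ed25519 keypair
    #'   under `dir/keys/` if absent.
    #' @param dir,clock see [notary_agent()].
    initialize = function(dir, clock = sandbox_clock()) {
      self$dir <- dir_create(dir)
      self$clock <- clock
      dir_create(file.path(dir, "offchain"))
      dir_create(file.path(dir, "keys"))
      private$ledger_path <- file.path(dir, "ledger.jsonl")
      private$records_path <- file.path(dir, "records.jsonl")
      if (!file.exists(private$ledger_path)) file.create(private$ledger_path)
      key_path <- file.path(dir, "keys", "sandbox_ed25519.pem")
      if (file.exists(key_path)) {
        private$key <- openssl::read_key(key_path)
      } else {
        private$key <- openssl::ed25519_keygen()
        openssl::write_pem(private$key, key_path)
        openssl::write_pem(as.list(private$key)$pubkey,
                           file.path(dir, "keys", "sandbox_ed25519.pub.pem"))
      }
      private$reload()
    },

    #' @description The sandbox public key (openssl pubkey object).
    sandbox_pubkey = function() as.list(private$key)$pubkey,

    #' @description Register a user's public key at enrolment; required
    #'   before that user can countersign.
    #' @param user_id principal.
    #' @param pubkey an openssl Ed25519 public key (or PEM file path).
    register_user_key = function(user_id, pubkey) {
      if (is.character(pubkey)) pubkey <- openssl::read_pubkey(pubkey)
      private$user_keys[[user_id]] <- pubkey
      invisible(NULL)
    },

    #' @description Hash an artefact, store the blob off-chain, then append
    #'   the digest to the ledger (off-chain write strictly precedes the
    #'   ledger append). At most one record may exist per (job_id, role).
    #' @param payload raw bytes (or single string).
    #' @param job_id job the artefact belongs to.
    #' @param role one of request, result, report-initial,
    #'   report-sandbox-signed, report-countersigned.
    #' @param user responsible user recorded in the metadata.
    #' @return list with `record` (off-chain metadata) and `entry` (ledger).
    notarize = function(payload, job_id, role, user = NA_character_) {
      if (!role %in% NOTARY_ROLES) {
        stop_sandbox("sandbox_contract_error", "invalid notarisation role '%s'", role)
      }
      key <- paste0(job_id, "\r", role)
      if (!is.null(private$record_index[[key]])) {
        stop_sandbox("sandbox_duplicate_error",
                     "job '%s' already notarised under role '%s'", job_id, role)
      }
      payload <- as_raw_bytes(payload)
      digest <- hash_artifact(payload)
      blob <- file.path(self$dir, "offchain", digest$hex)
      if (!file.exists(blob)) {
        atomic_write(blob, function(tmp) writeBin(payload, tmp))
      }
      record <- list(
        job_id = job_id, role = role, user = user,
        timestamp = self$clock$now_iso(),
        payload_digest = digest$hex, algorithm_id = digest$algorithm_id,
        blob = basename(blob)
      )
      cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
          sep = "", file = private$records_path, append = TRUE)
      private$record_index[[key]] <- record
      entry <- private$append_entry(digest$hex)
      list(record = record, entry = entry)
    },

    #' @description Number of ledger entries.
    ledger_length = function() length(private$entries),

    #' @description All ledger entries as a data frame.
    ledger = function() {
      do.call(rbind, lapply(private$entries, function(e) {
        data.frame(index = e$index, timestamp = e$timestamp,
                   payload_digest = e$payload_digest,
                   prev_entry_digest = e$prev_entry_digest,
                   entry_digest = e$entry_digest, stringsAsFactors = FALSE)
      })) %||% data.frame()
    },

    #' @description Digest of the newest entry (for external anchoring).
    head_digest = function() {
      n <- length(private$entries)
      if (n == 0L) ZERO_DIGEST else private$entries[[n]]$entry_digest
    },

    #' @description Re-read the ledger file and verify the whole chain:
    #'   every entry digest must recompute from its serialised fields and
    #'   link to its predecessor, with indices contiguous from 0.
    #' @return list: `ok` logical and `first_bad_index` (NA when ok).
    verify_ledger = function() {
      lines <- readLines(private$ledger_path, warn = FALSE)
      prev <- ZERO_DIGEST
      for (i in seq_along(lines)) {
        e <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(err) NULL)
        if (is.null(e) || !all(c("index", "timestamp", "payload_digest",
                                 "prev_entry_digest", "entry_digest") %in% names(e))) {
          return(list(ok = FALSE, first_bad_index = i - 1L))
        }
        expected <- entry_digest_hex(e$index, e$timestamp, e$payload_digest, e$prev_entry_digest)
        if (e$index != i - 1L || !identical(e$prev_entry_digest, prev) ||
            !identical(e$entry_digest, expected)) {
          return(list(ok = FALSE, first_bad_index = i - 1L))
        }
        prev <- e$entry_digest
      }
      list(ok = TRUE, first_bad_index = NA_integer_)
    },

    #' @description Verify every off-chain blob still matches its recorded
    #'   digest.
    #' @return list: `ok` and `bad_digests` (character).
    verify_offchain = function() {
      bad <- character()
      for (rec in as.list(private$record_index)) {
        blob <- file.path(self$dir, "offchain", rec$blob)
        if (!file.exists(blob) || !identical(hash_file(blob)$hex, rec$payload_digest)) {
          bad <- c(bad, rec$payload_digest)
        }
      }
      list(ok = length(bad) == 0L, bad_digests = unique(bad))
    },

    #' @description Proof of existence for a digest: earliest ledger entry
    #'   whose payload digest matches.
    #' @param digest hex string or a `sandbox_digest`.
    #' @return list: `found`, `index`, `timestamp`.
    proof_of_existence = function(digest) {
      hex <- if (inherits(digest, "sandbox_digest")) digest$hex else digest
      for (e in private$entries) {
        if (identical(e$payload_digest, hex)) {
          return(list(found = TRUE, index = e$index, timestamp = e$timestamp))
        }
      }
      list(found = FALSE, index = NA_integer_, timestamp = NA_character_)
    },

    #' @description Off-chain metadata record for a (job, role), or NULL.
    #' @param job_id,role record key.
    record_for = function(job_id, role) private$record_index[[paste0(job_id, "\r", role)]],

    #' @description Sign a report with the sandbox private key (detached
    #'   Ed25519 signature over the exact report bytes). Creates the report
    #'   record in state `sandbox_signed`.
    #' @param job_id job the report belongs to.
    #' @param report raw report bytes (or single string).
    #' @param user responsible user carried into later notarisation.
    #' @return the signed-report record (fields `state`, `report`,
    #'   `sandbox_signature`, `sandbox_envelope`).
    sign_report = function(job_id, report, user = NA_character_) {
      if (!is.null(private$reports[[job_id]])) {
        stop_sandbox("sandbox_state_error", "report for job '%s' already signed", job_id)
      }
      report <- as_raw_bytes(report)
      sig <- openssl::ed25519_sign(report, private$key)
      envelope <- charToRaw(as.character(jsonlite::toJSON(list(
        job_id = job_id,
        report = openssl::base64_encode(report),
        sandbox_signature = openssl::base64_encode(sig)
      ), auto_unbox = TRUE)))
      rep <- list(job_id = job_id, user = user, report = report,
                  sandbox_signature = sig, sandbox_envelope = envelope,
                  user_signature = NULL, state = "sandbox_signed")
      private$reports[[job_id]] <- rep
      invisible(rep)
    },

    #' @description The sandbox-signed envelope bytes the user is expected
    #'   to verify and countersign.
    #' @param job_id job id.
    signed_envelope = function(job_id) {
      rep <- private$reports[[job_id]]
      if (is.null(rep)) stop_sandbox("sandbox_state_error", "no signed report for job '%s'", job_id)
      rep$sandbox_envelope
    },

    #' @description Verify a detached signature against a public key.
    #' @param data,signature raw vectors.
    #' @param pubkey openssl public key; defaults to the sandbox key.
    verify_signature = function(data, signature, pubkey = NULL) {
      pubkey <- pubkey %||% self$sandbox_pubkey()
      isTRUE(tryCatch(
        openssl::ed25519_verify(as_raw_bytes(data), signature, pubkey),
        error = function(e) FALSE
      ))
    },

    #' @description Accept a user countersignature over the sandbox-signed
    #'   envelope. On success the three report artefacts (initial,
    #'   sandbox-signed, countersigned) are each stored off-chain and
    #'   appended to the ledger, and the report becomes officially issued.
    #'   A bad signature is rejected with state unchanged.
    #' @param job_id job id.
    #' @param user_signature raw detached signature by the user's key.
    #' @param user_id the countersigning user (must have a registered key).
    #' @return the countersigned report record, invisibly.
    countersign = function(job_id, user_signature, user_id) {
      rep <- private$reports[[job_id]]
      if (is.null(rep) || rep$state != "sandbox_signed") {
        stop_sandbox("sandbox_state_error",
                     "job '%s' has no report in state sandbox_signed", job_id)
      }
      pub <- private$user_keys[[user_id]]
      if (is.null(pub)) {
        stop_sandbox("sandbox_config_error", "no public key registered for user '%s'", user_id)
      }
      if (!self$verify_signature(rep$sandbox_envelope, user_signature, pub)) {
        stop_sandbox("sandbox_signature_error",
                     "user countersignature for job '%s' does not verify", job_id)
      }
      countersigned <- charToRaw(as.character(jsonlite::toJSON(list(
        job_id = job_id,
        report = openssl::base64_encode(rep$report),
        sandbox_signature = openssl::base64_encode(rep$sandbox_signature),
        user_id = user_id,
        user_signature = openssl::base64_encode(user_signature)
      ), auto_unbox = TRUE)))
      self$notarize(rep$report, job_id, "report-initial", user = user_id)
      self$notarize(rep$sandbox_envelope, job_id, "report-sandbox-signed", user = user_id)
      self$notarize(countersigned, job_id, "report-countersigned", user = user_id)
      rep$user_signature <- user_signature
      rep$countersigned_envelope <- countersigned
      rep$state <- "countersigned"
      private$reports[[job_id]] <- rep
      invisible(rep)
    },

    #' @description State of a job's report (`NULL` if never signed).
    #' @param job_id job id.
    report_state = function(job_id) private$reports[[job_id]]$state,

    #' @description Full report record for a job.
    #' @param job_id job id.
    report = function(job_id) private$reports[[job_id]]
  ),
  private = list(
    key = NULL, ledger_path = NULL, records_path = NULL,
    entries = list(), record_index = list(), user_keys = list(), reports = list(),

    append_entry = function(payload_hex) {
      idx <- length(private$entries)
      prev <- self$head_digest()
      ts <- self$clock$now_iso()
      e <- list(index = idx, timestamp = ts, payload_digest = payload_hex,
                prev_entry_digest = prev,
                entry_digest = entry_digest_hex(idx, ts, payload_hex, prev))
      cat(ledger_entry_json(e), "\n", sep = "", file = private$ledger_path, append = TRUE)
      private$entries[[idx + 1L]] <- e
      e
    },

    reload = function() {
      lines <- readLines(private$ledger_path, warn = FALSE)
      private$entries <- lapply(lines, jsonlite::fromJSON)
      if (file.exists(private$records_path)) {
        for (ln in readLines(private$records_path, warn = FALSE)) {
          rec <- jsonlite::fromJSON(ln)
          private$record_index[[paste0(rec$job_id, "\r", rec$role)]] <- rec
        }
      }
      invisible(NULL)
    }
  )
)

#' Countersign helper for the user side
#'
#' Convenience for the reference client: verify the sandbox signature inside
#' a signed envelope and produce the user's detached countersignature over
#' the envelope bytes.
#'
#' @param envelope raw bytes of the sandbox-signed envelope.
#' @param user_key the user's openssl Ed25519 private key.
#' @param sandbox_pubkey the sandbox public key to verify against first
#'   (skipped if `NULL`).
#' @return raw signature bytes.
#' @export
user_countersign <- function(envelope, user_key, sandbox_pubkey = NULL) {
  envelope <- as_raw_bytes(envelope)
  if (!is.null(sandbox_pubkey)) {
    payload <- jsonlite::fromJSON(rawToChar(envelope))
    ok <- tryCatch(openssl::ed25519_verify(
      openssl::base64_decode(payload$report),
      openssl::base64_decode(payload$sandbox_signature),
      sandbox_pubkey
    ), error = function(e) FALSE)
    if (!isTRUE(ok)) {
      stop_sandbox("sandbox_signature_error", "sandbox signature does not verify")
    }
  }
  openssl::ed25519_sign(envelope, user_key)
}
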