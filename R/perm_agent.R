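#' Identity and access management agent
#'
#' The permission agent owns principals, group/subgroup hierarchies, generic
#' resources ("items": datamarts, algorithms, explicit pairs), grants, and
#' time-limited ticketed sessions. Every resource access in the platform is
#' mediated by [PermAgent]'s `check_permission()`; decisions fail closed.
#'
#' Authentication supports several logical profiles per physical user: a
#' built-in local profile (salted, iterated password hashes) plus injectable
#' profile verifiers (e.g. an LDAP-style callback) registered with
#' `add_auth_profile()`.
#'
#' Pair authorisation: a (datamart, algorithm) pair is allowed iff both items
#' are allowed; if an explicit pair item `pair:<dm>|<alg>` has been
#' registered, the pair additionally requires a grant on that pair item —
#' registering a pair item restricts the pair, and deny wins.
#'
#' @examples
#' pa <- perm_agent(clock = fake_clock())
#' pa$add_principal("alice")
#' pa$add_local_profile("alice", "s3cret")
#' pa$add_item("dm1", "datamart")
#' pa$grant("alice", "dm1")
#' s <- pa$authenticate("alice", "s3cret")
#' pa$check_permission(s$ticket, "dm1")
#' @param clock a [sandbox_clock()].
#' @param ttl session time-to-live in seconds (default 8 hours).
#' @param store_path optional JSON file the agent state is persisted to.
#' @param hash_iterations iteration count of the salted password hash.
#' @return `perm_agent()` returns a `PermAgent` R6 object.
#' @export
perm_agent <- function(clock = sandbox_clock(), ttl = 8 * 3600,
                       store_path = NULL, hash_iterations = 2000L) {
  PermAgent$new(clock = clock, ttl = ttl, store_path = store_path,
                hash_iterations = hash_iterations)
}

hash_password <- function(password, salt, iterations) {
  h <- charToRaw(paste0(salt, enc2utf8(password)))
  for (i in seq_len(iterations)) h <- openssl::sha256(h)
  paste(sprintf("%02x", as.integer(h)), collapse = "")
}

# Length-independent-ish comparison over fixed-length hex digests.
const_eq <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b)) == 0L
}

#' @rdname perm_agent
#' @export
PermAgent <- R6::R6Class("PermAgent",
  public = list(
    #' @field clock the injected clock.
    clock = NULL,
    #' @description Create an agent; see [perm_agent()] for arguments.
    #' @param clock,ttl,store_path,hash_iterations see [perm_agent()].
    initialize = function(clock = sandbox_clock(), ttl = 8 * 3600,
                          store_path = NULL, hash_iterations = 2000L) {
      self$clock <- clock
      private$ttl <- ttl
      private$iterations <- as.integer(hash_iterations)
      private$store_path <- store_path
      if (!is.null(store_path) && file.exists(store_path)) private$load()
    },

    #' @description Register a group, optionally under a parent group.
    #'   Insertion that would close a cycle is rejected.
    #' @param group_id,parent group identifiers.
    add_group = function(group_id, parent = NULL) {
      assert_safe_id(group_id, "group_id")
      if (!is.null(parent)) {
        if (is.null(private$groups[[parent]])) {
          stop_sandbox("sandbox_contract_error", "parent group '%s' unknown", parent)
        }
        g <- parent
        while (!is.null(g)) {
          if (identical(g, group_id)) {
            stop_sandbox("sandbox_contract_error",
                         "adding group '%s' under '%s' would create a cycle",
                         group_id, parent)
          }
          g <- private$groups[[g]]$parent
        }
      }
      private$groups[[group_id]] <- list(group_id = group_id, parent = parent)
      private$persist()
      invisible(group_id)
    },

    #' @description Register a principal (physical user).
    #' @param user_id user identifier.
    #' @param groups groups the user is a direct member of.
    add_principal = function(user_id, groups = character()) {
      assert_safe_id(user_id, "user_id")
      for (g in groups) {
        if (is.null(private$groups[[g]])) {
          stop_sandbox("sandbox_contract_error", "group '%s' unknown", g)
        }
      }
      private$principals[[user_id]] <- list(
        user_id = user_id, groups = as.character(groups), profiles = list()
      )
      private$persist()
      invisible(user_id)
    },

    #' @description Add a group membership for an existing principal.
    #' @param user_id,group_id identifiers.
    add_membership = function(user_id, group_id) {
      p <- private$need_principal(user_id)
      if (is.null(private$groups[[group_id]])) {
        stop_sandbox("sandbox_contract_error", "group '%s' unknown", group_id)
      }
      p$groups <- union(p$groups, group_id)
      private$principals[[user_id]] <- p
      private$persist()
      invisible(NULL)
    },

    #' @description Attach a local (password) authentication profile.
    #' @param user_id principal.
    #' @param password clear-text password, stored as a salted iterated hash.
    add_local_profile = function(user_id, password) {
      p <- private$need_principal(user_id)
      salt <- rand_hex(16L)
      p$profiles[["local"]] <- list(
        kind = "local", salt = salt,
        hash = hash_password(password, salt, private$iterations)
      )
      private$principals[[user_id]] <- p
      private$persist()
      invisible(NULL)
    },

    #' @description Attach an injectable authentication profile (e.g. an
    #'   LDAP-style verifier used in tests).
    #' @param user_id principal.
    #' @param kind profile kind tag.
    #' @param verify `function(credentials) -> logical`.
    add_auth_profile = function(user_id, kind, verify) {
      p <- private$need_principal(user_id)
      p$profiles[[kind]] <- list(kind = kind, verify = verify)
      private$principals[[user_id]] <- p
      invisible(NULL)
    },

    #' @description Register an item (generic resource).
    #' @param item_id unique identifier.
    #' @param kind one of datamart, algorithm, pair, other.
    add_item = function(item_id, kind = c("datamart", "algorithm", "pair", "other")) {
      assert_scalar_string(item_id, "item_id")
      kind <- match.arg(kind)
      if (!is.null(private$items[[item_id]])) {
        stop_sandbox("sandbox_contract_error", "item '%s' already registered", item_id)
      }
      private$items[[item_id]] <- list(item_id = item_id, kind = kind)
      private$persist()
      invisible(item_id)
    },

    #' @description Does an item exist?
    #' @param item_id identifier.
    has_item = function(item_id) !is.null(private$items[[item_id]]),

    #' @description Grant an item to a principal or group. Duplicate grants
    #'   are idempotent no-ops.
    #' @param subject principal or group id.
    #' @param item_id granted item.
    grant = function(subject, item_id) {
      if (is.null(private$principals[[subject]]) && is.null(private$groups[[subject]])) {
        stop_sandbox("sandbox_contract_error", "unknown subject '%s'", subject)
      }
      if (is.null(private$items[[item_id]])) {
        stop_sandbox("sandbox_contract_error", "unknown item '%s'", item_id)
      }
      key <- paste0(subject, "\r", item_id)
      if (!is.null(private$grants[[key]])) return(invisible(FALSE))
      private$grants[[key]] <- list(subject = subject, item_id = item_id,
                                    granted_at = self$clock$now_iso())
      private$persist()
      invisible(TRUE)
    },

    #' @description Revoke a grant; unknown targets are a warning no-op, and
    #'   revocation takes effect on the next check.
    #' @param subject,item_id the grant edge.
    revoke_grant = function(subject, item_id) {
      key <- paste0(subject, "\r", item_id)
      if (is.null(private$grants[[key]])) {
        warning(sprintf("no grant (%s, %s) to revoke", subject, item_id))
        return(invisible(FALSE))
      }
      private$grants[[key]] <- NULL
      private$persist()
      invisible(TRUE)
    },

    #' @description Verify credentials and open a fresh ticketed session.
    #'   Unknown user and wrong password are indistinguishable failures.
    #' @param user_id claimed principal.
    #' @param credentials password (local profile) or whatever the profile
    #'   verifier expects.
    #' @param profile profile kind, default `"local"`.
    #' @return a session list (`ticket`, `user_id`, `issued_at`,
    #'   `expires_at`) or `NULL` on failure.
    authenticate = function(user_id, credentials, profile = "local") {
      p <- private$principals[[user_id]]
      prof <- if (!is.null(p)) p$profiles[[profile]]
      ok <- FALSE
      if (!is.null(prof) && prof$kind == "local") {
        ok <- const_eq(hash_password(credentials, prof$salt, private$iterations), prof$hash)
      } else if (!is.null(prof)) {
        ok <- isTRUE(prof$verify(credentials))
      } else {
        # burn comparable time for unknown user / profile
        hash_password(as.character(credentials)[1] %||% "", "decoy", private$iterations)
      }
      if (!ok) return(invisible(NULL))
      now <- self$clock$now()
      s <- list(
        ticket = rand_token(32L), user_id = user_id,
        issued_at = now, expires_at = now + private$ttl, revoked = FALSE
      )
      private$sessions[[s$ticket]] <- s
      s
    },

    #' @description Is a ticket live (known, unexpired, unrevoked)?
    #' @param ticket session ticket.
    ticket_live = function(ticket) {
      s <- if (is.character(ticket) && length(ticket) == 1L) private$sessions[[ticket]]
      !is.null(s) && !s$revoked && self$clock$now() <= s$expires_at
    },

    #' @description Look up the principal behind a live ticket.
    #' @param ticket session ticket.
    session_user = function(ticket) {
      if (!self$ticket_live(ticket)) return(NULL)
      private$sessions[[ticket]]$user_id
    },

    #' @description Revoke a session (idempotent); every later check on the
    #'   ticket yields `auth-required`.
    #' @param ticket session ticket.
    revoke_session = function(ticket) {
      s <- private$sessions[[ticket]]
      if (is.null(s)) {
        warning("no such session to revoke")
        return(invisible(FALSE))
      }
      s$revoked <- TRUE
      private$sessions[[ticket]] <- s
      invisible(TRUE)
    },

    #' @description Permission decision for one item. `allow` iff the ticket
    #'   is live and the principal has a direct grant or a grant on any
    #'   ancestor group along the membership/parent closure; `deny` when live
    #'   but ungranted (unknown items deny, fail closed); `auth-required`
    #'   when the ticket is dead.
    #' @param ticket session ticket.
    #' @param item_id item to check.
    check_permission = function(ticket, item_id) {
      if (!self$ticket_live(ticket)) return("auth-required")
      if (is.null(private$items[[item_id]])) return("deny")
      user <- private$sessions[[ticket]]$user_id
      subjects <- private$closure(user)
      for (s in subjects) {
        if (!is.null(private$grants[[paste0(s, "\r", item_id)]])) return("allow")
      }
      "deny"
    },

    #' @description Decision for a (datamart, algorithm) analysis pair; see
    #'   the class docs for the deny-wins pair-item rule.
    #' @param ticket session ticket.
    #' @param datamart_id,algorithm_id item ids of the pair.
    check_pair = function(ticket, datamart_id, algorithm_id) {
      d1 <- self$check_permission(ticket, datamart_id)
      if (d1 == "auth-required") return("auth-required")
      d2 <- self$check_permission(ticket, algorithm_id)
      if (d2 == "auth-required") return("auth-required")
      if (d1 != "allow" || d2 != "allow") return("deny")
      pair_id <- pair_item_id(datamart_id, algorithm_id)
      if (!is.null(private$items[[pair_id]])) {
        return(self$check_permission(ticket, pair_id))
      }
      "allow"
    },

    #' @description All subjects (the user plus every ancestor group) the
    #'   user's permissions flow from. Exposed for oracle comparison.
    #' @param user_id principal.
    reachable_subjects = function(user_id) private$closure(user_id),

    #' @description Snapshot of groups/items/grants (for inspection).
    state = function() {
      list(
        principals = names(private$principals),
        groups = lapply(as.list(private$groups), identity),
        items = names(private$items),
        grants = unname(lapply(as.list(private$grants), identity))
      )
    }
  ),
  private = list(
    ttl = NULL, iterations = NULL, store_path = NULL,
    principals = list(), groups = list(), items = list(),
    grants = list(), sessions = list(),

    need_principal = function(user_id) {
      p <- private$principals[[user_id]]
      if (is.null(p)) stop_sandbox("sandbox_contract_error", "unknown principal '%s'", user_id)
      p
    },

    closure = function(user_id) {
      p <- private$principals[[user_id]]
      if (is.null(p)) return(character())
      out <- user_id
      frontier <- p$groups
      while (length(frontier)) {
        g <- frontier[[1]]
        frontier <- frontier[-1]
        if (g %in% out) next
        out <- c(out, g)
        parent <- private$groups[[g]]$parent
        if (!is.null(parent)) frontier <- c(frontier, parent)
      }
      out
    },

    # Single-file JSON persistence of the durable part of the state
    # (sessions and injected verifiers are process-local by design).
    persist = function() {
      if (is.null(private$store_path)) return(invisible(NULL))
      durable <- list(
        principals = lapply(private$principals, function(p) {
          p$profiles <- Filter(function(pr) pr$kind == "local", p$profiles)
          p
        }),
        groups = private$groups,
        items = private$items,
        grants = private$grants
      )
      atomic_write(private$store_path, function(tmp) {
        jsonlite::write_json(durable, tmp, auto_unbox = TRUE, null = "null")
      })
      invisible(NULL)
    },

    load = function() {
      durable <- jsonlite::read_json(private$store_path)
      private$principals <- durable$principals %||% list()
      private$groups <- durable$groups %||% list()
      private$items <- durable$items %||% list()
      private$grants <- durable$grants %||% list()
      invisible(NULL)
    }
  )
)

# Canonical id of the optional explicit pair item.
pair_item_id <- function(datamart_id, algorithm_id) {
  paste0("pair:", datamart_id, "|", algorithm_id)
}
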