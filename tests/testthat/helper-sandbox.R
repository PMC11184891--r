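# Shared fixtures: random generators for property-style tests, brute-force
# oracles kept deliberately independent of the implementation paths they
# check, and a compact deployment builder.

new_root <- function(prefix = "sbtest-") {
  dir <- tempfile(prefix)
  dir.create(dir, recursive = TRUE)
  dir
}

# A deployment with short timeouts suitable for test runs.
test_sandbox <- function(..., users = c(alice = "pw"), n_processors = 1L,
                         max_parallel = 2L) {
  sandbox_local(new_root(), users = users, n_processors = n_processors,
                max_parallel = max_parallel, processor_timeout = 30, ...)
}

# -- random token descriptors ------------------------------------------------

random_descriptor <- function(i) {
  kinds <- c("script", "image", "locator")
  kind <- kinds[1 + (i %% 3)]
  aref <- switch(kind,
    script = algo_script(sprintf("algo/run_%d.sh", i)),
    image = algo_image(sprintf("img-%d", i)),
    locator = algo_locator(sprintf("loc_%d", i))
  )
  n_roles <- sample(0:4, 1)
  roles <- if (n_roles) {
    stats::setNames(sample(c("input", "target"), n_roles, replace = TRUE),
                    paste0("f", seq_len(n_roles), "_", sample(999, n_roles)))
  } else character()
  n_set <- sample(0:3, 1)
  settings <- if (n_set) {
    stats::setNames(as.list(as.character(sample(1000, n_set))),
                    paste0("s", seq_len(n_set)))
  } else list()
  sched <- if (i %% 5 == 0) cadence_interval(sample(10:600, 1),
                                             anchor = "2024-01-01T00:00:00.000000Z")
  else if (i %% 7 == 0) cadence_daily(sprintf("%02d:%02d", sample(0:23, 1), sample(0:59, 1)))
  token_descriptor(
    job_id = sprintf("job-%04d-%s", i, paste(sample(letters, 4), collapse = "")),
    user_id = sprintf("user%d", sample(20, 1)),
    algorithm_ref = aref,
    datamart_ref = if (i %% 2 == 0) dm_payload("data/datamart.csv") else dm_locator("dm1"),
    column_roles = roles,
    run_settings = settings,
    notarise = sample(c(TRUE, FALSE), 1),
    sign = sample(c(TRUE, FALSE), 1),
    schedule = sched,
    created_at = "2024-03-04T05:06:07.123456Z"
  )
}

random_payload <- function(max_members = 3L) {
  n <- sample(0:max_members, 1)
  if (!n) return(list())
  stats::setNames(
    lapply(seq_len(n), function(j) as.raw(sample(0:255, sample(1:64, 1), replace = TRUE))),
    paste0(sample(c("", "data/", "nested/dir/"), n, replace = TRUE),
           "m", seq_len(n), ".bin")
  )
}

# -- IAM brute-force oracle --------------------------------------------------

# Random IAM world: acyclic group forest, memberships, grants.
random_iam_world <- function(n_groups = 6L, n_users = 4L, n_items = 3L,
                             n_grants = 5L) {
  groups <- paste0("g", seq_len(n_groups))
  parent <- stats::setNames(vector("list", n_groups), groups)
  for (i in seq_along(groups)[-1]) {
    if (stats::runif(1) < 0.7) parent[[groups[i]]] <- groups[sample(i - 1, 1)]
  }
  users <- paste0("u", seq_len(n_users))
  membership <- lapply(stats::setNames(users, users), function(u) {
    unique(sample(groups, sample(0:2, 1)))
  })
  items <- paste0("it", seq_len(n_items))
  subjects <- c(users, groups)
  grants <- unique(data.frame(
    subject = sample(subjects, n_grants, replace = TRUE),
    item = sample(items, n_grants, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  list(groups = groups, parent = parent, users = users,
       membership = membership, items = items, grants = grants)
}

# Transitive-reachability oracle, independent of PermAgent internals:
# expand user -> groups -> parents to a fixed point, then scan grant edges.
oracle_allowed <- function(world, user, item) {
  subjects <- user
  frontier <- world$membership[[user]]
  while (length(frontier)) {
    g <- frontier[[1]]
    frontier <- frontier[-1]
    if (g %in% subjects) next
    subjects <- c(subjects, g)
    p <- world$parent[[g]]
    if (!is.null(p)) frontier <- c(frontier, p)
  }
  any(world$grants$subject %in% subjects & world$grants$item == item)
}

perm_agent_from_world <- function(world, clock = fake_clock()) {
  pa <- perm_agent(clock = clock)
  for (g in world$groups) pa$add_group(g, parent = world$parent[[g]])
  for (u in world$users) {
    pa$add_principal(u, groups = world$membership[[u]])
    pa$add_local_profile(u, "pw")
  }
  for (it in world$items) pa$add_item(it, "other")
  for (r in seq_len(nrow(world$grants))) {
    pa$grant(world$grants$subject[r], world$grants$item[r])
  }
  pa
}

# -- cohort-query oracle -----------------------------------------------------

# Brute-force row scan with an explicit loop; mirrors the documented
# conjunction semantics without sharing code with apply_cohort_query().
oracle_scan <- function(df, query) {
  keep <- logical(nrow(df))
  ops <- list(eq = `==`, ne = `!=`, lt = `<`, le = `<=`, gt = `>`, ge = `>=`)
  for (r in seq_len(nrow(df))) {
    ok <- TRUE
    for (p in query$predicates) {
      v <- df[[p$field]][r]
      lit <- p$value
      if (is.numeric(v) && is.character(lit)) lit <- as.numeric(lit)
      hit <- if (p$op == "in") v %in% lit else ops[[p$op]](v, lit[1])
      if (is.na(hit) || !hit) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  df[keep, , drop = FALSE]
}

random_query <- function(df, n_preds = 3L) {
  preds <- lapply(seq_len(n_preds), function(i) {
    col <- sample(names(df), 1)
    v <- df[[col]]
    if (is.numeric(v)) {
      pred(col, sample(c(">", ">=", "<", "<=", "=", "!="), 1),
           stats::quantile(v, stats::runif(1), names = FALSE))
    } else {
      pred(col, sample(c("=", "!=", "in"), 1),
           sample(unique(v), min(length(unique(v)), sample(1:2, 1))))
    }
  })
  do.call(cohort_query, preds)
}

count_sentinels <- function(text) {
  length(gregexpr("SENTINEL_", text, fixed = TRUE)[[1]][
    gregexpr("SENTINEL_", text, fixed = TRUE)[[1]] > 0])
}
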