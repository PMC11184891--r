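# Synthetic datamarts, cohort-query semantics and toy algorithms: everything
# needed to exercise the whole platform with zero external data.

#' Synthetic datamart schemas
#'
#' A schema is a list of typed field generators plus a seed; generation is
#' byte-deterministic given the seed. Fields: `sy_num()` draws from a normal
#' distribution (rounded to `digits`), `sy_cat()` samples weighted
#' categories, `sy_date()` samples days uniformly in a range.
#'
#' Generated tables carry an extra `row_sentinel` column by default
#' (`SENTINEL_<schema>_<row>`), a per-row marker that must never appear in
#' any message the proxy sends outward — mediation tests grep channel
#' transcripts for it.
#'
#' @param name schema (datamart) name.
#' @param fields list of field generators.
#' @param seed RNG seed for deterministic generation.
#' @return a `synthetic_schema` object.
#' @export
synthetic_schema <- function(name, fields, seed = 1L) {
  assert_safe_id(name, "schema name")
  structure(list(name = name, fields = fields, seed = as.integer(seed)),
            class = "synthetic_schema")
}

#' @rdname synthetic_schema
#' @param field field name.
#' @param mean,sd normal distribution parameters.
#' @param digits rounding applied to numeric draws.
#' @export
sy_num <- function(field, mean = 0, sd = 1, digits = 3L) {
  structure(list(field = field, type = "numeric", mean = mean, sd = sd,
                 digits = digits), class = "sy_field")
}

#' @rdname synthetic_schema
#' @param levels category labels.
#' @param weights sampling weights (recycled uniform when NULL).
#' @export
sy_cat <- function(field, levels, weights = NULL) {
  structure(list(field = field, type = "categorical", levels = levels,
                 weights = weights %||% rep(1, length(levels))),
            class = "sy_field")
}

#' @rdname synthetic_schema
#' @param from,to inclusive date range ("YYYY-MM-DD").
#' @export
sy_date <- function(field, from = "2015-01-01", to = "2023-12-31") {
  structure(list(field = field, type = "date", from = as.Date(from),
                 to = as.Date(to)), class = "sy_field")
}

#' Generate a synthetic datamart
#'
#' @param schema a [synthetic_schema()].
#' @param n_rows number of rows (>= 0; 0 yields a header-only table).
#' @param path optional CSV destination (RFC-4180, UTF-8, header row);
#'   written deterministically, so equal seeds give identical bytes.
#' @param sentinel include the `row_sentinel` marker column.
#' @return the generated data frame, invisibly when `path` is given.
#' @export
generate_datamart <- function(schema, n_rows, path = NULL, sentinel = TRUE) {
  if (!inherits(schema, "synthetic_schema")) {
    stop_sandbox("sandbox_contract_error", "schema must be a synthetic_schema")
  }
  n_rows <- as.integer(n_rows)
  if (is.na(n_rows) || n_rows < 0L) {
    stop_sandbox("sandbox_contract_error", "n_rows must be >= 0")
  }
  df <- with_seed(schema$seed, {
    cols <- lapply(schema$fields, function(f) {
      switch(f$type,
        numeric = round(stats::rnorm(n_rows, f$mean, f$sd), f$digits),
        categorical = if (n_rows == 0L) character() else {
          sample(f$levels, n_rows, replace = TRUE, prob = f$weights / sum(f$weights))
        },
        date = if (n_rows == 0L) as.Date(character()) else {
          f$from + sample.int(as.integer(f$to - f$from) + 1L, n_rows, replace = TRUE) - 1L
        }
      )
    })
    names(cols) <- vapply(schema$fields, `[[`, "", "field")
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  })
  if (n_rows == 0L && ncol(df) == 0L) {
    # as.data.frame of empty cols loses names; rebuild header-only frame
    df <- as.data.frame(stats::setNames(
      lapply(schema$fields, function(f) character()),
      vapply(schema$fields, `[[`, "", "field")
    ), check.names = FALSE)
  }
  if (sentinel) {
    df$row_sentinel <- if (n_rows == 0L) character() else {
      sprintf("SENTINEL_%s_%06d", schema$name, seq_len(n_rows))
    }
  }
  if (!is.null(path)) {
    atomic_write(path, function(tmp) {
      utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    })
    return(invisible(df))
  }
  df
}

#' Demo patient datamart schema
#'
#' The stock fixture used throughout the tests and examples: a plausible
#' oncology-flavoured patient table with age (normal, mean 62, sd 12),
#' sex, a continuous biomarker and a diagnosis date.
#'
#' @param name datamart name.
#' @param seed RNG seed.
#' @return a [synthetic_schema()].
#' @export
demo_patient_schema <- function(name = "patients", seed = 101L) {
  synthetic_schema(name, seed = seed, fields = list(
    sy_num("age", mean = 62, sd = 12, digits = 0L),
    sy_cat("sex", c("F", "M"), weights = c(0.52, 0.48)),
    sy_num("biomarker", mean = 50, sd = 10, digits = 2L),
    sy_date("diagnosis_date", "2016-01-01", "2023-12-31")
  ))
}

#' Generate a minimal OMOP-style two-table subset
#'
#' `person(person_id, gender, year_of_birth)` and
#' `condition_occurrence(person_id, condition_concept_id, start_date)`, with
#' referential integrity (every condition row's person exists) and 0-3
#' conditions per person. Deterministic given the seed.
#'
#' @param n_patients number of persons (>= 0).
#' @param seed RNG seed.
#' @param dir optional directory; when given, writes `person.csv` and
#'   `condition_occurrence.csv`.
#' @return named list of the two data frames.
#' @export
generate_omop_lite <- function(n_patients, seed = 1L, dir = NULL) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0L) {
    stop_sandbox("sandbox_contract_error", "n_patients must be >= 0")
  }
  concepts <- c(201826L, 316866L, 434557L, 443392L)  # toy condition concept ids
  tabs <- with_seed(seed, {
    person <- data.frame(
      person_id = seq_len(n_patients),
      gender = if (n_patients == 0L) character() else sample(c("F", "M"), n_patients, TRUE),
      year_of_birth = if (n_patients == 0L) integer() else sample(1930:2005, n_patients, TRUE),
      stringsAsFactors = FALSE
    )
    n_cond <- if (n_patients == 0L) integer() else pmin(stats::rpois(n_patients, 1.2), 3L)
    pid <- rep(person$person_id, n_cond)
    condition <- data.frame(
      person_id = pid,
      condition_concept_id = if (!length(pid)) integer() else sample(concepts, length(pid), TRUE),
      start_date = if (!length(pid)) character() else {
        as.character(as.Date("2018-01-01") + sample.int(2000L, length(pid), TRUE))
      },
      stringsAsFactors = FALSE
    )
    list(person = person, condition_occurrence = condition)
  })
  if (!is.null(dir)) {
    dir_create(dir)
    utils::write.csv(tabs$person, file.path(dir, "person.csv"), row.names = FALSE)
    utils::write.csv(tabs$condition_occurrence,
                     file.path(dir, "condition_occurrence.csv"), row.names = FALSE)
  }
  tabs
}

# -- cohort queries ----------------------------------------------------------

COHORT_OPS <- c("eq" = "==", "ne" = "!=", "lt" = "<", "le" = "<=",
                "gt" = ">", "ge" = ">=", "in" = "%in%")

normalize_op <- function(op) {
  if (op %in% names(COHORT_OPS)) return(op)
  sym <- c("=" = "eq", "==" = "eq", "!=" = "ne", "<" = "lt", "<=" = "le",
           ">" = "gt", ">=" = "ge", "in" = "in")
  if (op %in% names(sym)) return(unname(sym[[op]]))
  stop_sandbox("sandbox_query_error", "unknown predicate operator '%s'", op)
}

#' Cohort queries: conjunctions of field predicates
#'
#' A cohort query is a conjunction (AND) of predicates
#' `(field, operator, literal)` with operators `=, !=, <, <=, >, >=, in`.
#' Fields may be qualified `table.field` for the OMOP-lite two-table case,
#' where person and condition rows are joined on `person_id`. The empty
#' conjunction selects everything.
#'
#' @param ... predicates built with [pred()].
#' @return a `cohort_query` object.
#' @examples
#' q <- cohort_query(pred("age", ">=", 60), pred("sex", "=", "F"))
#' @export
cohort_query <- function(...) {
  preds <- list(...)
  for (p in preds) {
    if (!inherits(p, "cohort_pred")) {
      stop_sandbox("sandbox_query_error", "cohort_query() takes pred() predicates")
    }
  }
  structure(list(predicates = preds), class = "cohort_query")
}

#' @rdname cohort_query
#' @param field field name, optionally `table.`-qualified.
#' @param op comparison operator (symbolic or tag form).
#' @param value literal (vector allowed for `in`).
#' @export
pred <- function(field, op, value) {
  assert_scalar_string(field, "predicate field")
  structure(list(field = field, op = normalize_op(op), value = value),
            class = "cohort_pred")
}

pred_mask <- function(column, p, field_label) {
  value <- p$value
  if (is.numeric(column) && is.character(value)) {
    coerced <- suppressWarnings(as.numeric(value))
    if (anyNA(coerced)) {
      stop_sandbox("sandbox_query_error",
                   "literal for numeric field '%s' is not numeric", field_label)
    }
    value <- coerced
  }
  if (!is.numeric(column) && is.numeric(value) && p$op %in% c("eq", "ne", "in")) {
    value <- as.character(value)
  }
  if (inherits(column, "Date")) value <- as.Date(as.character(value))
  mask <- switch(p$op,
    eq = column == value[1],
    ne = column != value[1],
    lt = column < value[1],
    le = column <= value[1],
    gt = column > value[1],
    ge = column >= value[1],
    `in` = column %in% value
  )
  mask & !is.na(mask)
}

resolve_field <- function(df, field) {
  if (field %in% names(df)) return(field)
  # unqualified name against qualified join columns, if unambiguous
  hits <- names(df)[sub("^[^.]+\\.", "", names(df)) == field]
  if (length(hits) == 1L) return(hits)
  stop_sandbox("sandbox_query_error", "unknown field '%s' in cohort query", field)
}

#' Apply a cohort query
#'
#' Returns exactly the rows satisfying the conjunction, preserving input
#' order. For a named list of OMOP-lite tables (`person`,
#' `condition_occurrence`) the two tables are inner-joined on `person_id`
#' (columns become `table.field`-qualified) before filtering.
#'
#' @param tables a data frame, or a named list of the two OMOP-lite tables.
#' @param query a [cohort_query()] (or `NULL` for everything).
#' @return the selected rows as a data frame.
#' @export
apply_cohort_query <- function(tables, query = NULL) {
  df <- if (is.data.frame(tables)) tables else join_omop_tables(tables)
  if (is.null(query)) return(df)
  if (!inherits(query, "cohort_query")) {
    stop_sandbox("sandbox_query_error", "query must be a cohort_query")
  }
  keep <- rep(TRUE, nrow(df))
  for (p in query$predicates) {
    col <- resolve_field(df, p$field)
    keep <- keep & pred_mask(df[[col]], p, p$field)
  }
  df[keep, , drop = FALSE]
}

join_omop_tables <- function(tables) {
  if (!is.list(tables) || !all(c("person", "condition_occurrence") %in% names(tables))) {
    stop_sandbox("sandbox_query_error",
                 "expected a data frame or a list with person and condition_occurrence")
  }
  person <- tables$person
  cond <- tables$condition_occurrence
  qualify <- function(df, tab) {
    names(df) <- ifelse(names(df) == "person_id", "person_id", paste0(tab, ".", names(df)))
    df
  }
  person <- qualify(person, "person")
  cond <- qualify(cond, "condition_occurrence")
  person$..p <- seq_len(nrow(person))
  cond$..c <- seq_len(nrow(cond))
  joined <- merge(person, cond, by = "person_id", sort = FALSE)
  joined <- joined[order(joined$..p, joined$..c), , drop = FALSE]
  joined$..p <- NULL
  joined$..c <- NULL
  rownames(joined) <- NULL
  joined
}

# -- toy algorithms ----------------------------------------------------------

toy_sources <- function() {
  list(
    row_counter = list(ext = "sh", code = paste(
      "#!/bin/sh",
      "set -e",
      "n=$(wc -l < data/datamart.csv)",
      "echo $((n - 1)) > results/row_count.txt",
      sep = "\n"
    )),
    column_summariser = list(ext = "R", code = paste(
      'd <- utils::read.csv("data/datamart.csv", check.names = FALSE)',
      'con <- file("results/summary.txt", "w")',
      "for (nm in names(d)) {",
      "  v <- d[[nm]]",
      "  if (is.numeric(v)) {",
      '    cat(nm, "mean", format(mean(v), digits = 10), "\\n", file = con)',
      "  } else {",
      # aggregate only: number of distinct levels, never the level values
      '    cat(nm, "n_distinct", length(unique(v)), "\\n", file = con)',
      "  }",
      "}",
      "close(con)",
      sep = "\n"
    )),
    sleeper = list(ext = "sh", code = paste(
      "#!/bin/sh",
      'sleep "${SANDBOX_SETTING_DURATION:-0}"',
      'echo "slept ${SANDBOX_SETTING_DURATION:-0}" > results/slept.txt',
      sep = "\n"
    ))
  )
}

#' Toy algorithm catalog
#'
#' Writes the three runnable fixture algorithms into `dir` and returns their
#' catalog entries: `row_counter` (shell; writes the payload row count),
#' `column_summariser` (R; per-field mean for numerics, distinct-level count
#' for categoricals — aggregates only, never row values), and `sleeper`
#' (shell; sleeps `duration` seconds from the run settings, for
#' load-balancing and parallelism tests).
#'
#' @param dir directory the scripts are written to.
#' @return list of [algorithm_entry()] objects keyed by item id.
#' @export
toy_algorithm_catalog <- function(dir) {
  dir_create(dir)
  src <- toy_sources()
  entries <- list()
  for (nm in names(src)) {
    path <- file.path(dir, paste0(nm, ".", src[[nm]]$ext))
    writeLines(src[[nm]]$code, path)
    entries[[nm]] <- algorithm_entry(
      item_id = nm, name = gsub("_", " ", nm), kind = "script", locator = path
    )
  }
  entries
}
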