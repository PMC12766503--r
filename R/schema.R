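#' @importFrom rlang .data
#' @importFrom stats setNames rgeom runif rbinom
#' @importFrom utils head tail
NULL

FIELD_ROLES <- c("identifier", "eligibility", "demographic", "other")
NORMALIZERS <- c("exact", "text", "email", "phone", "date")

#' Declare one screening-survey field
#'
#' A field spec names a column of the screening export, assigns it a role
#' (identifiers are the fields fraudsters mutate; eligibility/demographic
#' fields drive quotas), and picks the normalizer applied before any
#' matching. Matching is always on canonical, never raw, values: real
#' submissions vary in case, spacing and phone formatting, and an
#' exact-match engine that compared raw strings would silently miss
#' duplicates.
#'
#' @param name unique, non-empty field name (the CSV column header).
#' @param role one of `"identifier"`, `"eligibility"`, `"demographic"`,
#'   `"other"`.
#' @param normalizer one of `"exact"`, `"text"`, `"email"`, `"phone"`,
#'   `"date"`. See [normalize_value()] for each rule.
#' @return a one-row tibble of class `field_spec`.
#' @export
#' @examples
#' field_spec("email", role = "identifier", normalizer = "email")
field_spec <- function(name, role = "other", normalizer = "exact") {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(trimws(name))) {
    abort_config("field_spec: `name` must be a non-empty string")
  }
  role <- match.arg(role, FIELD_ROLES)
  normalizer <- match.arg(normalizer, NORMALIZERS)
  out <- tibble::tibble(name = name, role = role, normalizer = normalizer)
  class(out) <- c("field_spec", class(out))
  out
}

#' Assemble a screening schema
#'
#' @param ... `field_spec` rows (or a single data frame with columns
#'   `name`, `role`, `normalizer`).
#' @return tibble of class `screen_schema`, one row per field.
#' @export
#' @examples
#' screen_schema(
#'   field_spec("first_name", "identifier", "text"),
#'   field_spec("email", "identifier", "email")
#' )
screen_schema <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]]) && !inherits(parts[[1]], "field_spec")) {
    df <- tibble::as_tibble(parts[[1]])
    need <- c("name", "role", "normalizer")
    if (!all(need %in% names(df))) {
      abort_config("screen_schema: data frame input needs columns name, role, normalizer")
    }
    parts <- lapply(seq_len(nrow(df)), function(i) {
      field_spec(df$name[i], df$role[i], df$normalizer[i])
    })
  }
  sch <- dplyr::bind_rows(parts)
  if (nrow(sch) == 0L) abort_config("screen_schema: at least one field is required")
  if (anyDuplicated(sch$name)) {
    abort_config(paste0(
      "screen_schema: duplicate field name(s): ",
      paste(unique(sch$name[duplicated(sch$name)]), collapse = ", ")
    ))
  }
  class(sch) <- c("screen_schema", "tbl_df", "tbl", "data.frame")
  sch
}

schema_fields <- function(schema) schema$name

schema_normalizer <- function(schema, field) schema$normalizer[match(field, schema$name)]

identifier_fields <- function(schema) schema$name[schema$role == "identifier"]

#' Normalize a raw field value to its canonical matching form
#'
#' Deterministic, idempotent canonicalization. Empty or whitespace-only
#' input maps to `NA` (missing), and missing never matches missing
#' downstream: two blank phone numbers are not evidence that two
#' submissions came from the same person.
#'
#' Rules:
#' * `exact` — value kept as-is (only the emptiness rule applies).
#' * `text` — Unicode NFC, case-fold, trim, internal whitespace collapsed
#'   to single spaces.
#' * `email` — trim + case-fold (the domain is case-insensitive and in
#'   practice so is the local part).
#' * `phone` — strip non-digits; when 10 or more digits remain, compare on
#'   the last 10 (drops country prefixes).
#' * `date` — parsed (ISO `YYYY-MM-DD`, `MM/DD/YYYY`, or `DD-Mon-YYYY`) and
#'   re-emitted as ISO `YYYY-MM-DD`; unparseable values become missing.
#'
#' @param raw character vector of raw values.
#' @param normalizer one of `"exact"`, `"text"`, `"email"`, `"phone"`,
#'   `"date"`.
#' @return character vector of canonical values, `NA` where missing.
#' @export
#' @examples
#' normalize_value("  Dana  SMITH ", "text")      # "dana smith"
#' normalize_value("(843) 555-0101", "phone")     # "8435550101"
#' normalize_value("A.B@Example.COM", "email")    # "a.b@example.com"
normalize_value <- function(raw, normalizer) {
  normalizer <- match.arg(normalizer, NORMALIZERS)
  raw <- as.character(raw)
  out <- switch(normalizer,
    exact = raw,
    text = {
      x <- stringi::stri_trans_nfc(raw)
      x <- stringi::stri_trans_tolower(x)
      x <- gsub("\\s+", " ", x, perl = TRUE)
      trimws(x)
    },
    email = tolower(trimws(raw)),
    phone = {
      d <- gsub("[^0-9]", "", raw)
      ifelse(nchar(d) >= 10L, substr(d, nchar(d) - 9L, nchar(d)), d)
    },
    date = {
      vapply(raw, function(v) {
        if (is.na(v) || !nzchar(trimws(v))) return(NA_character_)
        v <- trimws(v)
        for (fmt in c("%Y-%m-%d", "%m/%d/%Y", "%d-%b-%Y")) {
          dt <- as.Date(v, format = fmt)
          if (!is.na(dt)) return(format(dt, "%Y-%m-%d"))
        }
        NA_character_
      }, character(1), USE.NAMES = FALSE)
    }
  )
  out[is.na(out) | !nzchar(trimws(out))] <- NA_character_
  out
}

parse_submitted_at <- function(x, tz) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  fmts <- c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  )
  todo <- !is.na(x) & nzchar(trimws(x))
  for (fmt in fmts) {
    if (!any(todo & is.na(out))) break
    idx <- which(todo & is.na(out))
    parsed <- as.POSIXct(strptime(trimws(x[idx]), format = fmt, tz = tz))
    out[idx] <- parsed
  }
  out
}

#' Load screening submissions into an ordered record store
#'
#' Validates, normalizes, and time-orders a flat screening export. All
#' downstream matching and quota evaluation runs on the store, never on the
#' raw table. The row count is preserved exactly (no silent drops) and
#' records are ordered by submission time with ties broken by `record_id`,
#' which fixes which member of a same-timestamp duplicate pair counts as
#' the original.
#'
#' @param table data frame with columns `record_id`, `submitted_at`
#'   (ISO-8601 date or datetime), plus every schema field.
#' @param schema a [screen_schema()].
#' @param tz study timezone for interpreting timestamps; "same day" means
#'   same calendar date in this zone. Default `"UTC"`.
#' @return tibble of class `screen_store`: `record_id`, `submitted_at`
#'   (POSIXct), `submitted_date` (Date in `tz`), then one normalized column
#'   per schema field.
#' @export
load_records <- function(table, schema, tz = "UTC") {
  stopifnot(inherits(schema, "screen_schema"))
  table <- tibble::as_tibble(table)
  need <- c("record_id", "submitted_at", schema_fields(schema))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort_input(paste0("load_records: missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ids <- as.character(table$record_id)
  if (anyNA(ids) || any(!nzchar(ids))) abort_input("load_records: empty record_id")
  if (anyDuplicated(ids)) {
    abort_input(paste0(
      "load_records: duplicate record_id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  ts <- parse_submitted_at(table$submitted_at, tz = tz)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    abort_input(paste0(
      "load_records: unparseable submitted_at in row(s) ",
      paste(head(bad, 5L), collapse = ", "),
      " (record_id ", paste(head(ids[bad], 5L), collapse = ", "), ")"
    ))
  }
  store <- tibble::tibble(
    record_id = ids,
    submitted_at = ts,
    submitted_date = as.Date(ts, tz = tz)
  )
  for (f in schema_fields(schema)) {
    store[[f]] <- normalize_value(table[[f]], schema_normalizer(schema, f))
  }
  store <- store[order(store$submitted_at, store$record_id), , drop = FALSE]
  store <- tibble::as_tibble(store)
  attr(store, "schema") <- schema
  attr(store, "tz") <- tz
  class(store) <- c("screen_store", class(store))
  store
}

#' Read a screening CSV export into a record store
#'
#' Thin wrapper over [load_records()]: UTF-8, header row, all columns read
#' as character (so phone numbers and zero-padded ids survive).
#'
#' @inheritParams load_records
#' @param path path to the CSV file.
#' @return a `screen_store`; see [load_records()].
#' @export
read_screens <- function(path, schema, tz = "UTC") {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  load_records(tab, schema, tz = tz)
}

store_schema <- function(store) attr(store, "schema")
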