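#' Define one duplicate-flagging criterion (AND over its fields)
#'
#' A criterion is a conjunction: two submissions satisfy it only when
#' EVERY listed field agrees on canonical values, with neither side
#' missing. Criteria combine disjunctively in a [criteria_set()]: a pair
#' is a duplicate pair when ANY criterion fires within the time window.
#' A typical setup is `{first_name, last_name}` OR `{email}` OR `{phone}`.
#'
#' @param label short label reported in flag annotations.
#' @param fields character vector (length >= 1, duplicate-free) of schema
#'   field names.
#' @return object of class `match_criterion`.
#' @export
match_criterion <- function(label, fields) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_config("match_criterion: `label` must be a non-empty string")
  }
  fields <- as.character(fields)
  if (length(fields) < 1L || anyNA(fields) || any(!nzchar(fields))) {
    abort_config("match_criterion: `fields` must name at least one field")
  }
  if (anyDuplicated(fields)) abort_config("match_criterion: duplicate fields in one criterion")
  structure(list(label = label, fields = fields), class = "match_criterion")
}

#' Bundle criteria with a time window
#'
#' The full duplicate-flagging rule: OR across criteria, AND within each
#' criterion, evaluated only for submissions whose dates lie within
#' `window_days` of one another (inclusive). The shipped example uses 183
#' days for a six-month window; months are never computed calendar-wise.
#'
#' @param criteria list of [match_criterion()] objects (length >= 1).
#' @param window_days positive integer; window boundary is inclusive.
#' @param schema optional [screen_schema()]; when given, every referenced
#'   field is checked against it immediately.
#' @return object of class `criteria_set`.
#' @export
criteria_set <- function(criteria, window_days, schema = NULL) {
  if (inherits(criteria, "match_criterion")) criteria <- list(criteria)
  if (!is.list(criteria) || length(criteria) < 1L ||
      !all(vapply(criteria, inherits, logical(1), "match_criterion"))) {
    abort_config("criteria_set: `criteria` must be a list of match_criterion objects")
  }
  labels <- vapply(criteria, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort_config("criteria_set: duplicate criterion labels")
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1L) {
    abort_config("criteria_set: `window_days` must be a positive integer")
  }
  cs <- structure(list(criteria = criteria, window_days = window_days),
                  class = "criteria_set")
  if (!is.null(schema)) check_criteria_fields(cs, schema)
  cs
}

check_criteria_fields <- function(cs, schema) {
  known <- schema_fields(schema)
  for (cr in cs$criteria) {
    unknown <- setdiff(cr$fields, known)
    if (length(unknown)) {
      abort_config(paste0(
        "criterion '", cr$label, "' references unknown field(s): ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  invisible(cs)
}

criteria_labels <- function(cs) vapply(cs$criteria, `[[`, character(1), "label")

# Canonical per-criterion match key for each record in a store: the
# criterion's field values joined with an unprintable separator, NA if any
# field is missing (missing never matches missing).
criterion_key <- function(store, criterion) {
  vals <- lapply(criterion$fields, function(f) {
    if (is.null(store[[f]])) {
      abort_config(paste0("criterion '", criterion$label,
                          "' references unknown field: ", f))
    }
    store[[f]]
  })
  any_na <- Reduce(`|`, lapply(vals, is.na))
  key <- do.call(paste, c(vals, sep = "\x1f"))
  key[any_na] <- NA_character_
  key
}

#' Does one criterion match a pair of records?
#'
#' TRUE iff every field of the criterion has equal canonical values on the
#' two records and neither side is missing. Symmetric in its record
#' arguments.
#'
#' @param a,b single-row slices of a `screen_store`.
#' @param criterion a [match_criterion()].
#' @return logical scalar.
#' @export
criterion_matches <- function(a, b, criterion) {
  ka <- criterion_key(a, criterion)
  kb <- criterion_key(b, criterion)
  !is.na(ka) && !is.na(kb) && ka == kb
}

#' Which criteria match a pair of records?
#'
#' Returns the labels of ALL satisfied criteria, not just the first: flag
#' annotations report every failed criterion so staff can see which fields
#' triggered a flag and which fields a fraudster knew to change.
#'
#' @inheritParams criterion_matches
#' @param cs a [criteria_set()].
#' @return character vector of labels; empty means no match.
#' @export
matched_criteria <- function(a, b, cs) {
  hit <- vapply(cs$criteria, function(cr) criterion_matches(a, b, cr), logical(1))
  criteria_labels(cs)[hit]
}

#' Are two records within the comparison window?
#'
#' Date (not second) resolution, inclusive at the boundary: a gap of
#' exactly `window_days` calendar days still counts.
#'
#' @inheritParams criterion_matches
#' @param window_days positive integer.
#' @return logical scalar.
#' @export
within_window <- function(a, b, window_days) {
  gap <- abs(as.integer(a$submitted_date - b$submitted_date))
  gap <= window_days
}
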