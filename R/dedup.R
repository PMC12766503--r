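#' Enumerate duplicate pairs in a record store
#'
#' The batch matching engine. For each criterion, records are grouped on
#' the canonical joint value of the criterion's fields (records with any
#' missing field never group); every same-key pair is a candidate, and
#' candidates are kept when their date gap is within the window. Indices
#' `i < j` refer to store (time) order, so `j` is always the later record
#' of a pair.
#'
#' @param store a `screen_store`.
#' @param cs a [criteria_set()].
#' @return tibble: `i`, `j` (store row indices, `i < j`), `id_i`, `id_j`,
#'   `labels` (list column of matched criterion labels), `gap_days`.
#' @export
duplicate_pairs <- function(store, cs) {
  check_criteria_fields(cs, store_schema(store))
  n <- nrow(store)
  empty <- tibble::tibble(
    i = integer(), j = integer(),
    id_i = character(), id_j = character(),
    labels = list(), gap_days = integer()
  )
  if (n < 2L) return(empty)
  per_crit <- lapply(cs$criteria, function(cr) {
    key <- criterion_key(store, cr)
    idx <- which(!is.na(key))
    if (length(idx) < 2L) return(NULL)
    grp <- split(idx, key[idx])
    grp <- grp[lengths(grp) >= 2L]
    if (!length(grp)) return(NULL)
    pr <- do.call(rbind, lapply(grp, function(g) {
      g <- sort(g)
      t(utils::combn(g, 2L))
    }))
    tibble::tibble(i = pr[, 1L], j = pr[, 2L], label = cr$label)
  })
  pairs <- dplyr::bind_rows(per_crit)
  if (nrow(pairs) == 0L) return(empty)
  pairs$gap_days <- as.integer(abs(
    store$submitted_date[pairs$j] - store$submitted_date[pairs$i]
  ))
  pairs <- pairs[pairs$gap_days <= cs$window_days, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  out <- pairs |>
    dplyr::group_by(.data$i, .data$j, .data$gap_days) |>
    dplyr::summarise(labels = list(.data$label), .groups = "drop") |>
    dplyr::arrange(.data$i, .data$j)
  tibble::tibble(
    i = out$i, j = out$j,
    id_i = store$record_id[out$i], id_j = store$record_id[out$j],
    labels = out$labels, gap_days = out$gap_days
  )
}

#' Check one incoming submission against all prior submissions
#'
#' The streaming check applied at the moment a screening survey is
#' submitted: the new record is compared against every prior record whose
#' date lies within the window, and all matches are reported with their
#' criterion labels and day gaps (staff review sees the full evidence, not
#' just the first hit). The record then joins the comparison store
#' regardless of the decision, so later resubmissions match the whole
#' chain rather than only the original.
#'
#' @param record one-row `screen_store` slice (the incoming submission).
#' @param store prior records (a `screen_store`; may have zero rows).
#' @param cs a [criteria_set()].
#' @param mode `"auto"` (matched records are auto-rejected at screening) or
#'   `"review"` (matched records are flagged for a staff decision).
#' @return list of class `duplicate_flag`: `record_id`, `matched` (tibble
#'   `prior_record_id`, `criteria` list column, `gap_days`), `decision`
#'   (`"auto_rejected"`, `"needs_review"`, or `"clean"`).
#' @export
check_incoming <- function(record, store, cs, mode = c("review", "auto")) {
  mode <- match.arg(mode)
  matched <- tibble::tibble(
    prior_record_id = character(), criteria = list(), gap_days = integer()
  )
  if (nrow(store) > 0L) {
    gaps <- as.integer(abs(store$submitted_date - record$submitted_date))
    in_win <- gaps <= cs$window_days
    hit_labels <- rep(list(character(0)), nrow(store))
    for (cr in cs$criteria) {
      rk <- criterion_key(record, cr)
      if (is.na(rk)) next
      sk <- criterion_key(store, cr)
      hit <- !is.na(sk) & sk == rk & in_win
      if (any(hit)) {
        hit_labels[hit] <- lapply(hit_labels[hit], c, cr$label)
      }
    }
    idx <- which(lengths(hit_labels) > 0L)
    if (length(idx)) {
      matched <- tibble::tibble(
        prior_record_id = store$record_id[idx],
        criteria = hit_labels[idx],
        gap_days = gaps[idx]
      )
    }
  }
  decision <- if (nrow(matched) == 0L) {
    "clean"
  } else if (mode == "auto") {
    "auto_rejected"
  } else {
    "needs_review"
  }
  structure(
    list(record_id = record$record_id, matched = matched, decision = decision),
    class = "duplicate_flag"
  )
}

#' Flag every record of a store in streaming order
#'
#' Replays the incoming-record check over a batch: records are processed
#' in (submitted_at, record_id) order and each is checked against all
#' earlier records, exactly as if the stream had arrived live.
#'
#' @inheritParams check_incoming
#' @param store a `screen_store`.
#' @return tibble: `record_id`, `decision`, `n_matched`, `matched` (list
#'   column of per-record match tibbles), `min_gap_days` (NA when clean).
#' @export
flag_stream <- function(store, cs, mode = c("review", "auto")) {
  mode <- match.arg(mode)
  check_criteria_fields(cs, store_schema(store))
  n <- nrow(store)
  flags <- vector("list", n)
  for (i in seq_len(n)) {
    prior <- store[seq_len(i - 1L), , drop = FALSE]
    flags[[i]] <- check_incoming(store[i, , drop = FALSE], prior, cs, mode = mode)
  }
  tibble::tibble(
    record_id = vapply(flags, `[[`, character(1), "record_id"),
    decision = vapply(flags, `[[`, character(1), "decision"),
    n_matched = vapply(flags, function(f) nrow(f$matched), integer(1)),
    matched = lapply(flags, `[[`, "matched"),
    min_gap_days = vapply(flags, function(f) {
      if (nrow(f$matched) == 0L) NA_integer_ else min(f$matched$gap_days)
    }, integer(1))
  )
}

#' Group matching submissions into transitive duplicate sets
#'
#' Duplicate sets are the connected components (size >= 2) of the graph
#' whose edges are duplicate pairs. Transitivity is deliberate: if A
#' matches B and B matches C, all three belong to one set even when A and
#' C share no field directly — chained identifier mutation produces
#' exactly this pattern, and case studies report sets of up to 13-15
#' submissions. The earliest member by (submitted_at, record_id) is the
#' set's original; the rest are duplicate entries.
#'
#' @inheritParams duplicate_pairs
#' @return tibble of class `duplicate_sets`: `set_id`, `original_id`,
#'   `entry_ids` (list), `member_ids` (list), `size`; ordered by the
#'   original's timestamp, then id.
#' @export
build_duplicate_sets <- function(store, cs) {
  if (nrow(store) == 0L) abort_input("build_duplicate_sets: empty store")
  pairs <- duplicate_pairs(store, cs)
  empty <- tibble::tibble(
    set_id = integer(), original_id = character(),
    entry_ids = list(), member_ids = list(), size = integer()
  )
  if (nrow(pairs) == 0L) {
    class(empty) <- c("duplicate_sets", class(empty))
    return(empty)
  }
  g <- igraph::graph_from_edgelist(cbind(pairs$i, pairs$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(store) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  groups <- unname(split(seq_len(nrow(store)), comp))
  groups <- groups[lengths(groups) >= 2L]
  # store is time-ordered, so min(index) is the earliest member
  sets <- lapply(groups, function(g_idx) {
    g_idx <- sort(g_idx)
    list(
      original_idx = g_idx[1L],
      original_id = store$record_id[g_idx[1L]],
      member_ids = store$record_id[g_idx],
      entry_ids = store$record_id[g_idx[-1L]]
    )
  })
  ord <- order(
    store$submitted_at[vapply(sets, `[[`, integer(1), "original_idx")],
    vapply(sets, `[[`, character(1), "original_id")
  )
  sets <- sets[ord]
  out <- tibble::tibble(
    set_id = seq_along(sets),
    original_id = vapply(sets, `[[`, character(1), "original_id"),
    entry_ids = lapply(sets, `[[`, "entry_ids"),
    member_ids = lapply(sets, `[[`, "member_ids"),
    size = lengths(lapply(sets, `[[`, "member_ids"))
  )
  class(out) <- c("duplicate_sets", class(out))
  out
}

GAP_CATEGORIES <- c("same_day", "within_week", "within_month", "over_month")

gap_category <- function(gap_days) {
  cut(gap_days,
    breaks = c(-1L, 0L, 7L, 31L, Inf),
    labels = GAP_CATEGORIES
  ) |> as.character()
}

#' Classify duplicate sets into originals, entries, gaps, and field profiles
#'
#' Turns the raw duplicate sets into the audited tally: the number of
#' original duplicates (one per set — the earliest record later duplicated),
#' the number of duplicate entries (every subsequent matching record), the
#' overall duplicate rate, each entry's day gap to its nearest EARLIER
#' match (binned same_day / within_week / within_month / over_month), and a
#' profile of which identifier fields each entry kept versus changed
#' relative to that nearest match.
#'
#' @inheritParams duplicate_pairs
#' @param sets output of [build_duplicate_sets()] on the same store.
#' @return list of class `dedup_result`: counts (`total_records`,
#'   `n_original_duplicates`, `n_duplicate_entries`, `n_duplicate_records`,
#'   `duplicate_rate_pct`, `max_set_size`), `sets`, `entries` (per-entry
#'   tibble with `nearest_prior_id`, `gap_days`, `gap_category`,
#'   `kept_fields`, `changed_fields`), `gap_counts`, `field_profile`.
#' @export
classify_duplicates <- function(store, sets, cs) {
  total <- nrow(store)
  n_members <- sum(sets$size)
  if (total < n_members) abort_input("classify_duplicates: sets larger than store")
  pairs <- duplicate_pairs(store, cs)
  schema <- store_schema(store)
  id_fields <- identifier_fields(schema)

  entry_ids <- unlist(sets$entry_ids, use.names = FALSE)
  if (length(entry_ids)) {
    entry_idx <- match(entry_ids, store$record_id)
    rows <- lapply(entry_idx, function(j) {
      cand <- pairs[pairs$j == j, , drop = FALSE]
      # nearest earlier match: smallest day gap; tie -> latest prior record
      best <- cand[order(cand$gap_days, -cand$i), , drop = FALSE][1L, , drop = FALSE]
      pi <- best$i
      same <- vapply(id_fields, function(f) {
        a <- store[[f]][pi]; b <- store[[f]][j]
        !is.na(a) && !is.na(b) && a == b
      }, logical(1))
      crit_fields <- unique(unlist(lapply(
        cs$criteria[criteria_labels(cs) %in% best$labels[[1L]]], `[[`, "fields"
      )))
      tibble::tibble(
        record_id = store$record_id[j],
        nearest_prior_id = store$record_id[pi],
        matched_labels = best$labels,
        gap_days = best$gap_days,
        gap_category = gap_category(best$gap_days),
        kept_fields = list(crit_fields),
        changed_fields = list(id_fields[!same])
      )
    })
    entries <- dplyr::bind_rows(rows)
  } else {
    entries <- tibble::tibble(
      record_id = character(), nearest_prior_id = character(),
      matched_labels = list(), gap_days = integer(),
      gap_category = character(), kept_fields = list(), changed_fields = list()
    )
  }

  gap_counts <- setNames(integer(length(GAP_CATEGORIES)), GAP_CATEGORIES)
  tab <- table(factor(entries$gap_category, levels = GAP_CATEGORIES))
  gap_counts[names(tab)] <- as.integer(tab)

  profile_key <- vapply(seq_len(nrow(entries)), function(k) {
    kept <- id_fields[!id_fields %in% entries$changed_fields[[k]]]
    same <- vapply(id_fields, function(f) f %in% kept, logical(1))
    if (all(same)) "all_identifiers_kept" else {
      paste0("kept:", paste(id_fields[same], collapse = "+"),
             "|changed:", paste(id_fields[!same], collapse = "+"))
    }
  }, character(1))
  field_profile <- sort(table(profile_key), decreasing = TRUE)

  n_orig <- nrow(sets)
  n_entries <- length(entry_ids)
  res <- list(
    total_records = total,
    n_original_duplicates = n_orig,
    n_duplicate_entries = n_entries,
    n_duplicate_records = n_orig + n_entries,
    duplicate_rate_pct = if (total > 0L) round_half_up(100 * (n_orig + n_entries) / total, 2) else 0,
    max_set_size = if (nrow(sets)) max(sets$size) else 0L,
    sets = sets,
    entries = entries,
    gap_counts = gap_counts,
    field_profile = field_profile
  )
  class(res) <- "dedup_result"
  res
}

#' Per-entry intent profile
#'
#' Descriptive only — no hard fraud verdict. For each duplicate entry and
#' its nearest earlier match: how long after the previous submission it
#' arrived, which criterion fields stayed identical, and which identifier
#' fields were changed. Same-day entries with all identifiers kept look
#' like accidental resubmissions; rapid entries with a changed name but
#' the same email and phone suggest deliberate identity disguise. The
#' final call is left to study staff.
#'
#' @param result a `dedup_result` from [classify_duplicates()].
#' @return tibble: `record_id`, `gap_category`, `changed_fields`,
#'   `kept_fields` (list columns).
#' @export
intent_profile <- function(result) {
  stopifnot(inherits(result, "dedup_result"))
  result$entries[, c("record_id", "gap_category", "changed_fields", "kept_fields")]
}

#' Run the full duplicate-detection pipeline on a store
#'
#' Streaming flags, transitive sets, classification and summary in one
#' call; the pieces are also available individually.
#'
#' @inheritParams flag_stream
#' @return list: `flags` ([flag_stream()]), `sets`
#'   ([build_duplicate_sets()]), `result` ([classify_duplicates()]),
#'   `summary` ([summarize_dedup()]).
#' @export
dedup_screens <- function(store, cs, mode = c("review", "auto")) {
  mode <- match.arg(mode)
  flags <- flag_stream(store, cs, mode = mode)
  sets <- build_duplicate_sets(store, cs)
  result <- classify_duplicates(store, sets, cs)
  list(flags = flags, sets = sets, result = result, summary = summarize_dedup(result))
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("Duplicate screening result\n")
  cat(sprintf("  total screens:        %d\n", x$total_records))
  cat(sprintf("  duplicate sets:       %d (max size %d)\n",
              x$n_original_duplicates, x$max_set_size))
  cat(sprintf("  original duplicates:  %d\n", x$n_original_duplicates))
  cat(sprintf("  duplicate entries:    %d\n", x$n_duplicate_entries))
  cat(sprintf("  duplicate records:    %d (%.2f%%)\n",
              x$n_duplicate_records, x$duplicate_rate_pct))
  gp <- paste(sprintf("%s=%d", names(x$gap_counts), x$gap_counts), collapse = ", ")
  cat("  entry gaps:           ", gp, "\n", sep = "")
  invisible(x)
}
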