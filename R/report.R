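#' Summarize a duplicate-detection result
#'
#' Copies the counts from the result (never recomputes them differently)
#' and formats the rate and gap-category percentages to reporting
#' precision: rate to 2 decimals, category percents to 2 decimals, both
#' half-away-from-zero.
#'
#' @param result a `dedup_result` from [classify_duplicates()].
#' @return list of class `dedup_summary`: `total_screens`,
#'   `n_duplicate_records`, `duplicate_rate_pct`, `n_original_duplicates`,
#'   `n_duplicate_entries`, `max_set_size`, `gap_counts`, `gap_pcts`
#'   (percent of duplicate entries), `field_profile`.
#' @export
summarize_dedup <- function(result) {
  stopifnot(inherits(result, "dedup_result"))
  n_entries <- result$n_duplicate_entries
  gap_pcts <- if (n_entries > 0) {
    round_half_up(100 * result$gap_counts / n_entries, 2)
  } else {
    setNames(rep(0, length(result$gap_counts)), names(result$gap_counts))
  }
  structure(
    list(
      total_screens = result$total_records,
      n_duplicate_records = result$n_duplicate_records,
      duplicate_rate_pct = result$duplicate_rate_pct,
      n_original_duplicates = result$n_original_duplicates,
      n_duplicate_entries = result$n_duplicate_entries,
      max_set_size = result$max_set_size,
      gap_counts = result$gap_counts,
      gap_pcts = gap_pcts,
      field_profile = result$field_profile
    ),
    class = "dedup_summary"
  )
}

#' Duplicate-summary arithmetic from printed components
#'
#' The audit path for published tallies: given a total screen count, a
#' count of original duplicates (one per duplicate set) and of duplicate
#' entries (subsequent matching records), derive the total duplicate
#' records and the duplicate rate exactly as [summarize_dedup()] would.
#' Useful for checking a report's internal consistency when the raw
#' records are not available.
#'
#' @param total_screens total completed screening surveys.
#' @param n_original_duplicates number of original duplicates.
#' @param n_duplicate_entries number of duplicate entries.
#' @return list: `n_duplicate_records`, `duplicate_rate_pct` (2 decimals,
#'   half away from zero), plus the inputs.
#' @export
#' @examples
#' dedup_summary_from_counts(4844, 526, 971)  # 1497 records, 30.90%
dedup_summary_from_counts <- function(total_screens, n_original_duplicates,
                                      n_duplicate_entries) {
  stopifnot(total_screens >= n_original_duplicates + n_duplicate_entries)
  dup <- n_original_duplicates + n_duplicate_entries
  list(
    total_screens = total_screens,
    n_original_duplicates = n_original_duplicates,
    n_duplicate_entries = n_duplicate_entries,
    n_duplicate_records = dup,
    duplicate_rate_pct = round_half_up(100 * dup / total_screens, 2)
  )
}

#' Quota attainment table
#'
#' One row per rule: the effective target (summed per block when blocking
#' is enabled), the achieved enrollment count, and the achieved percent of
#' the final sample, integer-rounded half away from zero (the convention
#' enrollment tables print: 36 of 143 reads 25%).
#'
#' @param ledger a [quota_ledger()] (typically from [quota_replay()]).
#' @param spec the [quota_spec()].
#' @return tibble: `label`, `bound`, `kind`, `amount`, `target`,
#'   `achieved_n`, `achieved_pct`.
#' @export
summarize_quota <- function(ledger, spec = ledger$spec) {
  stopifnot(inherits(ledger, "quota_ledger"), inherits(spec, "quota_spec"))
  final_n <- nrow(ledger$enrolled)
  rows <- lapply(spec$rules, function(r) {
    achieved <- count_in_scope(r, ledger$enrolled)
    if (is.null(spec$block_size)) {
      target <- effective_count(r, spec$total_n)
    } else {
      # sum of per-block effective targets over the blocks actually opened
      n_blocks <- max(1L, ceiling(max(final_n, 1L) / spec$block_size))
      sizes <- pmin(spec$block_size,
                    spec$total_n - (seq_len(n_blocks) - 1L) * spec$block_size)
      target <- sum(vapply(sizes, function(s) scope_effective(r, spec, s), integer(1)))
    }
    tibble::tibble(
      label = r$label, bound = r$bound, kind = r$kind, amount = r$amount,
      target = as.integer(target),
      achieved_n = as.integer(achieved),
      achieved_pct = if (final_n > 0) round_half_up(100 * achieved / final_n) else 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Write dedup outputs (flags CSV, sets CSV, summary JSON)
#'
#' Stable, documented columns. Flags: `record_id`, `decision`,
#' `matched_record_ids` and `matched_criteria` (semicolon-joined),
#' `min_gap_days`. Sets: `set_id`, `original_id`, `entry_ids`
#' (semicolon-joined), `size`.
#'
#' @param dedup output of [dedup_screens()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dedup_outputs <- function(dedup, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flags <- dedup$flags
  flags_out <- tibble::tibble(
    record_id = flags$record_id,
    decision = flags$decision,
    matched_record_ids = vapply(flags$matched, function(m) {
      paste(m$prior_record_id, collapse = ";")
    }, character(1)),
    matched_criteria = vapply(flags$matched, function(m) {
      paste(unique(unlist(m$criteria)), collapse = ";")
    }, character(1)),
    min_gap_days = flags$min_gap_days
  )
  sets_out <- tibble::tibble(
    set_id = dedup$sets$set_id,
    original_id = dedup$sets$original_id,
    entry_ids = vapply(dedup$sets$entry_ids, paste, character(1), collapse = ";"),
    size = dedup$sets$size
  )
  s <- dedup$summary
  summary_json <- list(
    total_screens = s$total_screens,
    n_duplicate_records = s$n_duplicate_records,
    duplicate_rate_pct = s$duplicate_rate_pct,
    n_original_duplicates = s$n_original_duplicates,
    n_duplicate_entries = s$n_duplicate_entries,
    max_set_size = s$max_set_size,
    gap_counts = as.list(s$gap_counts),
    gap_pcts = as.list(s$gap_pcts),
    field_profile = as.list(s$field_profile)
  )
  paths <- file.path(dir, c("flags.csv", "duplicate_sets.csv", "dedup_summary.json"))
  readr::write_csv(flags_out, paths[1])
  readr::write_csv(sets_out, paths[2])
  jsonlite::write_json(summary_json, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write quota outputs (decisions CSV, attainment CSV)
#'
#' @param replay output of [quota_replay()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_quota_outputs <- function(replay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("quota_decisions.csv", "quota_attainment.csv"))
  readr::write_csv(replay$decisions, paths[1])
  readr::write_csv(replay$attainment, paths[2])
  invisible(paths)
}

#' @export
print.dedup_summary <- function(x, ...) {
  cat("Screening duplicate summary\n")
  cat(sprintf("  %d of %d screens were duplicate records (%.2f%%)\n",
              x$n_duplicate_records, x$total_screens, x$duplicate_rate_pct))
  cat(sprintf("  %d original duplicates + %d duplicate entries; largest set %d\n",
              x$n_original_duplicates, x$n_duplicate_entries, x$max_set_size))
  for (g in names(x$gap_counts)) {
    cat(sprintf("  entries %-13s %5d (%.2f%%)\n", paste0(g, ":"),
                x$gap_counts[[g]], x$gap_pcts[[g]]))
  }
  invisible(x)
}
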