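#' Define one enrollment quota rule
#'
#' A rule bounds enrollment of candidates matching a predicate. The
#' predicate is a conjunction of field = value conditions on canonical
#' values, so "nested" quotas (e.g. a minimum for rural women) are just
#' multi-condition predicates. Amounts are either absolute counts or
#' percentages of the scope size (the full sample, or one block when
#' blocking is enabled).
#'
#' @param label short unique label reported in decisions and attainment.
#' @param when named list/vector of field = required canonical value;
#'   must be non-empty.
#' @param bound `"minimum"` or `"maximum"`.
#' @param amount positive number; a count, or a percent in (0, 100].
#' @param kind `"count"` or `"percent"`.
#' @return object of class `quota_rule`.
#' @export
#' @examples
#' quota_rule("male-max", when = c(sex = "male"), bound = "maximum", amount = 2)
quota_rule <- function(label, when, bound = c("minimum", "maximum"),
                       amount, kind = c("count", "percent")) {
  bound <- match.arg(bound)
  kind <- match.arg(kind)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_config("quota_rule: `label` must be a non-empty string")
  }
  when <- as.list(when)
  if (length(when) == 0L || is.null(names(when)) || any(!nzchar(names(when)))) {
    abort_config(paste0("quota_rule '", label, "': `when` must be a named list of field = value"))
  }
  amount <- as.numeric(amount)
  if (is.na(amount) || amount <= 0) {
    abort_config(paste0("quota_rule '", label, "': `amount` must be positive"))
  }
  if (kind == "percent" && amount > 100) {
    abort_config(paste0("quota_rule '", label, "': percent amount must be in (0, 100]"))
  }
  if (kind == "count" && amount != floor(amount)) {
    abort_config(paste0("quota_rule '", label, "': count amount must be an integer"))
  }
  structure(
    list(label = label, when = lapply(when, as.character), bound = bound,
         amount = amount, kind = kind),
    class = "quota_rule"
  )
}

rule_fields <- function(rule) names(rule$when)

# does a one-row record (or ledger row) satisfy the rule predicate?
rule_satisfied <- function(rule, record) {
  all(vapply(names(rule$when), function(f) {
    v <- record[[f]]
    !is.null(v) && !is.na(v) && v == rule$when[[f]]
  }, logical(1)))
}

#' Effective count of a quota rule at a given scope size
#'
#' Percent minimums round up (a 25% floor must guarantee at least that
#' share); percent maximums round down (a 50% ceiling must never be
#' exceedable). Count amounts pass through unchanged.
#'
#' @param rule a [quota_rule()].
#' @param scope_size size of the scope the rule applies to (total sample,
#'   or one block).
#' @return integer effective count.
#' @export
#' @examples
#' effective_count(quota_rule("q", c(status = "quit"), "minimum", 25, "percent"), 143)  # 36
effective_count <- function(rule, scope_size) {
  stopifnot(scope_size >= 1)
  if (rule$kind == "count") return(as.integer(rule$amount))
  x <- rule$amount * scope_size / 100
  if (rule$bound == "minimum") as.integer(ceiling(x)) else as.integer(floor(x))
}

#' Assemble a quota specification
#'
#' @param total_n maximum (final) sample size.
#' @param rules list of [quota_rule()] objects (may be empty: no bounds,
#'   only the total cap applies).
#' @param block_size optional positive integer. When set, every rule is
#'   enforced within consecutive enrollment blocks of this size rather
#'   than over the full sample, which spreads quota enforcement evenly
#'   across the enrollment period; when `NULL` (default) rules apply to
#'   the full sample, which guarantees no candidate is turned away early
#'   for a quota they would satisfy later.
#' @param check_time `"screening"` (evaluate when the screening survey is
#'   completed) or `"enrollment"` (staff delay the check to enrollment
#'   confirmation; the decision stream is then the confirmation order).
#'   Recorded on every decision.
#' @param schema optional [screen_schema()] to validate rule fields
#'   against.
#' @return object of class `quota_spec`. Construction fails for specs
#'   provably infeasible: minimum rules with pairwise mutually exclusive
#'   predicates whose effective counts sum beyond the scope size.
#' @export
quota_spec <- function(total_n, rules = list(), block_size = NULL,
                       check_time = c("screening", "enrollment"), schema = NULL) {
  check_time <- match.arg(check_time)
  total_n <- as.integer(total_n)
  if (is.na(total_n) || total_n < 1L) abort_config("quota_spec: total_n must be a positive integer")
  if (inherits(rules, "quota_rule")) rules <- list(rules)
  if (!all(vapply(rules, inherits, logical(1), "quota_rule"))) {
    abort_config("quota_spec: `rules` must be a list of quota_rule objects")
  }
  labels <- vapply(rules, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort_config("quota_spec: duplicate rule labels")
  if (!is.null(block_size)) {
    block_size <- as.integer(block_size)
    if (is.na(block_size) || block_size < 1L || block_size > total_n) {
      abort_config("quota_spec: block_size must be in [1, total_n]")
    }
  }
  if (!is.null(schema)) {
    known <- schema_fields(schema)
    for (r in rules) {
      unknown <- setdiff(rule_fields(r), known)
      if (length(unknown)) {
        abort_config(paste0("quota rule '", r$label, "' references unknown field(s): ",
                            paste(unknown, collapse = ", ")))
      }
    }
  }
  spec <- structure(
    list(total_n = total_n, rules = rules, block_size = block_size,
         check_time = check_time),
    class = "quota_spec"
  )
  err <- check_feasibility(spec)
  if (!is.null(err)) abort_config(err)
  spec
}

# Provable infeasibility: groups of minimum rules that are pairwise
# mutually exclusive (they constrain a common field to different values)
# must have effective counts summing within the scope size.
check_feasibility <- function(spec) {
  scope <- spec$block_size %||% spec$total_n
  mins <- Filter(function(r) r$bound == "minimum", spec$rules)
  if (length(mins) < 2L) {
    if (length(mins) == 1L && effective_count(mins[[1L]], scope) > scope) {
      return(paste0("infeasible: minimum '", mins[[1L]]$label, "' exceeds scope size ", scope))
    }
    return(NULL)
  }
  if (length(mins) == 1L) return(NULL)
  all_fields <- unique(unlist(lapply(mins, rule_fields)))
  for (f in all_fields) {
    on_f <- Filter(function(r) f %in% rule_fields(r), mins)
    vals <- vapply(on_f, function(r) r$when[[f]], character(1))
    if (length(on_f) >= 1L && !anyDuplicated(vals)) {
      tot <- sum(vapply(on_f, effective_count, integer(1), scope_size = scope))
      if (tot > scope) {
        return(paste0(
          "infeasible: minimums on field '", f, "' (",
          paste(vapply(on_f, `[[`, character(1), "label"), collapse = ", "),
          ") require ", tot, " of ", scope, " scope slots"
        ))
      }
    }
  }
  NULL
}

#' Create an empty enrollment ledger for a quota spec
#'
#' The ledger is the running enrollment state: who was admitted, in what
#' order, with their quota-relevant categories and block index.
#'
#' @param spec a [quota_spec()].
#' @return object of class `quota_ledger`.
#' @export
quota_ledger <- function(spec) {
  stopifnot(inherits(spec, "quota_spec"))
  structure(
    list(spec = spec,
         enrolled = tibble::tibble(record_id = character(), position = integer(),
                                   block = integer())),
    class = "quota_ledger"
  )
}

ledger_block_of <- function(spec, position) {
  if (is.null(spec$block_size)) 0L else (position - 1L) %/% spec$block_size
}

# scope slice of the ledger and scope size for the NEXT admission
current_scope <- function(ledger) {
  spec <- ledger$spec
  n <- nrow(ledger$enrolled)
  if (is.null(spec$block_size)) {
    list(rows = ledger$enrolled, size = spec$total_n, block = 0L,
         filled = n, full_block = TRUE)
  } else {
    blk <- ledger_block_of(spec, n + 1L)
    start <- blk * spec$block_size
    size <- min(spec$block_size, spec$total_n - start)
    rows <- ledger$enrolled[ledger$enrolled$block == blk, , drop = FALSE]
    list(rows = rows, size = size, block = blk, filled = nrow(rows),
         full_block = size == spec$block_size)
  }
}

# effective count within a scope; the final partial block scales count
# amounts ceiling-wise for minimums (capped at scope size) and floor-wise
# for maximums, so no per-block quota becomes unreachable.
scope_effective <- function(rule, spec, scope_size) {
  base_scope <- spec$block_size %||% spec$total_n
  if (rule$kind == "percent" || scope_size == base_scope) {
    min(effective_count(rule, scope_size), scope_size)
  } else {
    full <- effective_count(rule, base_scope)
    scaled <- full * scope_size / base_scope
    if (rule$bound == "minimum") min(as.integer(ceiling(scaled)), scope_size)
    else as.integer(floor(scaled))
  }
}

count_in_scope <- function(rule, scope_rows) {
  if (nrow(scope_rows) == 0L) return(0L)
  ok <- Reduce(`&`, lapply(names(rule$when), function(f) {
    col <- scope_rows[[f]]
    if (is.null(col)) return(rep(FALSE, nrow(scope_rows)))
    !is.na(col) & col == rule$when[[f]]
  }))
  sum(ok)
}

#' Evaluate one eligible candidate against the quota state
#'
#' Decision order: the sample (or total) being full wins; then any maximum
#' the admission would violate; then reserved-slot logic — the candidate
#' is turned away when the open slots remaining after admitting them would
#' no longer suffice to cover the unmet minimums; otherwise admit and
#' update the ledger.
#'
#' Reserved-slot modes: `"independent"` sums per-rule shortfalls, which is
#' exact for mutually exclusive minimum predicates but over-reserves when
#' predicates overlap (one future rural woman covers both a rural and a
#' woman minimum). `"exact"` computes the minimum number of future
#' admissions needed via a greedy cover over category cells.
#'
#' @param record one-row record (e.g. a `screen_store` slice) carrying all
#'   quota fields; a missing quota field is an error, not a rejection.
#' @param ledger a [quota_ledger()].
#' @param spec the [quota_spec()] (must be the ledger's spec).
#' @param reserve_mode `"independent"` (default) or `"exact"`.
#' @return list: `decision` (`"admit"`, `"reject_full"`,
#'   `"reject_maximum"`, `"reject_reserved"`), `rules` (labels
#'   implicated), `ledger` (updated on admit, unchanged otherwise).
#' @export
quota_evaluate <- function(record, ledger, spec = ledger$spec,
                           reserve_mode = c("independent", "exact")) {
  reserve_mode <- match.arg(reserve_mode)
  stopifnot(inherits(ledger, "quota_ledger"), inherits(spec, "quota_spec"))
  n <- nrow(ledger$enrolled)
  if (n >= spec$total_n) {
    return(list(decision = "reject_full", rules = character(0), ledger = ledger))
  }
  qfields <- unique(unlist(lapply(spec$rules, rule_fields)))
  for (f in qfields) {
    v <- record[[f]]
    if (is.null(v) || is.na(v)) {
      abort_input(paste0("quota_evaluate: record '", record$record_id,
                         "' is missing quota field '", f, "'"))
    }
  }
  scope <- current_scope(ledger)

  # maximums first
  viol <- character(0)
  for (r in spec$rules) {
    if (r$bound != "maximum" || !rule_satisfied(r, record)) next
    eff <- scope_effective(r, spec, scope$size)
    if (count_in_scope(r, scope$rows) + 1L > eff) viol <- c(viol, r$label)
  }
  if (length(viol)) {
    return(list(decision = "reject_maximum", rules = viol, ledger = ledger))
  }

  # reserved-slot check for minimums
  mins <- Filter(function(r) r$bound == "minimum", spec$rules)
  if (length(mins)) {
    open_after <- scope$size - (scope$filled + 1L)
    shortfalls <- vapply(mins, function(r) {
      eff <- scope_effective(r, spec, scope$size)
      have <- count_in_scope(r, scope$rows) + as.integer(rule_satisfied(r, record))
      max(0L, eff - have)
    }, integer(1))
    needed <- if (reserve_mode == "independent") {
      sum(shortfalls)
    } else {
      min_cover_size(mins, shortfalls)
    }
    if (needed > open_after) {
      lab <- vapply(mins, `[[`, character(1), "label")
      blocked_by <- lab[shortfalls > 0L & !vapply(mins, rule_satisfied, logical(1), record = record)]
      return(list(decision = "reject_reserved", rules = blocked_by, ledger = ledger))
    }
  }

  pos <- n + 1L
  row <- tibble::tibble(record_id = as.character(record$record_id),
                        position = pos, block = ledger_block_of(spec, pos))
  for (f in qfields) row[[f]] <- as.character(record[[f]])
  ledger$enrolled <- dplyr::bind_rows(ledger$enrolled, row)
  sat <- vapply(spec$rules, rule_satisfied, logical(1), record = record)
  list(decision = "admit",
       rules = vapply(spec$rules, `[[`, character(1), "label")[sat],
       ledger = ledger)
}

# minimum number of future admissions that can cover all shortfalls when
# minimum predicates may overlap: greedy cover over category cells (each
# future admission picks a cell and decrements every rule it satisfies).
min_cover_size <- function(mins, shortfalls) {
  active <- which(shortfalls > 0L)
  if (!length(active)) return(0L)
  cells <- candidate_cells(mins[active])
  sat <- vapply(cells, function(cell) {
    vapply(mins, rule_satisfied, logical(1), record = cell)
  }, logical(length(mins)))
  if (length(mins) == 1L) sat <- matrix(sat, nrow = 1L)
  need <- shortfalls
  total <- 0L
  while (any(need > 0L)) {
    gain <- colSums(sat & matrix(need > 0L, nrow = length(need), ncol = ncol(sat)))
    best <- which.max(gain)
    if (gain[best] == 0L) {
      # no cell helps (cannot happen: each rule's own cell satisfies it)
      total <- total + sum(need)
      break
    }
    hit <- sat[, best] & need > 0L
    k <- min(need[hit])  # take k copies of the best cell at once
    need[hit] <- need[hit] - k
    total <- total + k
  }
  total
}

# all assignments of mentioned values to mentioned fields; each rule's own
# predicate is always among them (unconstrained fields take the rule's
# value or a sentinel "other")
candidate_cells <- function(rules) {
  fields <- unique(unlist(lapply(rules, rule_fields)))
  vals <- lapply(fields, function(f) {
    unique(c(unlist(lapply(rules, function(r) r$when[[f]])), ".other."))
  })
  names(vals) <- fields
  grid <- expand.grid(vals, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

#' Replay a stream of eligible candidates through the quota engine
#'
#' Applies [quota_evaluate()] sequentially (in stream order — screening
#' completion order or enrollment confirmation order, per the spec's
#' `check_time`) until the sample is full or the stream is exhausted. A
#' minimum still unmet at the end is reported as a warning, not an error:
#' an undersupplied recruitment stream is a study-management fact, not a
#' software failure.
#'
#' @param stream tibble of eligible candidates in arrival order, with
#'   `record_id` and all quota fields (a `screen_store` works).
#' @param spec a [quota_spec()].
#' @param reserve_mode passed to [quota_evaluate()].
#' @return list of class `quota_replay`: `ledger`, `decisions` (tibble
#'   `record_id`, `decision`, `rules`, `check_time`), `attainment`
#'   ([summarize_quota()] table), `unmet` (labels of unmet minimums).
#' @export
quota_replay <- function(stream, spec, reserve_mode = c("independent", "exact")) {
  reserve_mode <- match.arg(reserve_mode)
  ledger <- quota_ledger(spec)
  n <- nrow(stream)
  decisions <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- stream[i, , drop = FALSE]
    out <- quota_evaluate(rec, ledger, spec, reserve_mode = reserve_mode)
    ledger <- out$ledger
    decisions[[i]] <- tibble::tibble(
      record_id = as.character(rec$record_id),
      decision = out$decision,
      rules = paste(out$rules, collapse = ";"),
      check_time = spec$check_time
    )
    if (nrow(ledger$enrolled) >= spec$total_n) {
      decisions <- decisions[seq_len(i)]
      break
    }
  }
  decisions <- dplyr::bind_rows(decisions)
  att <- summarize_quota(ledger, spec)
  unmet <- att$label[att$bound == "minimum" & att$achieved_n < att$target]
  if (length(unmet)) {
    warning("unmet minimum(s) at end of stream: ", paste(unmet, collapse = ", "),
            call. = FALSE)
  }
  structure(list(ledger = ledger, decisions = decisions, attainment = att,
                 unmet = unmet),
            class = "quota_replay")
}
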