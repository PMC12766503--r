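# Fixtures and independent oracles, all built in code.

test_schema <- function() {
  screen_schema(
    field_spec("first_name", "identifier", "text"),
    field_spec("last_name", "identifier", "text"),
    field_spec("email", "identifier", "email"),
    field_spec("phone", "identifier", "phone"),
    field_spec("category", "eligibility", "exact")
  )
}

# name AND name, OR email, OR phone; six-month window
test_criteria <- function(window_days = 183) {
  criteria_set(
    list(
      match_criterion("name", c("first_name", "last_name")),
      match_criterion("email", "email"),
      match_criterion("phone", "phone")
    ),
    window_days = window_days
  )
}

# build a store from compact row descriptions
make_store <- function(rows, schema = test_schema(), tz = "UTC") {
  tab <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      record_id = r$id,
      submitted_at = r$at,
      first_name = r$first %||% paste0("fn-", r$id),
      last_name = r$last %||% paste0("ln-", r$id),
      email = r$email %||% paste0(r$id, "@example.com"),
      phone = r$phone %||% NA_character_,
      category = r$category %||% "cpd_1_5"
    )
  }))
  load_records(tab, schema, tz = tz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force duplicate-pair oracle: explicit double loop over
# record pairs using the single-pair predicates, no key grouping.
oracle_pairs <- function(store, cs) {
  n <- nrow(store)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      a <- store[i, , drop = FALSE]
      for (j in (i + 1L):n) {
        b <- store[j, , drop = FALSE]
        labs <- matched_criteria(a, b, cs)
        if (length(labs) && within_window(a, b, cs$window_days)) {
          out[[length(out) + 1L]] <- list(i = i, j = j, labels = sort(labs))
        }
      }
    }
  }
  out
}

# Independent connected components over oracle pairs (hand-rolled
# union-find, no igraph).
oracle_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in pairs) {
    ri <- find(p$i); rj <- find(p$j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  unname(comps[lengths(comps) >= 2L])
}

# Exact minimum number of future admissions covering all minimum-rule
# shortfalls: breadth-first search over shortfall vectors, each step
# admitting one record of any category cell.
oracle_min_cover <- function(rules, shortfalls, cells) {
  key <- function(v) paste(v, collapse = ",")
  seen <- new.env(parent = emptyenv())
  frontier <- list(shortfalls)
  assign(key(shortfalls), TRUE, envir = seen)
  depth <- 0L
  repeat {
    if (any(vapply(frontier, function(v) all(v == 0L), logical(1)))) return(depth)
    depth <- depth + 1L
    if (depth > sum(shortfalls) + 1L) return(depth)  # safety
    nxt <- list()
    for (v in frontier) {
      for (cell in cells) {
        sat <- vapply(rules, function(r) {
          all(vapply(names(r$when), function(f) {
            !is.null(cell[[f]]) && cell[[f]] == r$when[[f]]
          }, logical(1)))
        }, logical(1))
        w <- pmax(0L, v - as.integer(sat))
        k <- key(w)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
  }
}

# candidate stream over given categories, round-robin or sampled
make_candidates <- function(n, categories, seed = NULL, shuffle = TRUE) {
  cat_vec <- rep(categories, length.out = n)
  if (shuffle && !is.null(seed)) {
    cat_vec <- withr::with_seed(seed, sample(cat_vec))
  }
  tibble::tibble(
    record_id = sprintf("C%04d", seq_len(n)),
    category = cat_vec
  )
}
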