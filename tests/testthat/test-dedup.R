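test_that("check_incoming: empty store is clean; matches carry labels and gaps", {
  cs <- test_criteria()
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", phone = "8435550101")
  ))
  rec <- make_store(list(
    list(id = "B", at = "2024-01-11", phone = "(843) 555-0101")
  ))[1, ]
  empty <- store[0, ]
  expect_equal(check_incoming(rec, empty, cs)$decision, "clean")
  fl <- check_incoming(rec, store, cs, mode = "review")
  expect_equal(fl$decision, "needs_review")
  expect_equal(fl$matched$prior_record_id, "A")
  expect_equal(fl$matched$criteria[[1]], "phone")
  expect_equal(fl$matched$gap_days, 10L)
  expect_equal(check_incoming(rec, store, cs, mode = "auto")$decision, "auto_rejected")
})

test_that("a prior match outside the window does not flag", {
  cs <- test_criteria(183)
  # same phone throughout; gaps 10 and 400 days from the first record
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", phone = "8435550101"),
    list(id = "B", at = "2024-01-11", phone = "8435550101"),
    list(id = "C", at = "2025-02-04", phone = "8435550101")
  ))
  # C is 400 days after A and 390 after B: both out of window
  flags <- flag_stream(store, cs)
  expect_equal(flags$decision, c("clean", "needs_review", "clean"))
  # brute-force oracle agrees pair by pair
  expect_length(oracle_pairs(store, cs), 1L)
})

test_that("transitive chains form one set with the earliest member as original", {
  cs <- test_criteria()
  # A-B share email, B-C share phone; A and C share nothing directly
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", email = "x@x.com", phone = "1112223333"),
    list(id = "B", at = "2024-01-10", email = "x@x.com", phone = "4445556666"),
    list(id = "C", at = "2024-02-01", email = "y@x.com", phone = "4445556666")
  ))
  sets <- build_duplicate_sets(store, cs)
  expect_equal(nrow(sets), 1L)
  expect_equal(sets$original_id, "A")
  expect_setequal(sets$entry_ids[[1]], c("B", "C"))
  comps <- oracle_components(nrow(store), oracle_pairs(store, cs))
  expect_equal(length(comps), 1L)
  expect_setequal(store$record_id[comps[[1]]], c("A", "B", "C"))
})

test_that("all-unique stores produce no sets; identical pairs produce one", {
  cs <- test_criteria()
  unique_store <- make_store(list(
    list(id = "A", at = "2024-01-01"), list(id = "B", at = "2024-01-02"),
    list(id = "C", at = "2024-01-03")
  ))
  expect_equal(nrow(build_duplicate_sets(unique_store, cs)), 0L)
  pair <- make_store(list(
    list(id = "P2", at = "2024-01-05", email = "same@x.com"),
    list(id = "P1", at = "2024-01-05", email = "same@x.com")
  ))
  sets <- build_duplicate_sets(pair, cs)
  expect_equal(sets$size, 2L)
  # same timestamp: tie broken by record_id, P1 is the original
  expect_equal(sets$original_id, "P1")
  expect_equal(sets$entry_ids[[1]], "P2")
})

test_that("classification arithmetic: sets {2,3} over 10 records give rate 50.00", {
  cs <- test_criteria()
  rows <- list(
    # set of 2 on email
    list(id = "A1", at = "2024-01-01", email = "s1@x.com"),
    list(id = "A2", at = "2024-01-02", email = "s1@x.com"),
    # set of 3 on phone
    list(id = "B1", at = "2024-01-01", phone = "1112223333"),
    list(id = "B2", at = "2024-01-03", phone = "1112223333"),
    list(id = "B3", at = "2024-01-09", phone = "1112223333")
  )
  singles <- lapply(1:5, function(k) list(id = paste0("S", k), at = "2024-02-01"))
  store <- make_store(c(rows, singles))
  sets <- build_duplicate_sets(store, cs)
  res <- classify_duplicates(store, sets, cs)
  expect_equal(res$n_original_duplicates, 2L)
  expect_equal(res$n_duplicate_entries, 3L)
  expect_equal(res$n_duplicate_records, 5L)
  expect_equal(res$duplicate_rate_pct, 50.00)
  expect_equal(res$total_records, 10L)
})

test_that("gap categories partition entries by gap to the nearest earlier match", {
  cs <- test_criteria(365)
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", email = "s@x.com"),
    list(id = "B", at = "2024-01-01", email = "s@x.com"),   # gap 0 -> same_day
    list(id = "C", at = "2024-01-08", email = "s@x.com"),   # 7 from B -> within_week
    list(id = "D", at = "2024-02-08", email = "s@x.com"),   # 31 from C -> within_month
    list(id = "E", at = "2024-03-19", email = "s@x.com")    # 40 from D -> over_month
  ))
  res <- classify_duplicates(store, build_duplicate_sets(store, cs), cs)
  ent <- res$entries
  expect_equal(ent$gap_category[match(c("B", "C", "D", "E"), ent$record_id)],
               c("same_day", "within_week", "within_month", "over_month"))
  expect_equal(sum(res$gap_counts), res$n_duplicate_entries)
})

test_that("intent profile reports kept criterion fields and changed identifiers", {
  cs <- test_criteria()
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", first = "jo", last = "kim",
         email = "j@x.com", phone = "1112223333"),
    # same-day exact copy: nothing changed
    list(id = "B", at = "2024-01-01", first = "jo", last = "kim",
         email = "j@x.com", phone = "1112223333"),
    # same-day, name changed but email+phone kept: identity disguise pattern
    list(id = "C", at = "2024-01-01", first = "pat", last = "lee",
         email = "j@x.com", phone = "1112223333")
  ))
  res <- classify_duplicates(store, build_duplicate_sets(store, cs), cs)
  prof <- intent_profile(res)
  b <- prof[prof$record_id == "B", ]
  expect_equal(b$gap_category, "same_day")
  expect_length(b$changed_fields[[1]], 0L)
  c_ <- prof[prof$record_id == "C", ]
  expect_equal(c_$gap_category, "same_day")
  expect_setequal(c_$changed_fields[[1]], c("first_name", "last_name"))
  expect_true(all(c("email", "phone") %in% c_$kept_fields[[1]]))
})

test_that("pair engine agrees with the brute-force oracle on random stores", {
  cs <- test_criteria()
  withr::with_seed(97, {
    for (k in 1:8) {
      n <- sample(5:25, 1)
      rows <- lapply(seq_len(n), function(i) {
        list(
          id = sprintf("R%02d", i),
          at = format(as.Date("2024-01-01") + sample(0:400, 1)),
          first = sample(c("jo", "al", "max"), 1),
          last = sample(c("kim", "lee"), 1),
          email = sample(sprintf("e%d@x.com", 1:6), 1),
          phone = sample(c(sprintf("111222%04d", 1:5), NA), 1)
        )
      })
      store <- make_store(rows)
      got <- duplicate_pairs(store, cs)
      want <- oracle_pairs(store, cs)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        want_keys <- vapply(want, function(p) paste(p$i, p$j), character(1))
        got_keys <- paste(got$i, got$j)
        expect_setequal(got_keys, want_keys)
        for (m in seq_along(want)) {
          gi <- which(got_keys == want_keys[m])
          expect_setequal(got$labels[[gi]], want[[m]]$labels)
        }
      }
      comps <- oracle_components(n, want)
      sets <- build_duplicate_sets(store, cs)
      expect_equal(nrow(sets), length(comps))
    }
  })
})

test_that("input row order does not affect sets, originals, or counts", {
  cs <- test_criteria()
  p <- sim_params(n_identities = 40, seed = 303)
  st <- generate_stream(p)
  base <- dedup_screens(load_records(st$records, st$schema), cs)
  withr::with_seed(7, {
    for (k in 1:3) {
      perm <- st$records[sample(nrow(st$records)), ]
      res <- dedup_screens(load_records(perm, st$schema), cs)
      expect_equal(res$result$n_duplicate_records, base$result$n_duplicate_records)
      expect_equal(res$sets$original_id, base$sets$original_id)
      expect_equal(lapply(res$sets$member_ids, sort), lapply(base$sets$member_ids, sort))
      expect_equal(res$result$gap_counts, base$result$gap_counts)
    }
  })
})

test_that("a flagged record still joins the comparison chain", {
  cs <- test_criteria()
  # B matches A; C matches only B (email changed after A, phone changed after B)
  store <- make_store(list(
    list(id = "A", at = "2024-01-01", email = "a@x.com", phone = "1112223333"),
    list(id = "B", at = "2024-01-02", email = "b@x.com", phone = "1112223333"),
    list(id = "C", at = "2024-01-03", email = "b@x.com", phone = "9998887777")
  ))
  flags <- flag_stream(store, cs)
  cfl <- flags[flags$record_id == "C", ]
  expect_equal(cfl$decision, "needs_review")
  expect_equal(cfl$matched[[1]]$prior_record_id, "B")
})
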