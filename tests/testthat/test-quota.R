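cand <- function(id, ...) tibble::tibble(record_id = id, ...)

coast_spec <- function(check_time = "enrollment") {
  quota_spec(
    total_n = 143,
    rules = list(
      quota_rule("cpd-1-5-min", c(category = "cpd_1_5"), "minimum", 23),
      quota_rule("cpd-6-10-min", c(category = "cpd_6_10"), "minimum", 23),
      quota_rule("cpd-11-15-min", c(category = "cpd_11_15"), "minimum", 23),
      quota_rule("cpd-16up-min", c(category = "cpd_16_plus"), "minimum", 23),
      quota_rule("quit-30-min", c(category = "quit_30"), "minimum", 36)
    ),
    check_time = check_time
  )
}

test_that("effective counts: percent minimums ceil, percent maximums floor, counts pass through", {
  expect_equal(effective_count(quota_rule("w", c(sex = "f"), "minimum", 25, "percent"), 143), 36L)
  expect_equal(effective_count(quota_rule("m", c(sex = "m"), "maximum", 50, "percent"), 7), 3L)
  expect_equal(effective_count(quota_rule("c", c(sex = "f"), "minimum", 23, "count"), 999), 23L)
  expect_equal(effective_count(quota_rule("w", c(sex = "f"), "minimum", 25, "percent"), 8), 2L)
})

test_that("a maximum rejects the candidate that would exceed it", {
  spec <- quota_spec(6, list(quota_rule("male-max", c(sex = "male"), "maximum", 2)))
  led <- quota_ledger(spec)
  for (i in 1:2) {
    out <- quota_evaluate(cand(paste0("M", i), sex = "male"), led)
    expect_equal(out$decision, "admit")
    led <- out$ledger
  }
  out <- quota_evaluate(cand("M3", sex = "male"), led)
  expect_equal(out$decision, "reject_maximum")
  expect_equal(out$rules, "male-max")
  # non-males still welcome
  expect_equal(quota_evaluate(cand("F1", sex = "female"), led)$decision, "admit")
})

test_that("empty ledger admits any candidate under a satisfiable spec", {
  spec <- coast_spec()
  out <- quota_evaluate(cand("X", category = "cpd_1_5"), quota_ledger(spec))
  expect_equal(out$decision, "admit")
})

test_that("reserved-slot logic holds the last open slots for an unmet minimum", {
  spec <- quota_spec(8, list(quota_rule("women-min", c(sex = "f"), "minimum", 2)))
  led <- quota_ledger(spec)
  for (i in 1:6) led <- quota_evaluate(cand(paste0("N", i), sex = "m"), led)$ledger
  out <- quota_evaluate(cand("N7", sex = "m"), led)
  expect_equal(out$decision, "reject_reserved")
  expect_equal(out$rules, "women-min")
  out_w <- quota_evaluate(cand("W1", sex = "f"), led)
  expect_equal(out_w$decision, "admit")
  # brute-force completion check: from each hypothetical state, can the
  # remaining open slots still reach the 2-women minimum?
  can_finish <- function(led) {
    (sum(led$enrolled$sex == "f") + (8 - nrow(led$enrolled))) >= 2
  }
  hypo_m <- led
  hypo_m$enrolled <- dplyr::bind_rows(
    hypo_m$enrolled, tibble::tibble(record_id = "N7", position = 7L,
                                    block = 0L, sex = "m"))
  expect_false(can_finish(hypo_m))       # admitting the 7th man dooms the quota
  expect_true(can_finish(out_w$ledger))  # admitting the woman keeps it reachable
})

test_that("missing quota field is an error, not a rejection", {
  spec <- coast_spec()
  expect_error(
    quota_evaluate(cand("X", category = NA_character_), quota_ledger(spec)),
    class = "screensift_input_error"
  )
})

test_that("full sample rejects with reject_full", {
  spec <- quota_spec(2, list())
  led <- quota_ledger(spec)
  led <- quota_evaluate(cand("A", sex = "f"), led)$ledger
  led <- quota_evaluate(cand("B", sex = "f"), led)$ledger
  expect_equal(quota_evaluate(cand("C", sex = "f"), led)$decision, "reject_full")
})

test_that("provably infeasible minimums are rejected at construction", {
  expect_error(
    quota_spec(10, list(
      quota_rule("a", c(sex = "f"), "minimum", 6),
      quota_rule("b", c(sex = "m"), "minimum", 6)
    )),
    "infeasible"
  )
  # overlapping predicates are not provably exclusive: accepted
  expect_s3_class(
    quota_spec(10, list(
      quota_rule("a", c(sex = "f"), "minimum", 6),
      quota_rule("b", c(area = "rural"), "minimum", 6)
    )),
    "quota_spec"
  )
})

test_that("percent and count rules with equal effective counts decide identically", {
  mk_stream <- function() {
    withr::with_seed(21, {
      tibble::tibble(
        record_id = sprintf("C%03d", 1:120),
        sex = sample(c("f", "m"), 120, replace = TRUE, prob = c(0.3, 0.7))
      )
    })
  }
  spec_pct <- quota_spec(40, list(quota_rule("w", c(sex = "f"), "minimum", 25, "percent")))
  spec_cnt <- quota_spec(40, list(quota_rule("w", c(sex = "f"), "minimum", 10, "count")))
  expect_equal(effective_count(spec_pct$rules[[1]], 40),
               effective_count(spec_cnt$rules[[1]], 40))
  r1 <- suppressWarnings(quota_replay(mk_stream(), spec_pct))
  r2 <- suppressWarnings(quota_replay(mk_stream(), spec_cnt))
  expect_equal(r1$decisions$decision, r2$decisions$decision)
  expect_equal(r1$ledger$enrolled$record_id, r2$ledger$enrolled$record_id)
})

test_that("block_size = total_n replays identically to no blocks", {
  stream <- withr::with_seed(31, tibble::tibble(
    record_id = sprintf("C%03d", 1:200),
    category = sample(names(sim_categories()), 200, replace = TRUE)
  ))
  rules <- list(
    quota_rule("q", c(category = "quit_30"), "minimum", 12),
    quota_rule("h", c(category = "cpd_16_plus"), "maximum", 10)
  )
  no_blocks <- quota_spec(48, rules)
  one_block <- quota_spec(48, rules, block_size = 48)
  r1 <- suppressWarnings(quota_replay(stream, no_blocks))
  r2 <- suppressWarnings(quota_replay(stream, one_block))
  expect_equal(r1$decisions, r2$decisions)
  expect_equal(r1$attainment$achieved_n, r2$attainment$achieved_n)
})

test_that("blocked mode enforces per-block minima and maxima in completed blocks", {
  stream <- withr::with_seed(41, tibble::tibble(
    record_id = sprintf("C%03d", 1:300),
    sex = sample(c("f", "m"), 300, replace = TRUE)
  ))
  spec <- quota_spec(30, list(
    quota_rule("w-min", c(sex = "f"), "minimum", 4),
    quota_rule("m-max", c(sex = "m"), "maximum", 6)
  ), block_size = 10)
  rp <- suppressWarnings(quota_replay(stream, spec))
  enr <- rp$ledger$enrolled
  for (blk in unique(enr$block)) {
    rows <- enr[enr$block == blk, ]
    if (nrow(rows) == 10) {  # completed block
      expect_gte(sum(rows$sex == "f"), 4)
      expect_lte(sum(rows$sex == "m"), 6)
    }
  }
})

test_that("no ledger state ever violates a maximum and never exceeds total_n", {
  withr::with_seed(51, {
    for (k in 1:5) {
      total <- sample(10:30, 1)
      max_amt <- sample(2:6, 1)
      spec <- quota_spec(total, list(
        quota_rule("m-max", c(sex = "m"), "maximum", max_amt)
      ))
      stream <- tibble::tibble(
        record_id = sprintf("C%03d", 1:80),
        sex = sample(c("f", "m"), 80, replace = TRUE)
      )
      led <- quota_ledger(spec)
      for (i in seq_len(nrow(stream))) {
        led <- quota_evaluate(stream[i, ], led)$ledger
        expect_lte(sum(led$enrolled$sex == "m"), max_amt)
        expect_lte(nrow(led$enrolled), total)
      }
    }
  })
})

test_that("oversupplied streams meet all exclusive minimums in any arrival order", {
  spec <- coast_spec()
  withr::with_seed(61, {
    for (k in 1:5) {
      stream <- make_candidates(500, names(sim_categories()),
                                seed = sample.int(1e6, 1))
      rp <- quota_replay(stream, spec)
      att <- rp$attainment
      expect_true(all(att$achieved_n >= att$target))
      expect_equal(nrow(rp$ledger$enrolled), 143L)
      expect_length(rp$unmet, 0L)
    }
  })
})

test_that("a stream with no members of a minimum category warns as unmet", {
  spec <- quota_spec(6, list(quota_rule("w", c(sex = "f"), "minimum", 2)))
  stream <- tibble::tibble(record_id = sprintf("C%d", 1:4), sex = "m")
  expect_warning(rp <- quota_replay(stream, spec), "unmet minimum.*w")
  expect_equal(rp$unmet, "w")
})

test_that("exact reserve mode admits where independent over-reserves on overlap", {
  spec <- quota_spec(4, list(
    quota_rule("women", c(sex = "f"), "minimum", 2),
    quota_rule("rural", c(area = "rural"), "minimum", 2)
  ))
  led <- quota_ledger(spec)
  urban_man <- cand("X", sex = "m", area = "urban")
  # independent mode: 3 open slots after admit < 2+2 shortfall -> reject
  expect_equal(quota_evaluate(urban_man, led, reserve_mode = "independent")$decision,
               "reject_reserved")
  # exact mode: two rural women cover both minima -> admit
  expect_equal(quota_evaluate(urban_man, led, reserve_mode = "exact")$decision,
               "admit")
})

test_that("greedy cover matches brute-force BFS on small overlapping minima", {
  withr::with_seed(71, {
    for (k in 1:10) {
      rules <- list(
        quota_rule("a", c(sex = "f"), "minimum", sample(1:3, 1)),
        quota_rule("b", c(area = "rural"), "minimum", sample(1:3, 1)),
        quota_rule("c", c(sex = "f", area = "rural"), "minimum", sample(1:2, 1))
      )
      shortfalls <- vapply(rules, function(r) sample(0:3, 1), integer(1))
      cells <- screensift:::candidate_cells(rules)
      got <- screensift:::min_cover_size(rules, shortfalls)
      want <- oracle_min_cover(rules, shortfalls, cells)
      expect_equal(got, want, info = paste("shortfalls", paste(shortfalls, collapse = ",")))
    }
  })
})

test_that("ledger counts equal tallies recomputed from scratch", {
  spec <- coast_spec()
  stream <- make_candidates(400, names(sim_categories()), seed = 81)
  rp <- quota_replay(stream, spec)
  att <- rp$attainment
  for (r in spec$rules) {
    recount <- sum(rp$ledger$enrolled$category == r$when$category)
    expect_equal(att$achieved_n[att$label == r$label], recount)
  }
  expect_equal(sum(att$achieved_n), nrow(rp$ledger$enrolled))
})
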