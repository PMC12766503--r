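# Synthetic screening streams with ground truth. The generator emulates
# the three populations a remote screening survey receives: honest unique
# applicants (one submission), accidental resubmitters (exact copies,
# typically weeks apart), and intentional fraudsters (rapid resubmissions
# that mutate a subset of identifier fields to dodge exact matching).
# All identifiers are fabricated; no real personal data appears anywhere.

SIM_FIRST <- c(
  "alex", "amara", "ben", "brooke", "carlos", "casey", "dana", "devon",
  "elena", "eli", "farah", "finn", "grace", "hakim", "ida", "ivan",
  "jada", "jonas", "kira", "liam", "lucia", "mara", "nico", "nora",
  "omar", "priya", "quinn", "ravi", "rosa", "sam", "sofia", "tariq",
  "uma", "vera", "wes", "ximena", "yara", "zane", "amir", "bella",
  "cole", "daria", "emil", "freya", "gus", "hana", "iris", "jude",
  "kai", "lena", "milo", "nina", "otto", "pia", "reed", "sana",
  "theo", "una", "vik", "wren", "yusuf", "zoe", "arlo", "bree"
)
SIM_LAST <- c(
  "adams", "baker", "castillo", "davis", "edwards", "flores", "garcia",
  "hopkins", "ibrahim", "jackson", "kim", "lopez", "martin", "nguyen",
  "ortiz", "patel", "quigley", "rivera", "singh", "torres", "ueda",
  "vargas", "walker", "xu", "young", "zhang", "bennett", "cohen",
  "delgado", "evans", "fischer", "grant", "hayes", "ito", "jordan",
  "keller", "lund", "mori", "novak", "osman", "price", "reyes",
  "sato", "tran", "underwood", "vega", "weiss", "yilmaz", "zuniga",
  "abbott", "brennan", "chapman", "dunn", "eaton", "farrell", "gibbs"
)
SIM_DOMAINS <- c("example.com", "example.net", "example.org", "mail.example")

#' Default simulated-stream categories
#'
#' Five smoking-status bins matching a cessation-study screener: four
#' cigarettes-per-day bins plus recently quit. Used as the default
#' `category_mix` (uniform).
#' @return named numeric vector of category probabilities.
#' @export
sim_categories <- function() {
  setNames(rep(0.2, 5),
           c("cpd_1_5", "cpd_6_10", "cpd_11_15", "cpd_16_plus", "quit_30"))
}

#' Schema of the simulated screening stream
#'
#' Four identifier fields (first/last name, email, phone) and one
#' eligibility category field (`category`).
#' @return a [screen_schema()].
#' @export
sim_schema <- function() {
  screen_schema(
    field_spec("first_name", "identifier", "text"),
    field_spec("last_name", "identifier", "text"),
    field_spec("email", "identifier", "email"),
    field_spec("phone", "identifier", "phone"),
    field_spec("category", "eligibility", "exact")
  )
}

#' Simulation parameters
#'
#' Defaults encode the stream conditions observed in real remote
#' cessation screeners: fraudsters resubmit mostly the same day (mass
#' 0.72 at a zero-day gap, remaining gaps geometric with mean 7 days) and
#' up to 15 times with a geometric tail; accidental resubmitters come
#' back after a typically long delay (mean 45 days, often over a month).
#'
#' @param n_identities number of distinct people in the stream.
#' @param fraud_fraction fraction of identities that are fraudsters.
#' @param mistake_fraction fraction that accidentally resubmit once.
#' @param fraud_resubmissions integer range `c(min, max)` of TOTAL
#'   submissions per fraud identity (>= 2); counts decay geometrically
#'   (ratio `resub_decay`) across the range.
#' @param resub_decay geometric decay ratio for submission counts.
#' @param mutation_probs named per-field probability that a fraudster
#'   changes that identifier on each resubmission. Mutated values are
#'   drawn fresh and never revert, so resubmission chains only ever match
#'   adjacent links.
#' @param fraud_gap_model,mistake_gap_model `list(p_zero=, mean_positive=)`:
#'   probability of a same-day gap, and the mean of the geometric positive
#'   gap (days).
#' @param category_mix named probability vector over category values.
#' @param accrual_days length of the accrual window (first submissions
#'   uniform over it).
#' @param seed integer seed; the whole stream is a deterministic function
#'   of the parameters.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_identities = 300,
                       fraud_fraction = 0.15,
                       mistake_fraction = 0.10,
                       fraud_resubmissions = c(2L, 15L),
                       resub_decay = 0.55,
                       mutation_probs = c(first_name = 0.5, last_name = 0.5,
                                          email = 0.3, phone = 0.3),
                       fraud_gap_model = list(p_zero = 0.72, mean_positive = 7),
                       mistake_gap_model = list(p_zero = 0.05, mean_positive = 45),
                       category_mix = sim_categories(),
                       accrual_days = 365,
                       seed = 1L) {
  stopifnot(
    n_identities >= 1,
    fraud_fraction >= 0, fraud_fraction <= 1,
    mistake_fraction >= 0, mistake_fraction <= 1,
    fraud_fraction + mistake_fraction <= 1,
    length(fraud_resubmissions) == 2L,
    fraud_resubmissions[1] >= 2L,
    fraud_resubmissions[2] >= fraud_resubmissions[1],
    all(mutation_probs >= 0), all(mutation_probs <= 1),
    fraud_gap_model$p_zero >= 0, fraud_gap_model$p_zero <= 1,
    mistake_gap_model$p_zero >= 0, mistake_gap_model$p_zero <= 1,
    all(category_mix >= 0), abs(sum(category_mix) - 1) < 1e-8,
    accrual_days >= 1
  )
  structure(
    list(n_identities = as.integer(n_identities),
         fraud_fraction = fraud_fraction,
         mistake_fraction = mistake_fraction,
         fraud_resubmissions = as.integer(fraud_resubmissions),
         resub_decay = resub_decay,
         mutation_probs = mutation_probs,
         fraud_gap_model = fraud_gap_model,
         mistake_gap_model = mistake_gap_model,
         category_mix = category_mix,
         accrual_days = accrual_days,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

draw_gaps <- function(n, model) {
  zero <- runif(n) < model$p_zero
  pos <- 1L + rgeom(n, prob = 1 / model$mean_positive)
  ifelse(zero, 0L, pos)
}

# a pool-backed unique-value factory: draws until the value is unseen
new_unique <- function(used, draw) {
  repeat {
    v <- draw()
    if (!v %in% used) return(v)
  }
}

draw_phone <- function() {
  paste0(sample(2:9, 1), paste(sample(0:9, 9, replace = TRUE), collapse = ""))
}

#' Generate a synthetic screening stream with ground truth
#'
#' Deterministic given the parameters (including seed). Identifier values
#' are unique across identities by construction; fraud resubmissions
#' mutate each identifier independently with its per-field probability,
#' drawing fresh values that never collide with any existing identity or
#' earlier mutation.
#'
#' @param params a [sim_params()].
#' @return list: `records` — raw submission tibble (`record_id`,
#'   `submitted_at`, identifier fields, `category`) in the CSV dialect
#'   [load_records()] reads; `truth` — tibble (`record_id`, `identity_id`,
#'   `label` honest/mistake/fraud, `submission_index`); `schema` —
#'   [sim_schema()].
#' @export
generate_stream <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    n_id <- params$n_identities
    n_fraud <- round(params$fraud_fraction * n_id)
    n_mistake <- round(params$mistake_fraction * n_id)
    labels <- sample(c(rep("fraud", n_fraud), rep("mistake", n_mistake),
                       rep("honest", n_id - n_fraud - n_mistake)))

    used_email <- character(0); used_phone <- character(0); used_name <- character(0)
    identities <- vector("list", n_id)
    for (k in seq_len(n_id)) {
      nm <- new_unique(used_name, function() {
        paste(sample(SIM_FIRST, 1), sample(SIM_LAST, 1))
      })
      used_name <- c(used_name, nm)
      parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
      em <- new_unique(used_email, function() {
        paste0(parts[1], ".", parts[2], sample(100:9999, 1), "@",
               sample(SIM_DOMAINS, 1))
      })
      used_email <- c(used_email, em)
      ph <- new_unique(used_phone, draw_phone)
      used_phone <- c(used_phone, ph)
      identities[[k]] <- list(
        first_name = parts[1], last_name = parts[2], email = em, phone = ph,
        category = sample(names(params$category_mix), 1,
                          prob = params$category_mix)
      )
    }

    rng <- params$fraud_resubmissions
    ks <- rng[1]:rng[2]
    sub_probs <- params$resub_decay^(ks - rng[1])
    base <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

    rec_rows <- list(); truth_rows <- list(); ridx <- 0L
    for (k in seq_len(n_id)) {
      lab <- labels[k]
      n_sub <- switch(lab,
        honest = 1L,
        mistake = 2L,
        fraud = sample(ks, 1, prob = sub_probs)
      )
      gaps <- if (n_sub > 1L) {
        model <- if (lab == "fraud") params$fraud_gap_model else params$mistake_gap_model
        draw_gaps(n_sub - 1L, model)
      } else integer(0)
      t0 <- base + runif(1, 0, params$accrual_days) * 86400
      times <- t0 + c(0, cumsum(gaps)) * 86400 + (seq_len(n_sub) - 1L) * 600
      vals <- identities[[k]]
      own_names <- paste(vals$first_name, vals$last_name)
      for (s in seq_len(n_sub)) {
        if (s > 1L && lab == "fraud") {
          name_changed <- FALSE
          for (f in names(params$mutation_probs)) {
            if (runif(1) < params$mutation_probs[[f]]) {
              if (f == "first_name") {
                vals$first_name <- sample(SIM_FIRST, 1)
                name_changed <- TRUE
              } else if (f == "last_name") {
                vals$last_name <- sample(SIM_LAST, 1)
                name_changed <- TRUE
              } else if (f == "email") {
                vals$email <- new_unique(used_email, function() {
                  paste0(sample(SIM_FIRST, 1), ".", sample(SIM_LAST, 1),
                         sample(100:9999, 1), "@", sample(SIM_DOMAINS, 1))
                })
                used_email <- c(used_email, vals$email)
              } else if (f == "phone") {
                vals$phone <- new_unique(used_phone, draw_phone)
                used_phone <- c(used_phone, vals$phone)
              }
            }
          }
          if (name_changed) {
            # a mutated full name must be fresh: it may collide neither with
            # another identity nor with this identity's own earlier names
            nm <- paste(vals$first_name, vals$last_name)
            while (nm %in% used_name || nm %in% own_names) {
              vals$first_name <- sample(SIM_FIRST, 1)
              vals$last_name <- sample(SIM_LAST, 1)
              nm <- paste(vals$first_name, vals$last_name)
            }
            used_name <- c(used_name, nm)
            own_names <- c(own_names, nm)
          }
        }
        ridx <- ridx + 1L
        rec_rows[[ridx]] <- tibble::tibble(
          record_id = sprintf("R%05d", ridx),
          submitted_at = format(times[s], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
          first_name = vals$first_name, last_name = vals$last_name,
          email = vals$email, phone = vals$phone, category = vals$category
        )
        truth_rows[[ridx]] <- tibble::tibble(
          record_id = sprintf("R%05d", ridx),
          identity_id = sprintf("I%04d", k),
          label = lab,
          submission_index = s
        )
      }
    }
    records <- dplyr::bind_rows(rec_rows)
    truth <- dplyr::bind_rows(truth_rows)
    ord <- order(records$submitted_at, records$record_id)
    list(records = records[ord, ], truth = truth[ord, ], schema = sim_schema())
  })
}

#' Precision and recall of duplicate flags against simulator truth
#'
#' A "true duplicate entry" is any submission after an identity's first
#' (submission_index >= 2, mistake or fraud). Recall is the fraction of
#' those the detector flagged; precision the fraction of flagged records
#' that are true duplicate entries; `honest_flagged` counts false flags
#' on honest one-off applicants. With no flags at all, precision is
#' defined as 1 (nothing asserted, nothing wrong).
#'
#' @param flags output of [flag_stream()] (or any tibble with `record_id`
#'   and `decision`).
#' @param truth the simulator's truth tibble for the same stream.
#' @return list: `recall`, `precision`, `honest_flagged`,
#'   `n_true_entries`, `n_flagged`.
#' @export
truth_confusion <- function(flags, truth) {
  stopifnot(all(flags$record_id %in% truth$record_id))
  flagged <- flags$record_id[flags$decision != "clean"]
  entries <- truth$record_id[truth$submission_index >= 2L]
  honest <- truth$record_id[truth$label == "honest"]
  tp <- length(intersect(flagged, entries))
  list(
    recall = if (length(entries)) tp / length(entries) else 1,
    precision = if (length(flagged)) tp / length(flagged) else 1,
    honest_flagged = length(intersect(flagged, honest)),
    n_true_entries = length(entries),
    n_flagged = length(flagged)
  )
}
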