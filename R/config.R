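# Project configuration: one human-editable YAML file declaring the
# schema, the duplicate-flagging criteria + window, the decision mode, the
# optional quota specification, the study timezone and the simulation
# seed. Example configs ship under inst/extdata/.

#' Load and validate a project configuration file
#'
#' All cross-references are resolved at load time (criterion and quota
#' fields must exist in the schema; the quota feasibility pre-check runs)
#' and every problem found is reported at once, naming the offending key.
#'
#' @param path path to the YAML configuration file.
#' @return list of class `project_config`: `schema` ([screen_schema()]),
#'   `criteria_set` ([criteria_set()]), `dedup_mode`, `quota_spec`
#'   ([quota_spec()] or NULL), `timezone`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  schema <- NULL
  if (is.null(raw$schema) || !length(raw$schema)) {
    note("schema: at least one field is required")
  } else {
    schema <- tryCatch({
      specs <- lapply(raw$schema, function(f) {
        field_spec(f$name %||% "", f$role %||% "other", f$normalizer %||% "exact")
      })
      do.call(screen_schema, specs)
    }, error = function(e) { note(paste0("schema: ", conditionMessage(e))); NULL })
  }

  cs <- NULL
  if (is.null(raw$criteria)) {
    note("criteria: section is required")
  } else {
    cs <- tryCatch({
      rules <- lapply(raw$criteria$rules, function(r) {
        match_criterion(r$label %||% paste(unlist(r$fields), collapse = "+"),
                        unlist(r$fields))
      })
      criteria_set(rules, raw$criteria$window_days %||% 183L, schema = schema)
    }, error = function(e) { note(paste0("criteria: ", conditionMessage(e))); NULL })
  }

  dedup_mode <- raw$dedup_mode %||% "review"
  if (!dedup_mode %in% c("review", "auto")) {
    note("dedup_mode: must be 'review' or 'auto'")
  }

  qspec <- NULL
  if (!is.null(raw$quota)) {
    qspec <- tryCatch({
      rules <- lapply(raw$quota$rules, function(r) {
        quota_rule(r$label %||% "", r$when,
                   bound = r$bound %||% "minimum",
                   amount = r$amount, kind = r$kind %||% "count")
      })
      quota_spec(raw$quota$total_n, rules,
                 block_size = raw$quota$block_size,
                 check_time = raw$quota$check_time %||% "screening",
                 schema = schema)
    }, error = function(e) { note(paste0("quota: ", conditionMessage(e))); NULL })
  }

  tz <- raw$timezone %||% "UTC"
  if (!tz %in% OlsonNames() && tz != "UTC") note(paste0("timezone: unknown zone '", tz, "'"))

  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) note("seed: must be a single integer")

  if (length(errs)) {
    abort_config(paste0("invalid configuration:\n  - ", paste(errs, collapse = "\n  - ")))
  }
  structure(
    list(schema = schema, criteria_set = cs, dedup_mode = dedup_mode,
         quota_spec = qspec, timezone = tz, seed = as.integer(seed)),
    class = "project_config"
  )
}

#' Validate a configuration file, returning problems instead of erroring
#'
#' @param path path to the YAML configuration file.
#' @return character vector of problems; empty when the file is valid.
#' @export
cmd_validate <- function(path) {
  tryCatch({
    load_config(path)
    character(0)
  }, error = function(e) {
    msgs <- strsplit(conditionMessage(e), "\n  - ", fixed = TRUE)[[1]]
    msgs <- sub("^invalid configuration:\\s*$", "", msgs)
    msgs[nzchar(msgs)]
  })
}

#' Run duplicate detection from a config and a records CSV
#'
#' Reads and normalizes the records, runs streaming flags, transitive
#' sets and classification, and writes flags.csv, duplicate_sets.csv and
#' dedup_summary.json to `out_dir`. Nothing is written if any input is
#' malformed.
#'
#' @param config_path path to the YAML configuration.
#' @param records_csv path to the screening export CSV.
#' @param out_dir output directory.
#' @return invisibly, the [dedup_screens()] result.
#' @export
cmd_dedup <- function(config_path, records_csv, out_dir) {
  cfg <- load_config(config_path)
  store <- read_screens(records_csv, cfg$schema, tz = cfg$timezone)
  res <- dedup_screens(store, cfg$criteria_set, mode = cfg$dedup_mode)
  write_dedup_outputs(res, out_dir)
  invisible(res)
}

#' Replay quota decisions from a config and an eligible-candidates CSV
#'
#' Candidates are replayed in CSV (arrival) order. Writes
#' quota_decisions.csv and quota_attainment.csv to `out_dir`.
#'
#' @inheritParams cmd_dedup
#' @param candidates_csv CSV of eligible candidates (same dialect as the
#'   screening export).
#' @param reserve_mode passed to [quota_replay()].
#' @return invisibly, the [quota_replay()] result.
#' @export
cmd_quota <- function(config_path, candidates_csv, out_dir,
                      reserve_mode = "independent") {
  cfg <- load_config(config_path)
  if (is.null(cfg$quota_spec)) abort_config("cmd_quota: config has no quota section")
  store <- read_screens(candidates_csv, cfg$schema, tz = cfg$timezone)
  res <- quota_replay(store, cfg$quota_spec, reserve_mode = reserve_mode)
  write_quota_outputs(res, out_dir)
  invisible(res)
}

#' Generate a synthetic screening stream from a config
#'
#' Uses the config's seed (overridable) and writes records.csv plus
#' truth.csv to `out_dir`. The records CSV is accepted unchanged by
#' [cmd_dedup()] and [cmd_quota()] under the shipped example schema.
#'
#' @inheritParams cmd_dedup
#' @param params optional [sim_params()]; defaults to `sim_params(seed =
#'   <config seed>)`.
#' @return invisibly, the [generate_stream()] result.
#' @export
cmd_simulate <- function(config_path, out_dir, params = NULL) {
  cfg <- load_config(config_path)
  if (is.null(params)) params <- sim_params(seed = cfg$seed)
  stream <- generate_stream(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(stream$records, file.path(out_dir, "records.csv"))
  readr::write_csv(stream$truth, file.path(out_dir, "truth.csv"))
  invisible(stream)
}
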