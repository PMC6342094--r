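# Reading fitness records, scenario configurations, and writing reports.

#' Read individual fitness records from CSV
#'
#' Reads and validates a comma-separated file of individual fitness records
#' with header columns `line_id`, `sex`, `block`, `individual`, `fitness`,
#' and optionally `infected` (0/1/TRUE/FALSE/NA). Sex codes `M`/`F` (also
#' accepted case-insensitively, and as `male`/`female`) are normalized to
#' `"M"`/`"F"`. Rows with missing fitness are dropped with a message; any
#' other malformed value is an error that names the offending data row.
#'
#' @param path Path to the CSV file.
#'
#' @return A tibble of fitness records (see [generate_isolines()] for the
#'   schema).
#'
#' @export
read_fitness_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # read everything as character; typed validation below gives row numbers
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("line_id", "sex", "block", "individual", "fitness")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(basename(path), " is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  sex <- dplyr::case_match(
    toupper(raw$sex),
    c("M", "MALE") ~ "M",
    c("F", "FEMALE") ~ "F",
    .default = NA_character_
  )
  bad <- which(!is.na(raw$sex) & is.na(sex))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown sex code \"%s\" on data row %d of %s.",
      raw$sex[bad[1]], bad[1], basename(path)
    ))
  }
  fitness <- suppressWarnings(as.numeric(raw$fitness))
  bad <- which(!is.na(raw$fitness) & is.na(fitness))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-numeric fitness \"%s\" on data row %d of %s.",
      raw$fitness[bad[1]], bad[1], basename(path)
    ))
  }
  out <- tibble::tibble(
    line_id = raw$line_id,
    sex = sex,
    block = raw$block,
    individual = raw$individual,
    fitness = fitness
  )
  if ("infected" %in% names(raw)) {
    inf <- dplyr::case_match(
      toupper(raw$infected),
      c("1", "TRUE", "T") ~ TRUE,
      c("0", "FALSE", "F") ~ FALSE,
      .default = NA
    )
    bad <- which(!is.na(raw$infected) & is.na(inf))
    if (length(bad) > 0) {
      abort(sprintf(
        "unreadable infected flag \"%s\" on data row %d of %s.",
        raw$infected[bad[1]], bad[1], basename(path)
      ))
    }
    out$infected <- inf
  }
  n_missing <- sum(is.na(out$fitness))
  if (n_missing > 0) {
    inform(sprintf(
      "dropped %d record(s) with missing fitness from %s.",
      n_missing, basename(path)
    ))
    out <- out[!is.na(out$fitness), , drop = FALSE]
  }
  out
}

#' Write fitness records to CSV
#'
#' Inverse of [read_fitness_csv()]: writes the record columns (plus
#' `fitness_z` if present) as a comma-separated, UTF-8 file with header and
#' `NA` for missing values.
#'
#' @param records A data frame of fitness records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitness_csv <- function(records, path) {
  check_fitness_records(records)
  readr::write_csv(tibble::as_tibble(records), path, na = "NA")
  invisible(path)
}

#' Read a scenario configuration from JSON
#'
#' Reads a JSON object whose keys mirror the arguments of
#' [scenario_config()]; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path Path to the JSON file.
#' @return A validated [scenario_config()].
#' @export
read_scenario_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario field(s) in ", basename(path), ": ",
                 paste(unknown, collapse = ", "), "."))
  }
  do.call(scenario_config, vals)
}

report_payload <- function(report) {
  if (inherits(report, "ci_bias_report")) {
    list(
      type = "ci_bias_report",
      suspect_lines = report$suspect_lines,
      with_suspects = report$with_suspects,
      without_suspects = report$without_suspects,
      slope_comparison = report$slope_comparison,
      leverage = report$leverage,
      ranks = report$ranks
    )
  } else if (inherits(report, "scenario_summary")) {
    list(
      type = "scenario_summary",
      config = unclass(report$config),
      tallies = report$tallies,
      per_replicate = report$per_replicate
    )
  } else if (is.data.frame(report)) {
    list(type = "table", rows = tibble::as_tibble(report))
  } else if (is.list(report)) {
    report
  } else {
    abort("`report` must be a report object, data frame, or list.")
  }
}

#' Write an analysis report as JSON
#'
#' Serializes a report ([ci_bias_report()], `scenario_summary`, a data frame
#' such as the output of [simulate_table1()], or a plain list) to JSON with
#' full numeric precision and stable key order, wrapped in metadata
#' (package version, the seed used, and a hash of the payload) so a report
#' documents its own provenance.
#'
#' @param report The report object.
#' @param path Output path.
#' @param seed The seed that produced the report (recorded in the metadata;
#'   optional).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  payload <- report_payload(report)
  body <- list(
    package = "ciconflict",
    version = as.character(packageVersion("ciconflict")),
    seed = seed,
    content_hash = rlang::hash(payload),
    report = payload
  )
  jsonlite::write_json(
    body, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report_json()].
#' @return A list with elements `package`, `version`, `seed`,
#'   `content_hash`, and `report` (tables as data frames).
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
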