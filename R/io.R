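# CSV interfaces: raw measurements in, curated long/wide tables and split
# plans out. Column layouts are fixed so the CLI and the R API round-trip.

#' Read a raw measurement CSV
#'
#' Expected columns: `smiles`, `endpoint`, `value` (numeric or with `<`/`>`
#' prefix), optional `qualifier`, `date` (ISO-8601), `modality`.
#'
#' @param path CSV file.
#' @return data.frame of raw measurements.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(m)
  if (!is.null(m$date)) m$date <- as.Date(m$date)
  m
}

#' Write curated records and the wide multitask table
#'
#' @param result a `curation_result` from [curate()].
#' @param records_path output CSV for long-format aggregated records
#'   (`NULL` to skip).
#' @param table_path output CSV for the wide table, columns in the fixed
#'   endpoint order (`NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_curation <- function(result, records_path = NULL, table_path = NULL) {
  stopifnot(inherits(result, "curation_result"))
  if (!is.null(records_path)) {
    utils::write.csv(result$records, records_path, row.names = FALSE)
  }
  if (!is.null(table_path)) {
    tab <- result$table
    wide <- data.frame(smiles_std = rownames(tab$values),
                       tab$values, check.names = FALSE)
    utils::write.csv(wide, table_path, row.names = FALSE, na = "")
  }
  invisible(result)
}

#' Rebuild a multitask table from long-format curated records
#'
#' @param path CSV written by [write_curation()] (records layout).
#' @return A `multitask_table`.
#' @export
read_multitask_table <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$earliest_date <- as.Date(rec$earliest_date)
  build_multitask_table(rec)
}

#' Write a split plan as a long CSV
#' @param plan a `split_plan`.
#' @param path output CSV (columns `smiles_std`, `endpoint`, `round`,
#'   `role`).
#' @return `plan`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(plan)
}

#' Read a split plan written by [write_split_plan()]
#' @param path CSV file.
#' @param strategy strategy label to attach (stored layout does not carry
#'   it).
#' @return A `split_plan`.
#' @export
read_split_plan <- function(path, strategy = "unknown") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rounds <- lapply(sort(unique(d$round)), function(r) {
    list(round = r,
         train = d[d$round == r & d$role == "train", c("smiles_std", "endpoint")],
         test = d[d$round == r & d$role == "test", c("smiles_std", "endpoint")])
  })
  new_split_plan(strategy, rounds, seed = NA_integer_)
}

#' Write a synthetic dataset to raw-measurement and truth CSVs
#' @param dataset a `synthetic_dataset` from [generate()].
#' @param measurements_path output CSV of raw measurements.
#' @param truth_path optional output CSV of true log values (wide).
#' @return `dataset`, invisibly.
#' @export
write_synthetic <- function(dataset, measurements_path, truth_path = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  utils::write.csv(dataset$measurements, measurements_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(data.frame(smiles = rownames(dataset$truth),
                                dataset$truth, check.names = FALSE),
                     truth_path, row.names = FALSE)
  }
  invisible(dataset)
}
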