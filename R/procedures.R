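#' Read a procedure-outcome table
#'
#' Reads a delimited text file with one row per surgical procedure, carrying
#' the case count and in-hospital death count used by the shrinkage and
#' stratification stages. The delimiter (comma or tab) is auto-detected from
#' the header line. Column names are matched case-insensitively against
#' `procedure`/`name`, `cases`/`n`, `deaths`/`d`; optional ordinal grade
#' columns (`rachs_grade`, `stseacts_grade`) and any extra columns are carried
#' through untouched.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @return A tibble with columns `procedure` (character), `cases` (integer),
#'   `deaths` (integer), plus any additional columns, in file row order.
#' @examples
#' tab <- load_procedure_table(chd_table2_path())
#' nrow(tab)
#' @export
load_procedure_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_procedure_table(normalise_procedure_columns(raw))
}

normalise_procedure_columns <- function(tab) {
  nm <- tolower(names(tab))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0L) abort(paste0(
      "procedure table needs a column named one of: ",
      paste(cands, collapse = ", ")))
    hit[[1L]]
  }
  names(tab)[pick(c("procedure", "procedure_name", "name"))] <- "procedure"
  names(tab)[pick(c("cases", "n", "cases_n"))] <- "cases"
  names(tab)[pick(c("deaths", "death", "d", "death_n"))] <- "deaths"
  as_tibble(tab) |>
    relocate("procedure", "cases", "deaths") |>
    mutate(procedure = as.character(.data$procedure),
           cases = as.integer(.data$cases),
           deaths = as.integer(.data$deaths))
}

#' Validate a procedure-outcome table
#'
#' Checks the core invariants of a procedure-outcome table: non-negative
#' integer counts, `deaths <= cases` (violations are reported by row or
#' procedure name), and unique procedure names. An empty table is valid.
#'
#' @param tab A data frame with `procedure`, `cases` and `deaths` columns.
#' @return The validated table as a tibble.
#' @export
validate_procedure_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (nrow(tab) == 0L) return(as_tibble(tab))
  bad <- which(is.na(tab$cases) | is.na(tab$deaths) |
                 tab$cases < 0L | tab$deaths < 0L)
  if (length(bad) > 0L) {
    abort(paste0("non-negative integer cases/deaths required; bad row(s): ",
                 paste(bad, collapse = ", ")))
  }
  over <- which(tab$deaths > tab$cases)
  if (length(over) > 0L) {
    abort(paste0("deaths exceed cases for: ",
                 paste(tab$procedure[over], collapse = "; ")))
  }
  dup <- tab$procedure[duplicated(tab$procedure)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate procedure name(s): ",
                 paste(unique(dup), collapse = "; ")))
  }
  as_tibble(tab)
}

#' Write a procedure-outcome table
#'
#' Writes the table as CSV. Any rate columns ending in `_pct` are formatted
#' with exactly two decimals so that output files are bit-stable.
#'
#' @param tab A procedure-outcome tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_procedure_table <- function(tab, path) {
  tab <- validate_procedure_table(tab)
  pct <- grepl("_pct$", names(tab))
  tab[pct] <- lapply(tab[pct], function(x) sprintf("%.2f", x))
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Path to the packaged reference procedure table
#'
#' Location of the packaged per-procedure case/death table for 102 congenital
#' heart surgery procedures (24,685 operations, 591 in-hospital deaths),
#' together with the published unadjusted and model-based mortality columns,
#' the published 5-level risk stratification, and RACHS-1 / STS-EACTS grades.
#' Rows whose published RACHS-1 grade was ambiguous (e.g. "1/2") store the
#' higher grade in `rachs_grade`; the original string is kept in
#' `rachs_grade_raw`.
#'
#' @return File path of the CSV shipped in `inst/extdata`.
#' @seealso [chd_table2()]
#' @export
chd_table2_path <- function() {
  system.file("extdata", "table2_procedures.csv", package = "chdrisk",
              mustWork = TRUE)
}

#' Load the packaged reference procedure table
#'
#' @return A tibble with one row per procedure; see [chd_table2_path()].
#' @examples
#' chd_table2() |> dplyr::summarise(rate = sum(deaths) / sum(cases))
#' @export
chd_table2 <- function() {
  load_procedure_table(chd_table2_path())
}

#' Drop procedures performed in fewer than a minimum number of patients
#'
#' Low-volume procedures carry almost no information about their own
#' mortality; the analysis excludes procedures performed in fewer than
#' `min_cases` patients before any modelling.
#'
#' @param tab A procedure-outcome tibble.
#' @param min_cases Minimum case count to retain a procedure (default 3).
#' @return The filtered tibble; the number of removed rows is reported via
#'   a message and stored in the `n_excluded` attribute.
#' @export
apply_inclusion_rules <- function(tab, min_cases = 3L) {
  tab <- validate_procedure_table(tab)
  keep <- tab$cases >= min_cases
  out <- tab[keep, , drop = FALSE]
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    inform(paste0("excluded ", n_drop, " procedure(s) with fewer than ",
                  min_cases, " cases"))
  }
  attr(out, "n_excluded") <- n_drop
  out
}

#' Keep only each patient's last surgical record within a month
#'
#' Input contract helper for registries where a patient may have several
#' surgical records close in time: only the last record within a calendar
#' month is analysed and earlier ones count as operation history. Synthetic
#' registries produced by this package never contain such duplicates, so this
#' filter is normally a no-op.
#'
#' @param records A tibble with at least `patient_id` and `date` columns.
#' @return The tibble restricted to each patient's last record per month,
#'   with a logical `has_prior_record` column flagging patients whose earlier
#'   records were dropped.
#' @export
keep_last_record_per_month <- function(records) {
  stopifnot(all(c("patient_id", "date") %in% names(records)))
  records |>
    mutate(.month = format(as.Date(.data$date), "%Y-%m")) |>
    group_by(.data$patient_id, .data$.month) |>
    mutate(has_prior_record = dplyr::n() > 1L) |>
    slice_max(order_by = .data$date, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    select(-".month")
}

#' Unadjusted death rate
#'
#' @param deaths,cases Non-negative counts with `deaths <= cases`;
#'   vectorised.
#' @return `deaths / cases` as a proportion in `[0, 1]`.
#' @examples
#' raw_rate(23, 7910)
#' @export
raw_rate <- function(deaths, cases) {
  if (any(cases < 1L)) abort("raw_rate undefined for cases < 1")
  if (any(deaths < 0L | deaths > cases)) abort("need 0 <= deaths <= cases")
  deaths / cases
}
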