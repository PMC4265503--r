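# Mutation tables in the mandatory four-column schema:
#   "Gene name", "Mutation AA", "Position", "Source" (+ pass-through extras).

#' @importFrom rlang abort warn
NULL

CANONICAL_COLUMNS <- c("Gene name", "Mutation AA", "Position", "Source")

abort_schema <- function(msg) abort(msg, class = "mutoverlay_schema_error")
abort_arg <- function(msg) abort(msg, class = "mutoverlay_arg_error")
abort_io <- function(msg) abort(msg, class = "mutoverlay_io_error")

#' Construct a mutation table from a data frame
#'
#' A mutation table is a tibble holding one row per mutation entry, with the
#' canonical columns `Gene name` and `Mutation AA` (mandatory), `Position`
#' and `Source` (added by [annotate_positions()] and [set_source()]), and
#' any number of pass-through extra columns, which are never reordered or
#' mutated by package operations.  A `provenance` attribute records the
#' (path, source label) pairs the records came from.
#'
#' @param x A data frame with at least `Gene name` and `Mutation AA`
#'   columns (possibly via [read_mutation_table()]'s `column_map`).
#' @param provenance Optional tibble with columns `path` and `source`.
#' @return A `mutation_table` (tibble subclass).
#' @export
as_mutation_table <- function(x, provenance = NULL) {
  if (!is.data.frame(x)) abort_arg("`x` must be a data frame")
  missing_cols <- setdiff(c("Gene name", "Mutation AA"), names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "mandatory column%s missing: %s",
      if (length(missing_cols) > 1) "s" else "",
      paste(sQuote(missing_cols), collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(x)
  if ("Position" %in% names(out)) {
    out[["Position"]] <- suppressWarnings(as.integer(out[["Position"]]))
  }
  if (is.null(provenance)) {
    provenance <- tibble::tibble(path = character(), source = character())
  }
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("mutation_table", class(out)))
  out
}

#' Provenance of a mutation table
#'
#' @param table A mutation table.
#' @return Tibble of (path, source) pairs, or an empty tibble.
#' @export
provenance <- function(table) {
  p <- attr(table, "provenance", exact = TRUE)
  if (is.null(p)) tibble::tibble(path = character(), source = character()) else p
}

#' Read a mutation table from TSV or CSV
#'
#' Reads a COSMIC-style export (one row per mutation entry).  Columns
#' `Gene name` and `Mutation AA` are mandatory after mapping; `Position`
#' and `Source`, when present in the file, are loaded rather than
#' recomputed.  All other columns are carried through unchanged.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default; COSMIC exports are tab-separated) or
#'   `"csv"`.
#' @param column_map Optional named character vector mapping canonical
#'   names to the names actually used in the file, e.g. for MAF-like
#'   tables `c("Gene name" = "Hugo_Symbol", "Mutation AA" = "HGVSp_Short")`.
#' @return A `mutation_table`.
#' @export
read_mutation_table <- function(path, format = c("tsv", "csv"),
                                column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_io(sprintf("cannot read mutation table: no such file '%s'", path))
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!is.null(column_map)) {
    for (logical_name in names(column_map)) {
      actual <- column_map[[logical_name]]
      if (!actual %in% names(df)) {
        abort_schema(sprintf(
          "column_map names '%s' as '%s', but the file has no such column",
          logical_name, actual
        ))
      }
      names(df)[names(df) == actual] <- logical_name
    }
  }
  missing_cols <- setdiff(c("Gene name", "Mutation AA"), names(df))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "file '%s' lacks mandatory column%s: %s",
      path, if (length(missing_cols) > 1) "s" else "",
      paste(sQuote(missing_cols), collapse = ", ")
    ))
  }
  src <- if ("Source" %in% names(df)) unique(df[["Source"]]) else NA_character_
  prov <- tibble::tibble(path = rep(path, length(src)), source = src)
  as_mutation_table(df, provenance = prov)
}

#' Write a mutation table to TSV or CSV
#'
#' Columns are written in canonical order — `Gene name`, `Mutation AA`,
#' `Position`, `Source` (those present) — followed by the extra columns in
#' their original order.  `read_mutation_table()` on the written file
#' reproduces the table's content.
#'
#' @param table A mutation table.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  lead <- intersect(CANONICAL_COLUMNS, names(table))
  extras <- setdiff(names(table), CANONICAL_COLUMNS)
  out <- table[, c(lead, extras), drop = FALSE]
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  tryCatch(
    writer(as.data.frame(out), path, progress = FALSE),
    error = function(e) abort_io(sprintf("cannot write '%s': %s", path,
                                         conditionMessage(e)))
  )
  invisible(path)
}

#' Validate a mutation table against the mandatory schema
#'
#' Report-only check of the four mandatory columns, of how many records
#' lack a position, and of whether the source labels attached to different
#' provenance entries are distinct (distinct names in the `Source` column
#' are what separate the reference from the test set).
#'
#' @param table A mutation table.
#' @return A list of class `schema_report` with elements `columns_present`
#'   (named logical over the four canonical columns), `n_records`,
#'   `n_unpositioned`, `sources` (unique labels), `sources_distinct`
#'   (logical: no two provenance entries share a label), and `ok`.
#' @export
validate_schema <- function(table) {
  cols <- stats::setNames(
    CANONICAL_COLUMNS %in% names(table), CANONICAL_COLUMNS
  )
  n_unpos <- if (cols[["Position"]]) sum(is.na(table[["Position"]])) else nrow(table)
  sources <- if (cols[["Source"]]) unique(table[["Source"]]) else character()
  prov <- provenance(table)
  prov_sources <- prov$source[!is.na(prov$source)]
  distinct <- !anyDuplicated(prov_sources)
  src_nonempty <- cols[["Source"]] &&
    all(!is.na(table[["Source"]])) && all(nzchar(table[["Source"]]))
  report <- structure(
    list(
      columns_present = cols,
      n_records = nrow(table),
      n_unpositioned = n_unpos,
      sources = sources,
      sources_distinct = distinct,
      sources_nonempty = src_nonempty || nrow(table) == 0,
      ok = all(cols) && distinct && (src_nonempty || nrow(table) == 0)
    ),
    class = "schema_report"
  )
  report
}

#' @export
print.schema_report <- function(x, ...) {
  cat("mutation table schema report\n")
  for (col in names(x$columns_present)) {
    cat(sprintf("  column %-12s %s\n", sQuote(col),
                if (x$columns_present[[col]]) "present" else "MISSING"))
  }
  cat(sprintf("  records: %d (%d without position)\n",
              x$n_records, x$n_unpositioned))
  cat(sprintf("  sources: %s%s\n",
              if (length(x$sources)) paste(x$sources, collapse = ", ") else "(none)",
              if (x$sources_distinct) "" else "  [NOT DISTINCT]"))
  cat(sprintf("  overall: %s\n", if (x$ok) "OK" else "FAILED"))
  invisible(x)
}

#' Label every record of a table with a source name
#'
#' Fills the `Source` column with a single label (e.g. `"COSMIC"` for the
#' reference compendium, a cohort name for a test set).  Distinct labels on
#' the reference and the test table are what keep the two point series
#' separate in the overlay.
#'
#' @param table A mutation table.
#' @param label Non-empty source label.
#' @return The relabelled table.
#' @export
set_source <- function(table, label) {
  if (!is.character(label) || length(label) != 1 || is.na(label) ||
      !nzchar(label)) {
    abort_arg("`label` must be a single non-empty string")
  }
  table[["Source"]] <- rep(label, nrow(table))
  prov <- provenance(table)
  prov$source <- rep(label, nrow(prov))
  as_mutation_table(table, provenance = prov)
}

#' Append a test mutation table to a reference table
#'
#' The combined table drives the overlay: reference records precede test
#' records, no record is altered, and the two tables must carry disjoint
#' source labels so the series remain distinguishable.
#'
#' @param reference,test Annotated, labelled mutation tables.
#' @return The combined `mutation_table` with
#'   `nrow = nrow(reference) + nrow(test)`.
#' @export
merge_tables <- function(reference, test) {
  for (tbl in list(reference, test)) {
    if (!"Source" %in% names(tbl)) {
      abort_schema("both tables must carry a 'Source' column before merging")
    }
  }
  shared <- intersect(unique(reference[["Source"]]), unique(test[["Source"]]))
  shared <- shared[!is.na(shared)]
  if (length(shared) > 0) {
    abort_arg(sprintf(
      paste0("reference and test tables share source label%s %s; ",
             "distinct names in the 'Source' column are necessary"),
      if (length(shared) > 1) "s" else "",
      paste(sQuote(shared), collapse = ", ")
    ))
  }
  combined <- dplyr::bind_rows(reference, test)
  as_mutation_table(
    combined,
    provenance = dplyr::bind_rows(provenance(reference), provenance(test))
  )
}

#' Remove records belonging to given samples or studies
#'
#' Self-reference exclusion: when the test cohort's calls are already part
#' of the reference compendium, the cohort's samples must be removed from
#' the reference so that overlap in the overlay is not an artifact of
#' shared data.
#'
#' @param reference A mutation table.
#' @param key_column Name of the column identifying samples or studies
#'   (the identifier column varies between database exports, so it is a
#'   parameter rather than a fixed name).
#' @param keys Character vector of identifiers to drop.
#' @return The filtered table, with attribute `n_excluded` giving the
#'   number of records removed.
#' @export
exclude_samples <- function(reference, key_column, keys) {
  if (!key_column %in% names(reference)) {
    abort_schema(sprintf("key column '%s' not present in table", key_column))
  }
  keys <- as.character(keys)
  keep <- !(reference[[key_column]] %in% keys)
  out <- as_mutation_table(
    reference[keep, , drop = FALSE],
    provenance = provenance(reference)
  )
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "parse_report") <- attr(reference, "parse_report", exact = TRUE)
  out
}
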