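# Region selection and drill-down export of the underlying records.

#' Define a region query over a gene's amino-acid positions
#'
#' Intervals are closed on both ends: a region quoted as residues 23-48
#' contains positions 23 and 48.
#'
#' @param gene Gene symbol.
#' @param start,end 1-based residue positions, `start <= end`, both
#'   inclusive.
#' @param sources Optional character vector restricting the query to given
#'   source labels; the default (`NULL`) returns records from all sources,
#'   so a drill-down shows reference and test records side by side.
#' @return A `region_query` object.
#' @export
region_query <- function(gene, start, end, sources = NULL) {
  if (!is.character(gene) || length(gene) != 1 || !nzchar(gene)) {
    abort_arg("`gene` must be a single non-empty gene symbol")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || end < 1) {
    abort_arg("`start` and `end` must be positive residue positions")
  }
  if (start > end) {
    abort_arg(sprintf("invalid region: start (%d) > end (%d)", start, end))
  }
  structure(
    list(gene = gene, start = start, end = end, sources = sources),
    class = "region_query"
  )
}

#' Select the records underlying a gene region
#'
#' Returns exactly the records of the queried gene whose position lies in
#' the closed interval, optionally restricted by source.  Records lacking
#' a position are never returned (region membership is undefined for
#' them).  All extra columns are preserved and input order is kept.
#'
#' @param table An annotated mutation table.
#' @param query A [region_query()].
#' @return The matching subset as a `mutation_table`.
#' @export
select_region <- function(table, query) {
  if (!inherits(query, "region_query")) {
    abort_arg("`query` must be built with region_query()")
  }
  if (!all(c("Gene name", "Position") %in% names(table))) {
    abort_schema("table must be annotated ('Gene name' and 'Position') before region selection")
  }
  keep <- table[["Gene name"]] == query$gene &
    !is.na(table[["Position"]]) &
    table[["Position"]] >= query$start &
    table[["Position"]] <= query$end
  keep[is.na(keep)] <- FALSE
  if (!is.null(query$sources)) {
    keep <- keep & table[["Source"]] %in% query$sources
  }
  as_mutation_table(table[keep, , drop = FALSE],
                    provenance = provenance(table))
}

#' Export the underlying records of a selection, drill-down style
#'
#' Writes the records ranked first by source (ascending lexicographic,
#' C-locale), then by position at which the alteration is localized, with
#' ties kept in input order (stable sort).  All columns — mandatory and
#' extras — are included.
#'
#' @param table An annotated, labelled mutation table (typically the
#'   output of [select_region()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_underlying <- function(table, path) {
  if (!all(c("Source", "Position") %in% names(table))) {
    abort_schema("table must carry 'Source' and 'Position' columns for export")
  }
  ord <- order(table[["Source"]], table[["Position"]], method = "radix")
  write_mutation_table(table[ord, , drop = FALSE], path, format = "tsv")
}
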