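# Per-(gene, position, source) recurrence counts -- the plotted y value.

#' Count mutation entries per gene, amino-acid position and source
#'
#' Computes the "count of position": the number of entries carrying a
#' mutation at each amino-acid position of each gene, kept separate per
#' source.  Source separation is the core of the overlay method — counts
#' from the reference and the test set are never pooled.  Different
#' amino-acid changes at one position (e.g. V600E and V600K) contribute to
#' one site count, since the unit of analysis is the position.  Records
#' without a position are skipped; their number is attached as the
#' `n_skipped` attribute.
#'
#' Counts are per annotated entry, not per unique patient: compendia such
#' as COSMIC lack a definitive sample denominator and contain redundant
#' entries, so no normalization or deduplication is attempted.
#'
#' @param table An annotated, labelled mutation table.
#' @return A tibble of class `site_counts` with columns `gene`, `position`,
#'   `source`, `count` (one row per distinct triple, `count >= 1`), sorted
#'   by gene, position, source.  The counts sum to the number of
#'   positioned records.
#' @export
count_sites <- function(table) {
  for (col in c("Gene name", "Position", "Source")) {
    if (!col %in% names(table)) {
      abort_schema(sprintf(
        "column '%s' required for counting; annotate and label the table first",
        col
      ))
    }
  }
  positioned <- !is.na(table[["Position"]])
  counts <- table[positioned, , drop = FALSE] |>
    dplyr::count(
      gene = .data[["Gene name"]],
      position = .data[["Position"]],
      source = .data[["Source"]],
      name = "count"
    ) |>
    dplyr::arrange(.data$gene, .data$position, .data$source)
  counts <- tibble::as_tibble(counts)
  attr(counts, "n_skipped") <- sum(!positioned)
  class(counts) <- unique(c("site_counts", class(counts)))
  counts
}

#' Filter site counts by a minimum recurrence threshold
#'
#' Retains the sites with `count >= min_count`.  The default threshold in
#' this package is 1 (no filtering), because the method's point is that
#' low-frequency test mutations become interpretable against the
#' reference; a threshold of 10 entries is the documented preset for
#' browsing dominant sites in a large reference set alone.  Per-source
#' thresholds allow a rare test cohort (min 1) to be overlaid on a
#' thresholded reference.
#'
#' @param counts A `site_counts` tibble from [count_sites()].
#' @param min_count Positive integer threshold applied to every source
#'   without an entry in `per_source`.
#' @param per_source Optional named integer vector of per-source
#'   thresholds, e.g. `c(COSMIC = 10, UCEC = 1)`.
#' @return The filtered subset of `counts` (always a subset; thresholds
#'   are monotone: a larger `min_count` retains a subset of a smaller one).
#' @export
apply_threshold <- function(counts, min_count = 1L, per_source = NULL) {
  if (!is.numeric(min_count) || length(min_count) != 1 || is.na(min_count) ||
      min_count < 1) {
    abort_arg("`min_count` must be a single integer >= 1")
  }
  thr <- rep(as.integer(min_count), nrow(counts))
  if (!is.null(per_source)) {
    if (is.null(names(per_source)) || any(!nzchar(names(per_source)))) {
      abort_arg("`per_source` must be a named vector of thresholds")
    }
    if (any(per_source < 1)) abort_arg("per-source thresholds must be >= 1")
    hit <- match(counts$source, names(per_source))
    thr[!is.na(hit)] <- as.integer(per_source[hit[!is.na(hit)]])
  }
  out <- counts[counts$count >= thr, , drop = FALSE]
  class(out) <- class(counts)
  out
}

#' Most recurrent sites of one gene in one source
#'
#' @param counts A `site_counts` tibble.
#' @param gene Gene symbol (matched exactly, case-sensitively).
#' @param source Source label.
#' @param n Number of sites to return (`n >= 1`); fewer are returned when
#'   fewer exist, and an unknown gene or source yields an empty result.
#' @return Up to `n` rows ordered by descending count, ties broken by
#'   ascending position.
#' @export
top_sites <- function(counts, gene, source, n = 10L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort_arg("`n` must be a single integer >= 1")
  }
  sel <- counts[counts$gene == gene & counts$source == source, , drop = FALSE]
  sel <- sel[order(-sel$count, sel$position), , drop = FALSE]
  out <- utils::head(sel, as.integer(n))
  class(out) <- class(counts)
  out
}

#' Write site counts as TSV
#'
#' @param counts A `site_counts` tibble.
#' @param path Output path (columns gene, position, source, count).
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(counts, path) {
  readr::write_tsv(as.data.frame(counts), path, progress = FALSE)
  invisible(path)
}
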