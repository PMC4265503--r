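# Independent oracles and small fixture specs shared across test files.
# The oracles deliberately avoid the package's own code paths (plain loops
# over rows) so they stay independent of what they check.

# Content-only view of a table: strips package bookkeeping attributes
# (provenance, parse report, exclusion tally) so content comparisons do
# not trip over them.
bare_table <- function(x) {
  out <- tibble::as_tibble(x)
  for (a in c("provenance", "parse_report", "n_excluded", "n_skipped")) {
    attr(out, a) <- NULL
  }
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

# O(n^2)-style per-row tally of (gene, position, source) counts.
brute_force_tally <- function(table) {
  keep <- !is.na(table[["Position"]])
  g <- table[["Gene name"]][keep]
  p <- table[["Position"]][keep]
  s <- table[["Source"]][keep]
  seen <- character()
  out <- list()
  for (i in seq_along(g)) {
    key <- paste(g[i], p[i], s[i], sep = "\r")
    if (key %in% seen) {
      out[[key]]$count <- out[[key]]$count + 1L
    } else {
      seen <- c(seen, key)
      out[[key]] <- list(gene = g[i], position = p[i], source = s[i],
                         count = 1L)
    }
  }
  df <- do.call(rbind, lapply(out, function(x) {
    data.frame(gene = x$gene, position = x$position, source = x$source,
               count = x$count, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(gene = character(), position = integer(),
                     source = character(), count = integer())
  }
  df[order(df$gene, df$position, df$source), , drop = FALSE]
}

# Linear-scan region filter over raw rows.
linear_filter_region <- function(table, gene, start, end) {
  keep <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    pos <- table[["Position"]][i]
    keep[i] <- !is.na(pos) &&
      identical(table[["Gene name"]][i], gene) &&
      pos >= start && pos <= end
  }
  table[keep, , drop = FALSE]
}

# Stable sort by (source, position) via explicit index bookkeeping.
stable_sort_oracle <- function(table) {
  idx <- seq_len(nrow(table))
  key <- data.frame(s = table[["Source"]], p = table[["Position"]], i = idx)
  key <- key[order(key$s, key$p, key$i, method = "radix"), ]
  table[key$i, , drop = FALSE]
}

# Compact two-gene spec used across module tests.
small_fixture_spec <- function(seed = 42L, background = 0) {
  fixture_spec(
    genes = c(GENEA = 800L, GENEB = 400L),
    planted_sites = data.frame(
      gene = c("GENEA", "GENEA", "GENEB", "GENEB"),
      position = c(600L, 12L, 132L, 300L),
      source = c("REF", "REF", "REF", "TEST"),
      count = c(12L, 3L, 10L, 2L)
    ),
    region_hotspots = data.frame(
      gene = "GENEA", start = 23L, end = 48L, source = "REF", count = 26L
    ),
    background = background, seed = seed,
    reference_source = "REF", test_source = "TEST"
  )
}

# Generate, annotate and label both tables of a spec.
prepared_tables <- function(spec) {
  tabs <- generate_fixture(spec)
  list(
    reference = set_source(annotate_positions(tabs$reference),
                           spec$reference_source),
    test = set_source(annotate_positions(tabs$test), spec$test_source)
  )
}

count_svg_markers <- function(path) {
  doc <- xml2::read_xml(path)
  list(
    all = xml2::xml_find_all(doc, "//*[contains(@class, 'marker ')]"),
    reference = xml2::xml_find_all(
      doc, "//*[contains(@class, 'marker-reference')]"),
    test = xml2::xml_find_all(doc, "//*[contains(@class, 'marker-test')]")
  )
}
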