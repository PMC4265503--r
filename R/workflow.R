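# Command-style workflow: prepare -> merge -> plot -> query (-> simulate).
# Each cmd_* function is the programmatic form of one CLI subcommand; the
# CLI dispatcher maps argument vectors onto them and errors onto exit
# codes (0 success, 2 usage/schema error, 1 I/O error).

#' Prepare a mutation table: annotate positions and label the source
#'
#' Reads a raw table, extracts amino-acid positions from the annotation
#' column into `Position`, fills the `Source` column with one label,
#' validates the four-column schema and writes the prepared table.  The
#' parse report is printed to standard error.  Re-running on an already
#' prepared file reproduces it (idempotence).
#'
#' @param input,output File paths.
#' @param source_label Label for the `Source` column (e.g. `"COSMIC"`).
#' @param format `"tsv"` or `"csv"` (both input and output).
#' @param column_map Optional named character vector, see
#'   [read_mutation_table()].
#' @param recompute Recompute positions even where present.
#' @param quiet Suppress the report message.
#' @return Invisibly, a list with the prepared `table`, the `parse_report`
#'   tallies and the `schema` report.
#' @export
cmd_prepare <- function(input, output, source_label, format = "tsv",
                        column_map = NULL, recompute = FALSE, quiet = FALSE) {
  table <- read_mutation_table(input, format = format, column_map = column_map)
  table <- annotate_positions(table, recompute = recompute)
  table <- set_source(table, source_label)
  report <- parse_report(table)
  schema <- validate_schema(table)
  write_mutation_table(table, output, format = format)
  if (!quiet) {
    message(sprintf(
      "prepared %d records (%s): %s",
      nrow(table), source_label,
      paste(sprintf("%s=%d", names(report), report), collapse = ", ")
    ))
  }
  invisible(list(table = table, parse_report = report, schema = schema))
}

#' Merge a prepared test table onto a prepared reference table
#'
#' Optionally removes reference records belonging to the test cohort
#' first (self-reference exclusion), then appends the test rows to the
#' reference rows and writes the combined table.
#'
#' @param reference,test,output File paths of prepared tables.
#' @param exclusion_column Optional column identifying samples/studies to
#'   drop from the reference.
#' @param exclusion_keys Character vector of identifiers to drop (used
#'   with `exclusion_column`).
#' @param format `"tsv"` or `"csv"`.
#' @param quiet Suppress the report message.
#' @return Invisibly, a list with the combined `table`, `n_reference`,
#'   `n_test`, `n_excluded`.
#' @export
cmd_merge <- function(reference, test, output, exclusion_column = NULL,
                      exclusion_keys = NULL, format = "tsv", quiet = FALSE) {
  ref <- read_mutation_table(reference, format = format)
  tst <- read_mutation_table(test, format = format)
  n_excluded <- 0L
  if (!is.null(exclusion_column)) {
    ref <- exclude_samples(ref, exclusion_column, exclusion_keys)
    n_excluded <- attr(ref, "n_excluded", exact = TRUE)
  }
  combined <- merge_tables(ref, tst)
  write_mutation_table(combined, output, format = format)
  if (!quiet) {
    message(sprintf(
      "merged %d reference + %d test records (%d excluded from reference)",
      nrow(ref), nrow(tst), n_excluded
    ))
  }
  invisible(list(table = combined, n_reference = nrow(ref),
                 n_test = nrow(tst), n_excluded = n_excluded))
}

#' Plot the overlay for selected genes
#'
#' Counts sites, applies the recurrence threshold, builds the overlay and
#' renders the requested outputs.  Requesting a gene absent from the data
#' yields a warning and an empty facet, not an error.
#'
#' @param input Combined (or single-source) prepared table path.
#' @param genes Character vector of gene symbols, facet order.
#' @param svg,png,html Optional output paths; each given one is rendered.
#' @param min_count Recurrence threshold (default 1 = no filtering; 10 is
#'   the browsing preset for dominant sites in a large reference).
#' @param per_source Optional named per-source thresholds.
#' @param roles,style Passed to [build_overlay()].
#' @param format Input format.
#' @param quiet Suppress messages.
#' @return Invisibly, a list with the `spec` and the thresholded `counts`.
#' @export
cmd_plot <- function(input, genes, svg = NULL, png = NULL, html = NULL,
                     min_count = 1L, per_source = NULL, roles = NULL,
                     style = NULL, format = "tsv", quiet = FALSE) {
  table <- read_mutation_table(input, format = format)
  counts <- count_sites(table)
  counts <- apply_threshold(counts, min_count, per_source = per_source)
  absent <- setdiff(genes, unique(counts$gene))
  if (length(absent) > 0 && !quiet) {
    warn(sprintf("no sites to plot for gene%s %s; facet(s) will be empty",
                 if (length(absent) > 1) "s" else "",
                 paste(sQuote(absent), collapse = ", ")))
  }
  spec <- build_overlay(counts, genes, roles = roles, style = style)
  if (!is.null(svg)) render_static(spec, svg, format = "svg")
  if (!is.null(png)) render_static(spec, png, format = "png")
  if (!is.null(html)) render_interactive(spec, html)
  invisible(list(spec = spec, counts = counts))
}

#' Export the records underlying a gene region
#'
#' @param input Combined prepared table path.
#' @param gene Gene symbol.
#' @param start,end Closed residue interval.
#' @param output Output TSV path (sorted by source, then position).
#' @param sources Optional source filter.
#' @param format Input format.
#' @param quiet Suppress messages.
#' @return Invisibly, the selected `mutation_table`.
#' @export
cmd_query <- function(input, gene, start, end, output, sources = NULL,
                      format = "tsv", quiet = FALSE) {
  table <- read_mutation_table(input, format = format)
  q <- region_query(gene, start, end, sources = sources)
  sel <- select_region(table, q)
  export_underlying(sel, output)
  if (!quiet) {
    message(sprintf("%d records in %s[%d,%d] written to %s",
                    nrow(sel), gene, q$start, q$end, output))
  }
  invisible(sel)
}

#' Generate fixture tables on disk
#'
#' Writes the synthetic reference and test tables of a fixture spec as
#' raw (pre-preparation) TSV files: `Gene name`, `Mutation AA` and
#' `Sample name` columns only, so the prepare step can be exercised on
#' them.
#'
#' @param output_dir Directory (created if needed).
#' @param spec A [fixture_spec()]; default [default_fixture_spec()].
#' @param seed Optional seed overriding the spec's.
#' @param quiet Suppress messages.
#' @return Invisibly, named character vector of the two written paths.
#' @export
cmd_simulate <- function(output_dir, spec = default_fixture_spec(),
                         seed = NULL, quiet = FALSE) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  tables <- generate_fixture(spec)
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  paths <- c(
    reference = file.path(output_dir, "synthetic_reference.tsv"),
    test = file.path(output_dir, "synthetic_test.tsv")
  )
  for (role in names(paths)) {
    raw <- tables[[role]]
    raw <- raw[, setdiff(names(raw), c("Position", "Source")), drop = FALSE]
    readr::write_tsv(as.data.frame(raw), paths[[role]], progress = FALSE)
  }
  if (!quiet) {
    message(sprintf("wrote %d reference and %d test records to %s",
                    nrow(tables$reference), nrow(tables$test), output_dir))
  }
  invisible(paths)
}

# ---------------------------------------------------------------------------
# CLI dispatcher

.cli_usage <- function() {
  paste(
    "usage: mutoverlay <command> [flags]",
    "",
    "commands:",
    "  prepare   --input F --output F --source LABEL [--format tsv|csv]",
    "            [--map 'Gene name=Hugo_Symbol,Mutation AA=HGVSp_Short']",
    "            [--recompute]",
    "  merge     --reference F --test F --output F",
    "            [--exclude-column COL --exclude-keys K1,K2|--exclude-file F]",
    "            [--format tsv|csv]",
    "  plot      --input F --genes A,B,C [--min-count N]",
    "            [--svg F] [--png F] [--html F]",
    "            [--reference-source S] [--test-source S] [--format tsv|csv]",
    "  query     --input F --gene G --start N --end N --output F",
    "            [--sources S1,S2] [--format tsv|csv]",
    "  simulate  --out-dir D [--seed N]",
    sep = "\n"
  )
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      abort_arg(sprintf("unexpected argument '%s'", a))
    }
    key <- substring(a, 3L)
    if (key %in% c("recompute", "quiet")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) abort_arg(sprintf("flag --%s needs a value", key))
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

.split_csv <- function(x) if (is.null(x)) NULL else strsplit(x, ",", fixed = TRUE)[[1]]

.parse_map <- function(x) {
  if (is.null(x)) return(NULL)
  pairs <- strsplit(.split_csv(x), "=", fixed = TRUE)
  bad <- vapply(pairs, length, integer(1)) != 2L
  if (any(bad)) abort_arg("--map expects 'logical=actual' pairs separated by commas")
  stats::setNames(
    vapply(pairs, `[[`, character(1), 2L),
    vapply(pairs, `[[`, character(1), 1L)
  )
}

.require_flags <- function(flags, needed) {
  missing_flags <- setdiff(needed, names(flags))
  if (length(missing_flags) > 0) {
    abort_arg(sprintf("missing required flag%s: %s",
                      if (length(missing_flags) > 1) "s" else "",
                      paste0("--", missing_flags, collapse = ", ")))
  }
}

#' Command-line entry point
#'
#' Dispatches an argument vector (by default the process arguments) onto
#' the `cmd_*` functions.  Intended to be called from the bundled
#' `inst/cli/mutoverlay.R` script; exposed as a function so the dispatch
#' and exit-code behaviour are testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 on success, 2 on usage or schema errors,
#'   1 on I/O errors.
#' @export
mutoverlay_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[[1]] %in% c("-h", "--help", "help")) {
    cat(.cli_usage(), "\n")
    return(invisible(0L))
  }
  command <- args[[1]]
  run <- function() {
    flags <- .parse_flags(args[-1])
    quiet <- isTRUE(flags$quiet)
    switch(
      command,
      prepare = {
        .require_flags(flags, c("input", "output", "source"))
        cmd_prepare(flags$input, flags$output, flags$source,
                    format = flags$format %||% "tsv",
                    column_map = .parse_map(flags$map),
                    recompute = isTRUE(flags$recompute), quiet = quiet)
      },
      merge = {
        .require_flags(flags, c("reference", "test", "output"))
        keys <- .split_csv(flags[["exclude-keys"]])
        if (!is.null(flags[["exclude-file"]])) {
          if (!file.exists(flags[["exclude-file"]])) {
            abort_io(sprintf("no such file '%s'", flags[["exclude-file"]]))
          }
          keys <- c(keys, readLines(flags[["exclude-file"]]))
        }
        cmd_merge(flags$reference, flags$test, flags$output,
                  exclusion_column = flags[["exclude-column"]],
                  exclusion_keys = keys,
                  format = flags$format %||% "tsv", quiet = quiet)
      },
      plot = {
        .require_flags(flags, c("input", "genes"))
        roles <- NULL
        if (!is.null(flags[["reference-source"]])) {
          roles <- c(reference = flags[["reference-source"]])
          if (!is.null(flags[["test-source"]])) {
            roles <- c(roles, test = flags[["test-source"]])
          }
        }
        cmd_plot(flags$input, .split_csv(flags$genes),
                 svg = flags$svg, png = flags$png, html = flags$html,
                 min_count = as.integer(flags[["min-count"]] %||% "1"),
                 roles = roles, format = flags$format %||% "tsv",
                 quiet = quiet)
      },
      query = {
        .require_flags(flags, c("input", "gene", "start", "end", "output"))
        cmd_query(flags$input, flags$gene,
                  as.integer(flags$start), as.integer(flags$end),
                  flags$output, sources = .split_csv(flags$sources),
                  format = flags$format %||% "tsv", quiet = quiet)
      },
      simulate = {
        .require_flags(flags, "out-dir")
        cmd_simulate(flags[["out-dir"]],
                     seed = if (!is.null(flags$seed)) as.integer(flags$seed),
                     quiet = quiet)
      },
      abort_arg(sprintf("unknown command '%s'", command))
    )
    0L
  }
  tryCatch(
    run(),
    mutoverlay_arg_error = function(e) {
      message("error: ", conditionMessage(e))
      2L
    },
    mutoverlay_schema_error = function(e) {
      message("error: ", conditionMessage(e))
      2L
    },
    mutoverlay_io_error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
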