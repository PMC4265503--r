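# Synthetic reference/test mutation tables with planted hotspot sites and
# regions over a uniform background, so the whole pipeline is testable
# without access to licensed mutation databases.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.residue_at <- function(position, shift = 0L) {
  .AA1[(position - 1L + shift) %% 20L + 1L]
}

# Deterministic annotation template for record i at a site; cycles through
# mutation classes so parser coverage is exercised without randomness.
# Every template parses to `position` (first-affected-residue rule).
.annotation_template <- function(position, i, protein_length) {
  r1 <- .residue_at(position)
  r2 <- .residue_at(position, 7L)
  switch(
    as.character((i - 1L) %% 6L),
    "0" = sprintf("p.%s%d%s", r1, position, r2),                     # substitution
    "1" = sprintf("p.%s%d*", r1, position),                          # nonsense
    "2" = if (position + 2L <= protein_length) {
      sprintf("p.%s%d_%s%ddel", r1, position,
              .residue_at(position + 2L), position + 2L)             # deletion
    } else {
      sprintf("p.%s%ddel", r1, position)
    },
    "3" = sprintf("p.%s%dfs*%d", r1, position, (i %% 9L) + 2L),      # frameshift
    "4" = sprintf("p.%s%ddup", r1, position),                        # duplication
    "5" = if (position + 1L <= protein_length) {
      sprintf("p.%s%d_%s%dins%s", r1, position,
              .residue_at(position + 1L), position + 1L, r2)         # insertion
    } else {
      sprintf("p.%s%d%s", r1, position, r2)
    }
  )
}

#' Specify a synthetic mutation fixture
#'
#' Describes two synthetic mutation tables — a large reference set and a
#' small test set — with hotspots planted at known sites and regions over
#' a uniform Poisson background, emulating the structure of a compendium
#' such as COSMIC with a cohort call set overlaid.  Generation from a
#' spec is bit-reproducible under a fixed seed.
#'
#' @param genes Named integer vector: gene symbol -> protein length in
#'   residues (realistic lengths, several hundred to ~2000, keep axis and
#'   faceting code honest).
#' @param planted_sites Data frame with columns `gene`, `position`,
#'   `source`, `count`: single-site hotspots, `count` entries each.
#' @param region_hotspots Data frame with columns `gene`, `start`, `end`,
#'   `source`, `count`: `count` entries distributed round-robin over the
#'   closed residue interval, emulating a hotspot region of individually
#'   infrequent mutations.
#' @param background Expected number of background mutations per gene per
#'   source (rate of a Poisson count; positions uniform over the
#'   protein).  Default 0.
#' @param seed Integer random seed.
#' @param reference_source,test_source Source labels for the two tables.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(genes, planted_sites = NULL, region_hotspots = NULL,
                         background = 0, seed = 1L,
                         reference_source = "REF", test_source = "TEST") {
  if (is.null(names(genes)) || any(!nzchar(names(genes))) ||
      any(genes < 1)) {
    abort_arg("`genes` must be a named vector of positive protein lengths")
  }
  genes <- stats::setNames(as.integer(genes), names(genes))
  empty_sites <- tibble::tibble(gene = character(), position = integer(),
                                source = character(), count = integer())
  empty_regions <- tibble::tibble(gene = character(), start = integer(),
                                  end = integer(), source = character(),
                                  count = integer())
  planted_sites <- if (is.null(planted_sites)) empty_sites else
    tibble::as_tibble(planted_sites)
  region_hotspots <- if (is.null(region_hotspots)) empty_regions else
    tibble::as_tibble(region_hotspots)

  check_gene <- function(g, what) {
    unknown <- setdiff(g, names(genes))
    if (length(unknown)) {
      abort_arg(sprintf("%s name unknown gene(s): %s", what,
                        paste(sQuote(unknown), collapse = ", ")))
    }
  }
  check_gene(planted_sites$gene, "planted sites")
  check_gene(region_hotspots$gene, "region hotspots")
  if (nrow(planted_sites)) {
    too_far <- planted_sites$position > genes[planted_sites$gene]
    if (any(too_far)) {
      abort_arg(sprintf(
        "planted position beyond protein length for gene(s): %s",
        paste(sQuote(unique(planted_sites$gene[too_far])), collapse = ", ")
      ))
    }
  }
  if (nrow(region_hotspots)) {
    if (any(region_hotspots$start > region_hotspots$end)) {
      abort_arg("region hotspot with start > end")
    }
    too_far <- region_hotspots$end > genes[region_hotspots$gene]
    if (any(too_far)) {
      abort_arg(sprintf(
        "region hotspot beyond protein length for gene(s): %s",
        paste(sQuote(unique(region_hotspots$gene[too_far])), collapse = ", ")
      ))
    }
  }
  allowed <- c(reference_source, test_source)
  bad_src <- setdiff(c(planted_sites$source, region_hotspots$source), allowed)
  if (length(bad_src)) {
    abort_arg(sprintf(
      "planted source(s) %s are neither the reference nor the test label",
      paste(sQuote(bad_src), collapse = ", ")
    ))
  }
  if (!is.numeric(background) || length(background) != 1 || background < 0) {
    abort_arg("`background` must be a single non-negative rate")
  }
  structure(
    list(
      genes = genes,
      planted_sites = planted_sites,
      region_hotspots = region_hotspots,
      background = background,
      seed = as.integer(seed),
      reference_source = reference_source,
      test_source = test_source
    ),
    class = "fixture_spec"
  )
}

#' Generate synthetic reference and test mutation tables
#'
#' Emits well-formed annotation strings (cycling deterministically through
#' substitution, nonsense, deletion, frameshift, duplication and insertion
#' templates) at the planted positions, distributes region-hotspot counts
#' round-robin over their intervals, and adds Poisson background
#' substitutions at uniform positions.  Pushing the result through
#' [annotate_positions()] and [count_sites()] recovers exactly the planted
#' counts plus the realized background.  Each record carries a synthetic
#' `Sample name` extra column.  The returned tables are labelled with the
#' spec's source names but deliberately carry no `Position` column: the
#' preparation step computes it.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `reference` and `test`, both
#'   `mutation_table`s.
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) {
    abort_arg("`spec` must be built with fixture_spec()")
  }
  withr::with_seed(spec$seed, {
    rows <- list()
    counter <- stats::setNames(
      rep(0L, 2), c(spec$reference_source, spec$test_source)
    )
    emit <- function(gene, position, source, n_records) {
      L <- spec$genes[[gene]]
      ann <- vapply(seq_len(n_records), function(i) {
        .annotation_template(position, i, L)
      }, character(1))
      ids <- sprintf("%s-S%05d", source, counter[[source]] + seq_len(n_records))
      counter[[source]] <<- counter[[source]] + n_records
      tibble::tibble(
        `Gene name` = gene, `Mutation AA` = ann, Source = source,
        `Sample name` = ids
      )
    }
    for (i in seq_len(nrow(spec$planted_sites))) {
      s <- spec$planted_sites[i, ]
      rows[[length(rows) + 1L]] <- emit(s$gene, s$position, s$source, s$count)
    }
    for (i in seq_len(nrow(spec$region_hotspots))) {
      r <- spec$region_hotspots[i, ]
      span <- r$end - r$start + 1L
      positions <- r$start + (seq_len(r$count) - 1L) %% span
      for (p in unique(positions)) {
        rows[[length(rows) + 1L]] <-
          emit(r$gene, p, r$source, sum(positions == p))
      }
    }
    if (spec$background > 0) {
      for (source in c(spec$reference_source, spec$test_source)) {
        for (gene in names(spec$genes)) {
          n_bg <- stats::rpois(1L, spec$background)
          if (n_bg == 0) next
          positions <- sample.int(spec$genes[[gene]], n_bg, replace = TRUE)
          for (p in positions) {
            rows[[length(rows) + 1L]] <- emit(gene, p, source, 1L)
          }
        }
      }
    }
    all_rows <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(`Gene name` = character(), `Mutation AA` = character(),
                     Source = character(), `Sample name` = character())
    split_tbl <- function(source) {
      as_mutation_table(
        all_rows[all_rows$Source == source, , drop = FALSE],
        provenance = tibble::tibble(path = "<generated>", source = source)
      )
    }
    list(
      reference = split_tbl(spec$reference_source),
      test = split_tbl(spec$test_source)
    )
  })
}

#' Check that planted hotspots survive the pipeline
#'
#' End-to-end self-test: verifies, for site counts produced by the
#' pipeline on tables from [generate_fixture()], that every planted site
#' with `count >= min_count` survives [apply_threshold()] and that no
#' non-planted (background) site reaches the threshold.
#'
#' @param spec The [fixture_spec()] the tables came from.
#' @param counts `site_counts` computed from the generated (annotated,
#'   merged) tables.
#' @param min_count Threshold to check against.
#' @return A list with `sites` (planted sites tibble plus `observed` and
#'   `survives` columns), `n_expected_survivors`, `n_false_survivors`
#'   (non-planted sites at or above threshold), and `all_recovered`.
#' @export
recover_planted <- function(spec, counts, min_count) {
  planted <- spec$planted_sites
  expected <- planted
  # realized per-position counts of region hotspots are planted too
  if (nrow(spec$region_hotspots)) {
    reg <- lapply(seq_len(nrow(spec$region_hotspots)), function(i) {
      r <- spec$region_hotspots[i, ]
      span <- r$end - r$start + 1L
      positions <- r$start + (seq_len(r$count) - 1L) %% span
      tibble::tibble(
        gene = r$gene,
        position = as.integer(sort(unique(positions))),
        source = r$source,
        count = as.integer(table(positions)[as.character(sort(unique(positions)))])
      )
    })
    expected <- dplyr::bind_rows(expected, dplyr::bind_rows(reg))
  }
  # same site may be planted twice; pool
  expected <- expected |>
    dplyr::group_by(.data$gene, .data$position, .data$source) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  surv <- apply_threshold(counts, min_count)
  key <- function(d) paste(d$gene, d$position, d$source, sep = "\r")
  observed <- counts$count[match(key(expected), key(counts))]
  observed[is.na(observed)] <- 0L
  sites <- expected
  sites$observed <- observed
  sites$survives <- key(expected) %in% key(surv)
  false_survivors <- sum(!(key(surv) %in% key(expected)))
  list(
    sites = sites,
    n_expected_survivors = sum(expected$count >= min_count),
    n_false_survivors = false_survivors,
    all_recovered = all((expected$count >= min_count) == sites$survives)
  )
}

#' Bundled default fixture: scaled-down driver-gene landscape
#'
#' Eight well-known driver genes at their real protein lengths, with a
#' large "COSMIC"-labelled reference carrying dominant single-site
#' hotspots (a BRAF-like site at 600, an IDH1-like site at 132, TP53
#' DNA-binding-domain sites) and region hotspots (NFE2L2-like regions
#' 23-48 and 71-86, a KIT-like region), plus a small "UCEC"-labelled test
#' cohort whose mutations are individually rare (1-3 entries per site)
#' but overlap the reference regions — the configuration the overlay
#' method is designed to surface.  All counts are synthetic, scaled far
#' below real compendium sizes.
#'
#' @param seed Integer seed (default 20140101).
#' @param background Background rate per gene per source (default 5).
#' @return A [fixture_spec()].
#' @export
default_fixture_spec <- function(seed = 20140101L, background = 5) {
  genes <- c(
    TP53 = 393L, PTEN = 403L, CTNNB1 = 781L, NFE2L2 = 605L,
    BRAF = 766L, IDH1 = 414L, KIT = 976L, EGFR = 1210L
  )
  planted <- tibble::tribble(
    ~gene,     ~position, ~source,  ~count,
    "BRAF",     600L,     "COSMIC", 120L,
    "IDH1",     132L,     "COSMIC",  85L,
    "TP53",     273L,     "COSMIC",  60L,
    "TP53",     248L,     "COSMIC",  45L,
    "TP53",     175L,     "COSMIC",  30L,
    "PTEN",     130L,     "COSMIC",  40L,
    "PTEN",     173L,     "COSMIC",  35L,
    "CTNNB1",    45L,     "COSMIC",  30L,
    "KIT",      816L,     "COSMIC",  25L,
    "EGFR",     746L,     "COSMIC",  50L,
    "TP53",     273L,     "UCEC",     3L,
    "TP53",     248L,     "UCEC",     2L,
    "PTEN",     130L,     "UCEC",     2L,
    "PTEN",     173L,     "UCEC",     1L,
    "CTNNB1",    45L,     "UCEC",     2L,
    "NFE2L2",    29L,     "UCEC",     2L,
    "NFE2L2",    79L,     "UCEC",     3L,
    "NFE2L2",    82L,     "UCEC",     1L,
    "IDH1",     132L,     "UCEC",     1L,
    "EGFR",     746L,     "UCEC",     1L
  )
  regions <- tibble::tribble(
    ~gene,     ~start, ~end, ~source,  ~count,
    "NFE2L2",    23L,   48L, "COSMIC",  40L,
    "NFE2L2",    71L,   86L, "COSMIC",  30L,
    "KIT",      550L,  590L, "COSMIC",  35L,
    "BRAF",     460L,  480L, "COSMIC",  20L
  )
  fixture_spec(
    genes = genes, planted_sites = planted, region_hotspots = regions,
    background = background, seed = seed,
    reference_source = "COSMIC", test_source = "UCEC"
  )
}
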