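# mutoverlay

Overlay visualization of recurrent somatic mutation sites and regions.

## The problem

Somatic driver mutations are usually recognized by recurrence: the same
amino-acid position mutated again and again across tumors (hotspot *sites*
such as BRAF V600 or IDH1 R132), or a contiguous stretch of positions each
mutated rarely but collectively often (hotspot *regions*). Frequency
filters applied within a single cohort miss both patterns when the cohort
is small: a mutation seen once or twice in your samples can still sit
squarely on a hotspot of a large pan-cancer compendium — strong evidence
of functional relevance.

`mutoverlay` makes that comparison visual. It takes two mutation tables —
a large *reference* set (e.g. a COSMIC export) and a small *test* set
(e.g. a cohort's mutation calls) — and renders, per gene, the recurrence
count of every mutated amino-acid position, with the test set drawn as
large salient points on top of the reference cloud. Hotspot sites and
regions are identified by eye; no significance statistic is computed,
which keeps the method agnostic to upstream calling pipelines and to the
within- vs across-cancer frequency question.

For each source *s*, gene *g* and 1-based amino-acid position *p*, the
plotted quantity is the **count of position**

  n(g, p, s) = #{ entries of source s in gene g whose protein change starts at residue p },

where the position of a non-substitution change (deletion, insertion,
frameshift, ...) is the first residue it affects: `p.E746_A750del` counts
at 746. Counts are per database entry, not per unique patient, because
compendia like COSMIC lack a reliable sample denominator.

The package covers the whole workflow:

- **parse** — `parse_mutation_aa()`, `annotate_positions()`: HGVS-style
  protein annotations (`p.V600E`, `p.G12fs*2`, `Val600Glu`, ...) to
  positions and mutation classes, totally (typed failures, nothing thrown);
- **tables** — `read_mutation_table()`, `set_source()`, `merge_tables()`,
  `exclude_samples()`, `write_mutation_table()`: the four-column schema
  `Gene name`, `Mutation AA`, `Position`, `Source` (+ pass-through extras),
  TSV/CSV, MAF-like inputs via a column map, self-reference exclusion;
- **aggregate** — `count_sites()`, `apply_threshold()`, `top_sites()`;
- **viz** — `build_overlay()`, `render_static()` (SVG/PNG),
  `render_interactive()` (self-contained HTML with per-point tooltips);
- **query** — `select_region()`, `export_underlying()`: drill-down export
  of the records behind a region, ranked by source then position;
- **fixtures** — `fixture_spec()`, `generate_fixture()`: synthetic tables
  with planted hotspots, so everything is testable without licensed data.

## Worked example

The repository bundles a small synthetic fixture (`inst/extdata/`): a
"COSMIC"-labelled reference with planted hotspots and a "UCEC"-labelled
test cohort whose mutations are individually rare but overlap the
reference's hotspot regions.

```r
library(mutoverlay)

ref_raw  <- system.file("extdata", "synthetic_reference.tsv", package = "mutoverlay")
test_raw <- system.file("extdata", "synthetic_test.tsv",      package = "mutoverlay")
dir <- tempdir()

cmd_prepare(ref_raw,  file.path(dir, "ref.tsv"),  "COSMIC")
#> prepared 686 records (COSMIC): ok=686, no_position=0, wildtype_or_unknown=0, malformed=0
cmd_prepare(test_raw, file.path(dir, "test.tsv"), "UCEC")
#> prepared 62 records (UCEC): ok=62, no_position=0, wildtype_or_unknown=0, malformed=0
m <- cmd_merge(file.path(dir, "ref.tsv"), file.path(dir, "test.tsv"),
               file.path(dir, "combined.tsv"))
#> merged 686 reference + 62 test records (0 excluded from reference)

counts <- count_sites(m$table)
top_sites(counts, "BRAF", "COSMIC", 3)
#> # A tibble: 3 × 4
#>   gene  position source count
#>   <chr>    <int> <chr>  <int>
#> 1 BRAF       600 COSMIC   120
#> 2 BRAF         3 COSMIC     1
#> 3 BRAF       252 COSMIC     1
```

The dominant BRAF site sits at position 600 with 120 entries against a
background of singletons — a hotspot *site*. The overlay itself:

```r
spec <- build_overlay(counts, genes = c("TP53", "NFE2L2", "BRAF", "IDH1"),
                      roles = c(reference = "COSMIC", test = "UCEC"))
render_static(spec, "overlay.svg")          # small blue ref, large orange test
render_interactive(spec, "overlay.html")    # hover shows gene/position/source/count
```

Drill-down into a hotspot *region* the test cohort touches:

```r
sel <- select_region(m$table, region_query("NFE2L2", 23, 48))
nrow(sel)
#> [1] 42
export_underlying(sel, "nfe2l2_23_48.tsv")  # ranked by source, then position
```

42 records underlie NFE2L2 residues 23–48; the UCEC test entries there are
each seen only once or twice, yet the region is densely mutated in the
reference — exactly the pattern per-cohort recurrence filters miss.

The same workflow is available from a shell via the bundled script:

```sh
Rscript inst/cli/mutoverlay.R prepare --input ref.tsv --output prep.tsv --source COSMIC
Rscript inst/cli/mutoverlay.R plot --input combined.tsv --genes BRAF,IDH1 \
    --min-count 10 --svg overlay.svg --html overlay.html
```

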