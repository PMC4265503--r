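---
title: "Identifying mutation hotspots by overlay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying mutation hotspots by overlay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutoverlay)
```

## The method

Driver mutations are positively selected during tumor evolution and tend
to recur — either at a single amino-acid position (a hotspot *site*, the
BRAF V600 / IDH1 R132 pattern) or spread across a contiguous stretch of
positions that is collectively, but not site-wise, recurrent (a hotspot
*region*). A mutation observed once in a small cohort carries little
evidence on its own; the same mutation observed to land on a position or
region that a large pan-cancer compendium mutates hundreds of times is a
different matter.

`mutoverlay` operationalizes this as a visualization, not a test. The
pipeline is:

1. **Position extraction.** Each protein-level annotation string is parsed
   to the 1-based position of the *first* residue the alteration affects.
   A substitution `p.R132H` maps to 132; a deletion `p.E746_A750del` maps
   to its left endpoint 746; a frameshift `p.G12fs*2` to 12. Using the
   left endpoint for multi-residue events is a deliberate collapse: it
   keeps every event representable as a single x-coordinate at the cost of
   under-representing the footprint of long deletions.
2. **Counting.** For every (gene, position, source) triple the package
   counts contributing entries. Sources are never pooled — the separation
   of reference counts from test counts *is* the method. Distinct
   amino-acid changes at one position (V600E, V600K) pool into one site,
   because the unit of interpretation is the position.
3. **Overlay.** Per gene facet, reference sites are drawn as small muted
   points and test sites as larger salient points on top (the z-order is a
   contract, not a styling accident: rare test points must never be hidden
   under the reference cloud). Hotspots are identified by eye.
4. **Drill-down.** Any gene region can be materialized as the records
   behind it, exported ranked by source then position, for downstream
   scrutiny (which cancers, which samples, which exact changes).

### Assumptions and what the y-axis means

The y value is a raw entry count. Compendia such as COSMIC carry no
definitive per-mutation sample denominator and contain redundant entries
(cell lines, re-submissions), so a proportion would suggest precision the
data cannot support; we count entries and document the caveat rather than
deduplicate. Consequences: counts are comparable *within* a source, and
the overlay is a qualitative instrument — "this test mutation lands where
the reference is dense" — not an estimator of mutation frequency.

If the test cohort's calls are already part of the reference compendium,
overlap is circular. `exclude_samples()` removes the cohort's records
from the reference by any identifier column before merging
(self-reference exclusion). The identifier column is a parameter because
export dialects name it differently.

## The annotation parser

The parser is *total*: any string yields a typed result, never an error,
because real mutation tables are messy and a single bad row must not kill
a 1.5-million-row preparation run. Dialect decisions:

- `p.`-prefixed and bare annotations are both accepted; MAF exports often
  drop the prefix. Parenthesized predictions (`p.(V600E)`) are unwrapped.
- Three-letter residue codes (`Val600Glu`) normalize to one-letter;
  residue case is ignored. `*` and `X` are valid stop tokens: `p.R661*`
  and `p.Q61X` are nonsense changes; the stop-loss `p.*757L` parses to
  position 757 with class `other`.
- Compound deletion–insertions (`p.E746_A750delinsQ`) map to class
  `complex` at the left endpoint — consistent with the
  first-affected-residue rule, though dialects differ in how they encode
  these.
- `p.?`, `p.unknown`, `p.0`, `p.0?`, `p.=` assert absence of information
  or of change, not a site: `wildtype_or_unknown`, no position. We extend
  the same reading to silent changes written with a position (`p.V600=`):
  they name a residue but assert no alteration there, so counting them as
  mutated sites would inflate hotspots with synonymous calls.
- A class keyword without any residue number (`p.del`) is `no_position`;
  a string with no interpretable residue-number pattern is `malformed`.
  Both are retained in the table with an empty `Position`, tallied in the
  parse report, and excluded from counting — never dropped silently.

Out of scope by design: reference-sequence validation, nucleotide-level
(c./g.) notation, and transcript selection. The parser trusts the
annotation it is given.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `min_count` | `apply_threshold()` | 1 (no filter) | The method's point is surfacing *low*-frequency test mutations; filtering is opt-in. 10 is a sensible browsing preset when looking at a large reference alone, and is the value exercised throughout the tests. |
| `per_source` | `apply_threshold()` | unset | Lets a strict reference threshold coexist with an unfiltered test set (e.g. `c(COSMIC = 10, UCEC = 1)`). |
| `roles` | `build_overlay()` | inferred | With one source, it is the reference; with two and no mapping, the source with more total entries is taken as reference (the compendium is the big set), ties lexicographic. Explicit mapping overrides; >2 sources require one. |
| point sizes | style | 4 px ref / 10 px test | Only the ordering (test strictly larger, drawn above) is contractual; magnitudes are style. |
| colors | style | blue ref / orange test | Convention for muted-vs-salient; swappable without affecting z-order. |
| `y_log` | style | linear | Counts are the quantity of interest; a log axis is opt-in for genes whose dominant site dwarfs the rest. |
| intervals | `region_query()` | closed | Regions quoted as residue ranges ("23–48") read naturally as closed intervals. |

## Rendering: numerical and format choices

The SVG and HTML renderers are written by the package so their output is
a contract: every site count serializes as exactly one
`<circle class="marker">` carrying `data-gene`, `data-position`,
`data-source`, `data-count`; reference circles precede test circles
within each facet; coordinates are formatted with fixed two-decimal
`sprintf`, so rendering a spec twice is byte-identical (no timestamps, no
run-dependent ids). The interactive HTML is a single self-contained file:
inline SVG, an embedded JSON payload of all points, and a few lines of
vanilla JavaScript for tooltips and horizontal range selection — it can
be mailed or published as-is. PNG output delegates to ggplot2 and is for
figures, not for machine consumption.

Facets stack vertically with gene names on the left; y-scales are
independent per facet, since maximum counts differ by orders of magnitude
between genes. Coincident reference points at the same (position, count)
are plotted faithfully without jitter: overplotting within one series is
acceptable because the marker of interest (test) is on top and larger.
Degenerate inputs are rendered, not rejected: a requested gene with no
sites yields a labelled empty facet, an empty count set a valid empty
figure.

Drill-down export sorts by source (ascending lexicographic, C locale —
the rank order between sources is a presentation choice, so we fix the
simplest reproducible one) then position, with ties stable in input
order.

## The synthetic fixture: what it emulates, what it does not

`fixture_spec()` / `generate_fixture()` produce a reference and a test
table with: planted single-site hotspots (a fixed count at a fixed
position), planted region hotspots (a total count distributed round-robin
over a closed interval — deterministic, so exact recovery is checkable),
and a homogeneous background (per gene and source, a Poisson number of
entries at uniform positions). Annotation strings cycle deterministically
through substitution, nonsense, deletion, frameshift, duplication and
insertion templates so the parser's classes are exercised without
randomizing class choice. Generation is bit-reproducible under the seed.

The bundled default (`default_fixture_spec()`) plants a scaled-down
driver landscape across eight genes at their real protein lengths: a
dominant site at BRAF 600 (120 entries) and IDH1 132 (85), TP53
DNA-binding-domain sites, NFE2L2 regions 23–48 and 71–86, a KIT region —
against a background of 5 entries per gene per source — and a test cohort
whose planted sites carry only 1–3 entries each but overlap the reference
hotspots. That is the configuration the overlay exists to surface, at
roughly 750 records total, small enough that the full workflow (including
50-seed property sweeps in the tests and the acceptance script) runs in
seconds.

What the generator does *not* emulate: mutational signatures and sequence
context, per-gene mutability covariates (expression, replication timing),
sample redundancy, annotation errors beyond the parser's typed-failure
classes, and the sheer scale of real compendia. Passing tests therefore
demonstrate the pipeline's correctness contracts (conservation,
threshold semantics, rendering bijection, sort rules), not robustness to
the full messiness of production mutation tables.

## Known limitations

- Visual identification only: no binomial/Poisson hotspot statistic, no
  multiple-testing machinery. The package deliberately stops where
  interpretation starts.
- Entry counting inherits compendium biases: over-represented cancer
  types and redundant samples inflate counts.
- First-residue positioning under-represents long deletions' footprints.
- Gene symbols are matched exactly and case-sensitively; no alias
  resolution. Rows whose symbols disagree between sources will not
  overlay.
- Duplicate rows are retained by design; if your input contains
  accidental duplicates, deduplicate upstream.
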