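# Protein-level mutation annotation parsing (COSMIC "Mutation AA" dialect).

# Three-letter residue codes -> one-letter, HGVS Ter -> "*".
.AA3 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

.PARSE_STATUSES <- c("ok", "no_position", "wildtype_or_unknown", "malformed")
.MUTATION_CLASSES <- c(
  "substitution", "nonsense", "deletion", "insertion", "duplication",
  "frameshift", "start_lost", "complex", "other"
)

.normalize_residues <- function(x) {
  for (code in names(.AA3)) {
    x <- gsub(code, .AA3[[code]], x, ignore.case = TRUE, fixed = FALSE)
  }
  x
}

#' Parse protein-level mutation annotations into amino-acid positions
#'
#' Converts annotation strings in the COSMIC "Mutation AA" dialect of HGVS
#' protein notation (e.g. `"p.V600E"`, `"p.E746_A750del"`, `"p.G12fs*2"`)
#' into 1-based amino-acid positions and mutation classes.  The position of
#' a non-substitution mutation is the first residue at which the alteration
#' occurs: for range notations (`A_B`) the left endpoint is used.
#'
#' The parser is total: every input string yields a result row and nothing
#' is thrown.  Failures are typed in `status`:
#' \describe{
#'   \item{`ok`}{a position was extracted; `position` and `mutation_class`
#'     are filled.}
#'   \item{`wildtype_or_unknown`}{the annotation asserts no change or an
#'     unknown consequence (`"p.?"`, `"p.unknown"`, `"p.0"`, `"p.0?"`,
#'     `"p.="`, silent changes such as `"p.V600="`).}
#'   \item{`no_position`}{a mutation-class keyword (del/ins/dup/fs) is
#'     present but no residue number is.}
#'   \item{`malformed`}{no interpretable residue-number pattern at all
#'     (includes the empty string).}
#' }
#'
#' Both `"p."`-prefixed and bare annotations (`"V600E"`) are accepted;
#' three-letter residue codes (`"p.Val600Glu"`) are normalized; residue
#' letters are matched case-insensitively.  `"*"` and `"X"` are valid
#' residue tokens: `"p.R661*"` is a nonsense change at 661, while the
#' stop-loss `"p.*757L"` parses to position 757 with class `"other"`.
#'
#' @param annotation Character vector of annotation strings (may be empty
#'   strings or `NA`; `NA` is treated as malformed).
#' @return A tibble with one row per input and columns `raw` (the input,
#'   preserved byte-for-byte), `status`, `position` (integer, `NA` unless
#'   `status == "ok"`), and `mutation_class` (`NA` unless `status == "ok"`).
#' @examples
#' parse_mutation_aa(c("p.V600E", "p.R132H", "p.E746_A750del", "p.?"))
#' @export
parse_mutation_aa <- function(annotation) {
  raw <- as.character(annotation)
  n <- length(raw)
  status <- rep("malformed", n)
  position <- rep(NA_integer_, n)
  mclass <- rep(NA_character_, n)
  if (n == 0L) {
    return(tibble::tibble(
      raw = character(), status = character(),
      position = integer(), mutation_class = character()
    ))
  }

  x <- raw
  x[is.na(x)] <- ""
  x <- trimws(x)
  x <- sub("^[pP]\\.", "", x)
  x <- sub("^\\((.+)\\)$", "\\1", x)   # predicted consequences: p.(V600E)
  y <- toupper(.normalize_residues(x))

  wt <- y %in% c("?", "0", "0?", "=", "UNKNOWN", "WT") |
    grepl("^[A-Z*][0-9]+=$", y)        # silent: V600=
  status[wt] <- "wildtype_or_unknown"

  # First residue token followed by an integer -> position.
  m <- regexpr("[A-Z*][0-9]+", y)
  tok <- rep(NA_character_, n)
  tok[m > 0L] <- regmatches(y, m)
  found <- m > 0L & !wt
  first_res <- substr(tok, 1L, 1L)
  pos <- suppressWarnings(as.integer(sub("^[A-Z*]", "", tok)))
  found <- found & !is.na(pos) & pos >= 1L

  status[found] <- "ok"
  position[found] <- pos[found]

  cls <- rep("other", n)
  cls[grepl("^[A-Z][0-9]+[A-Z]$", y)] <- "substitution"
  cls[grepl("^[A-Z][0-9]+[*X]$", y)] <- "nonsense"
  cls[grepl("EXT", y, fixed = TRUE)] <- "other"
  cls[grepl("DUP", y, fixed = TRUE)] <- "duplication"
  cls[grepl("INS", y, fixed = TRUE)] <- "insertion"
  cls[grepl("DEL", y, fixed = TRUE)] <- "deletion"
  cls[grepl("DELINS", y, fixed = TRUE)] <- "complex"
  cls[grepl("FS", y, fixed = TRUE)] <- "frameshift"
  cls[first_res == "*" & !is.na(first_res)] <- "other"   # stop-loss
  cls[grepl("^M1\\??$", y)] <- "start_lost"
  mclass[found] <- cls[found]

  # Class keyword but no residue number: typed failure, not malformed.
  kw_only <- !found & !wt & grepl("DEL|INS|DUP|FS", y)
  status[kw_only] <- "no_position"

  tibble::tibble(
    raw = raw, status = status,
    position = position, mutation_class = mclass
  )
}

#' Annotate a mutation table with amino-acid positions
#'
#' Applies [parse_mutation_aa()] to the `Mutation AA` column and fills the
#' `Position` column, mirroring the preparation step in which positions are
#' appended to a COSMIC-style export.  Unparseable records are retained
#' with `Position = NA` (they are flagged in the parse report and excluded
#' from downstream counting, never dropped silently).  The operation is
#' idempotent and preserves input order and all other columns.
#'
#' @param table A mutation table (see [read_mutation_table()]).
#' @param recompute If `FALSE` (default) positions already present in the
#'   table are trusted and only missing ones are filled; if `TRUE` every
#'   position is recomputed from the annotation string.
#' @return The table with a filled `Position` column and a `parse_report`
#'   attribute (named integer vector of per-status tallies), retrievable
#'   with [parse_report()].
#' @export
annotate_positions <- function(table, recompute = FALSE) {
  if (!"Mutation AA" %in% names(table)) {
    abort_schema("column 'Mutation AA' is missing; cannot annotate positions")
  }
  parsed <- parse_mutation_aa(table[["Mutation AA"]])
  existing <- if ("Position" %in% names(table)) {
    suppressWarnings(as.integer(table[["Position"]]))
  } else {
    rep(NA_integer_, nrow(table))
  }
  table[["Position"]] <- if (recompute) {
    parsed$position
  } else {
    ifelse(is.na(existing), parsed$position, existing)
  }
  report <- vapply(
    .PARSE_STATUSES, function(s) sum(parsed$status == s), integer(1)
  )
  out <- as_mutation_table(table, provenance = provenance(table))
  attr(out, "parse_report") <- report
  out
}

#' Retrieve the parse report attached by [annotate_positions()]
#'
#' @param table An annotated mutation table.
#' @return Named integer vector with one tally per parse status
#'   (`ok`, `no_position`, `wildtype_or_unknown`, `malformed`), or `NULL`
#'   if the table has not been annotated.
#' @export
parse_report <- function(table) {
  attr(table, "parse_report", exact = TRUE)
}
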