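# Overlay figure specification: reference sites as small muted points
# beneath test sites as large salient points, y = count of position,
# x = amino-acid position, one facet per gene.

.default_style <- function() {
  list(
    reference = list(color = "#3B6FB6", size = 4),   # small blue
    test      = list(color = "#E6791E", size = 10),  # intentionally large orange
    width = 900,
    facet_height = 150,
    y_log = FALSE
  )
}

#' Build an overlay figure specification from site counts
#'
#' Lays out one facet per requested gene (facets for genes absent from the
#' counts are rendered empty) and at most two layered point series: the
#' reference series drawn first (small, blue by default) and the test
#' series drawn above it (large, orange by default) so that rare test
#' mutations are never occluded by the reference cloud.  Every plotted
#' point corresponds to exactly one site count.
#'
#' @param counts A `site_counts` tibble from [count_sites()], containing at
#'   most two distinct source labels (or more if `roles` picks two).
#' @param genes Character vector of gene symbols, in facet order.
#' @param roles Optional named character vector mapping roles to source
#'   labels, e.g. `c(reference = "COSMIC", test = "UCEC")`.  When omitted:
#'   a single source becomes the reference (reference-only browsing is
#'   valid); with exactly two sources the one with the larger total entry
#'   count is taken as the reference (the reference compendium is the big
#'   set), ties broken lexicographically.  More than two sources without a
#'   role mapping is a configuration error.
#' @param style Optional list of style overrides merged over the defaults:
#'   `reference`/`test` sublists with `color` and `size` (pixels),
#'   `width`, `facet_height` (pixels), `y_log` (logical, opt-in log10
#'   count axis).
#' @param tooltip_fields Order of the per-point hover fields; a permutation
#'   of a subset of `c("gene", "position", "source", "count")`.
#' @return An `overlay_spec` object.
#' @export
build_overlay <- function(counts, genes, roles = NULL, style = NULL,
                          tooltip_fields = c("gene", "position",
                                             "source", "count")) {
  if (length(genes) == 0 || !is.character(genes)) {
    abort_arg("`genes` must be a non-empty character vector")
  }
  if (!all(tooltip_fields %in% c("gene", "position", "source", "count"))) {
    abort_arg("tooltip fields must be drawn from gene, position, source, count")
  }
  sources <- unique(counts$source)

  if (is.null(roles)) {
    if (length(sources) > 2) {
      abort_arg(paste0(
        "counts contain more than two sources (",
        paste(sQuote(sources), collapse = ", "),
        "); supply `roles = c(reference = ..., test = ...)`"
      ))
    }
    if (length(sources) <= 1) {
      roles <- c(reference = if (length(sources)) sources else NA_character_)
    } else {
      totals <- vapply(sources, function(s) sum(counts$count[counts$source == s]),
                       numeric(1))
      ord <- order(-totals, sources, method = "radix")
      roles <- c(reference = sources[ord[1]], test = sources[ord[2]])
    }
  } else {
    if (is.null(names(roles)) ||
        !all(names(roles) %in% c("reference", "test")) ||
        !"reference" %in% names(roles)) {
      abort_arg("`roles` must be named with 'reference' and optionally 'test'")
    }
    unknown <- setdiff(roles, sources)
    if (length(unknown) > 0 && nrow(counts) > 0) {
      abort_arg(sprintf("role mapping names unknown source%s: %s",
                        if (length(unknown) > 1) "s" else "",
                        paste(sQuote(unknown), collapse = ", ")))
    }
    unmapped <- setdiff(sources, roles)
    if (length(unmapped) > 0) {
      abort_arg(sprintf("source%s %s not covered by the role mapping",
                        if (length(unmapped) > 1) "s" else "",
                        paste(sQuote(unmapped), collapse = ", ")))
    }
  }

  sty <- utils::modifyList(.default_style(), if (is.null(style)) list() else style)

  data <- counts[counts$gene %in% genes, , drop = FALSE]
  role_of <- stats::setNames(names(roles), roles)
  data$role <- unname(role_of[data$source])
  data <- data[order(match(data$gene, genes), data$position,
                     match(data$role, c("reference", "test")),
                     method = "radix"), , drop = FALSE]

  series <- list(reference = list(
    source = unname(roles[["reference"]]),
    color = sty$reference$color, size = sty$reference$size, zorder = 1L
  ))
  if ("test" %in% names(roles)) {
    series$test <- list(
      source = unname(roles[["test"]]),
      color = sty$test$color, size = sty$test$size, zorder = 2L
    )
  }

  structure(
    list(
      facets = genes,
      data = tibble::as_tibble(data),
      series = series,
      axes = list(x = "Amino-acid position", y = "Count of position",
                  y_log = isTRUE(sty$y_log)),
      tooltip_fields = tooltip_fields,
      style = sty
    ),
    class = "overlay_spec"
  )
}

#' @export
print.overlay_spec <- function(x, ...) {
  cat(sprintf("overlay spec: %d facet(s) [%s]\n",
              length(x$facets), paste(x$facets, collapse = ", ")))
  for (role in names(x$series)) {
    s <- x$series[[role]]
    cat(sprintf("  %-9s source=%s color=%s size=%spx (z=%d)\n",
                role, s$source, s$color, s$size, s$zorder))
  }
  cat(sprintf("  %d point(s); tooltip: %s\n",
              nrow(x$data), paste(x$tooltip_fields, collapse = ", ")))
  invisible(x)
}
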