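# Renderers for overlay specs.  The SVG and HTML writers are implemented
# directly so that output is byte-deterministic (no timestamps, no
# device-run-dependent element ids) and markers stay machine-checkable:
# every site count becomes exactly one <circle class="marker"> carrying its
# gene/position/source/count as data attributes, reference circles are
# serialized before test circles (document order = z-order).  PNG output
# goes through ggplot2.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

.fmt <- function(v) sprintf("%.2f", v)

# Shared geometry for the SVG/HTML renderers.
.overlay_svg <- function(spec, standalone = TRUE) {
  sty <- spec$style
  margin <- list(left = 110, right = 25, top = 15, bottom = 35)
  fh <- sty$facet_height
  plot_w <- sty$width - margin$left - margin$right
  n_facets <- length(spec$facets)
  total_h <- margin$top + n_facets * fh + margin$bottom

  data <- spec$data
  xmax <- max(c(data$position, 10)) * 1.04
  y_log <- isTRUE(spec$axes$y_log)
  yval <- function(count) if (y_log) log10(count + 1) else count

  sx <- function(p) margin$left + (p / xmax) * plot_w

  lines <- character()
  push <- function(...) lines[[length(lines) + 1L]] <<- paste0(...)

  if (standalone) {
    push("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  }
  push(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
           "height=\"%d\" viewBox=\"0 0 %d %d\" font-family=\"sans-serif\">"),
    sty$width, total_h, sty$width, total_h
  ))
  push("<rect width=\"100%\" height=\"100%\" fill=\"#FFFFFF\"/>")

  for (i in seq_along(spec$facets)) {
    gene <- spec$facets[[i]]
    top <- margin$top + (i - 1L) * fh
    plot_h <- fh - 20
    fdata <- data[data$gene == gene, , drop = FALSE]
    ymax <- if (nrow(fdata)) max(yval(fdata$count)) else 1
    if (ymax <= 0) ymax <- 1
    ymax <- ymax * 1.1
    sy <- function(count) top + 10 + plot_h - (yval(count) / ymax) * plot_h

    push(sprintf("<g class=\"facet\" data-gene=\"%s\">", .xml_escape(gene)))
    # frame and gene label
    push(sprintf(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"none\" stroke=\"#CCCCCC\"/>",
      .fmt(margin$left), .fmt(top + 10), .fmt(plot_w), .fmt(plot_h)
    ))
    push(sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"end\" font-size=\"13\" fill=\"#222222\">%s</text>",
      .fmt(margin$left - 10), .fmt(top + 10 + plot_h / 2), .xml_escape(gene)
    ))
    # per-facet y-axis maximum (counts scale independently per gene)
    ylab_max <- if (nrow(fdata)) max(fdata$count) else 0
    push(sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"end\" font-size=\"9\" fill=\"#888888\">%d</text>",
      .fmt(margin$left - 4), .fmt(top + 16), as.integer(ylab_max)
    ))
    push(sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"end\" font-size=\"9\" fill=\"#888888\">0</text>",
      .fmt(margin$left - 4), .fmt(top + 10 + plot_h)
    ))

    # series in z-order: reference first, test drawn above it
    for (role in c("reference", "test")) {
      s <- spec$series[[role]]
      if (is.null(s)) next
      push(sprintf("<g class=\"series series-%s\" data-source=\"%s\">",
                   role, .xml_escape(s$source)))
      sdata <- fdata[fdata$role == role, , drop = FALSE]
      if (nrow(sdata)) {
        for (j in seq_len(nrow(sdata))) {
          push(sprintf(
            paste0("<circle class=\"marker marker-%s\" cx=\"%s\" cy=\"%s\" ",
                   "r=\"%s\" fill=\"%s\" fill-opacity=\"0.85\" ",
                   "data-gene=\"%s\" data-position=\"%d\" data-source=\"%s\" ",
                   "data-count=\"%d\"/>"),
            role, .fmt(sx(sdata$position[j])), .fmt(sy(sdata$count[j])),
            .fmt(s$size / 2), s$color,
            .xml_escape(sdata$gene[j]), as.integer(sdata$position[j]),
            .xml_escape(sdata$source[j]), as.integer(sdata$count[j])
          ))
        }
      }
      push("</g>")
    }
    push("</g>")
  }

  # x axis along the bottom facet
  axis_y <- margin$top + n_facets * fh
  push(sprintf(
    "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#444444\"/>",
    .fmt(margin$left), .fmt(axis_y), .fmt(margin$left + plot_w), .fmt(axis_y)
  ))
  for (tick in pretty(c(0, xmax), n = 6)) {
    if (tick < 0 || tick > xmax) next
    push(sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"10\" fill=\"#444444\">%d</text>",
      .fmt(sx(tick)), .fmt(axis_y + 16), as.integer(tick)
    ))
  }
  push(sprintf(
    "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"11\" fill=\"#222222\">%s</text>",
    .fmt(margin$left + plot_w / 2), .fmt(axis_y + 30),
    .xml_escape(spec$axes$x)
  ))
  push("</svg>")
  lines
}

.overlay_ggplot <- function(spec) {
  data <- spec$data
  facets <- spec$facets
  scaffold <- tibble::tibble(
    gene = factor(facets, levels = facets), position = 1, count = 0
  )
  data$gene <- factor(data$gene, levels = facets)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$position,
                                          y = .data$count)) +
    ggplot2::geom_blank(data = scaffold) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$gene),
                        scales = "free_y") +
    ggplot2::labs(x = spec$axes$x, y = spec$axes$y) +
    ggplot2::theme_bw() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
  for (role in c("reference", "test")) {
    s <- spec$series[[role]]
    if (is.null(s)) next
    sdata <- data[data$role == role, , drop = FALSE]
    if (nrow(sdata) == 0) next
    p <- p + ggplot2::geom_point(
      data = sdata, color = s$color, size = s$size / 2.5, alpha = 0.85
    )
  }
  if (isTRUE(spec$axes$y_log)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Render an overlay spec to a static image
#'
#' SVG output is written directly by the package and is byte-deterministic:
#' rendering the same spec twice yields identical files.  Each site count
#' appears as exactly one `<circle class="marker">` at (position, count) in
#' its gene facet, carrying `data-gene`, `data-position`, `data-source` and
#' `data-count` attributes; reference markers precede test markers in
#' document order so the test series is never occluded.  PNG output is
#' rasterized with ggplot2.
#'
#' @param spec An [build_overlay()] spec.
#' @param path Output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @return `path`, invisibly.
#' @export
render_static <- function(spec, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (!inherits(spec, "overlay_spec")) {
    abort_arg("`spec` must be built with build_overlay()")
  }
  if (format == "svg") {
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) abort_io(sprintf(
                      "cannot write '%s': %s", path, conditionMessage(e))))
    on.exit(close(con))
    writeLines(.overlay_svg(spec, standalone = TRUE), con, sep = "\n",
               useBytes = TRUE)
  } else {
    grDevices::png(path, width = spec$style$width,
                   height = 120 + length(spec$facets) * spec$style$facet_height,
                   res = 96, type = "cairo")
    on.exit(grDevices::dev.off())
    print(.overlay_ggplot(spec))
  }
  invisible(path)
}

#' Render an overlay spec to a self-contained interactive HTML file
#'
#' Writes a single HTML file (no server, no external assets) embedding the
#' overlay as inline SVG plus a JSON payload of every point.  Hovering a
#' marker shows a tooltip with the gene name, amino-acid position, source
#' and count of position (order configurable in the spec); dragging a
#' horizontal selection within a facet lists the covered sites so the
#' selection can be exported as a region query with [select_region()].
#' Output is byte-deterministic for a fixed spec.
#'
#' @param spec An [build_overlay()] spec.
#' @param path Output HTML path.
#' @return `path`, invisibly.
#' @export
render_interactive <- function(spec, path) {
  if (!inherits(spec, "overlay_spec")) {
    abort_arg("`spec` must be built with build_overlay()")
  }
  payload <- jsonlite::toJSON(
    list(
      facets = spec$facets,
      tooltip_fields = spec$tooltip_fields,
      series = spec$series,
      points = spec$data
    ),
    auto_unbox = TRUE, digits = NA
  )
  field_labels <- c(gene = "Gene name", position = "Position",
                    source = "Source", count = "Count of position")
  labels_js <- jsonlite::toJSON(as.list(field_labels), auto_unbox = TRUE)

  html <- c(
    "<!DOCTYPE html>",
    "<html lang=\"en\">",
    "<head>",
    "<meta charset=\"utf-8\"/>",
    "<title>Mutation hotspot overlay</title>",
    "<style>",
    "body { font-family: sans-serif; margin: 1em; }",
    "#tooltip { position: absolute; display: none; background: #fff;",
    "  border: 1px solid #888; padding: 4px 8px; font-size: 12px;",
    "  pointer-events: none; box-shadow: 2px 2px 4px rgba(0,0,0,0.2); }",
    "#selection-info { font-size: 12px; color: #333; margin-top: 0.5em; }",
    ".marker:hover { stroke: #000; stroke-width: 1.5; }",
    "</style>",
    "</head>",
    "<body>",
    "<div id=\"plot\">",
    .overlay_svg(spec, standalone = FALSE),
    "</div>",
    "<div id=\"tooltip\"></div>",
    "<div id=\"selection-info\">Drag horizontally inside a facet to list the covered region.</div>",
    sprintf("<script type=\"application/json\" id=\"overlay-data\">%s</script>",
            payload),
    "<script>",
    sprintf("var spec = JSON.parse(document.getElementById('overlay-data').textContent);"),
    sprintf("var labels = %s;", labels_js),
    "var tip = document.getElementById('tooltip');",
    "document.querySelectorAll('.marker').forEach(function (m) {",
    "  m.addEventListener('mousemove', function (ev) {",
    "    var parts = spec.tooltip_fields.map(function (f) {",
    "      return labels[f] + ': ' + m.dataset[f];",
    "    });",
    "    tip.innerHTML = parts.join('<br/>');",
    "    tip.style.left = (ev.pageX + 12) + 'px';",
    "    tip.style.top = (ev.pageY + 12) + 'px';",
    "    tip.style.display = 'block';",
    "  });",
    "  m.addEventListener('mouseleave', function () {",
    "    tip.style.display = 'none';",
    "  });",
    "});",
    "var dragStart = null;",
    "var svg = document.querySelector('#plot svg');",
    "svg.addEventListener('mousedown', function (ev) { dragStart = ev; });",
    "svg.addEventListener('mouseup', function (ev) {",
    "  if (!dragStart) return;",
    "  var x0 = Math.min(dragStart.clientX, ev.clientX);",
    "  var x1 = Math.max(dragStart.clientX, ev.clientX);",
    "  var hits = [];",
    "  document.querySelectorAll('.marker').forEach(function (m) {",
    "    var r = m.getBoundingClientRect();",
    "    var cx = (r.left + r.right) / 2;",
    "    if (cx >= x0 && cx <= x1) {",
    "      hits.push(m.dataset.gene + ' ' + m.dataset.position + ' (' +",
    "                m.dataset.source + ', n=' + m.dataset.count + ')');",
    "    }",
    "  });",
    "  var info = document.getElementById('selection-info');",
    "  info.textContent = hits.length ?",
    "    'Selected sites: ' + hits.join('; ') :",
    "    'No sites in selection.';",
    "  dragStart = null;",
    "});",
    "</script>",
    "</body>",
    "</html>"
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_io(sprintf(
                    "cannot write '%s': %s", path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
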