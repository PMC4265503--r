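overlay_fixture <- function(seed = 77L) {
  tabs <- prepared_tables(small_fixture_spec(seed = seed, background = 3))
  counts <- count_sites(merge_tables(tabs$reference, tabs$test))
  build_overlay(counts, genes = c("GENEA", "GENEB"),
                roles = c(reference = "REF", test = "TEST"))
}

test_that("build_overlay assigns roles, facets and the layering contract", {
  spec <- overlay_fixture()
  expect_s3_class(spec, "overlay_spec")
  expect_equal(spec$facets, c("GENEA", "GENEB"))
  expect_equal(spec$series$reference$source, "REF")
  expect_equal(spec$series$test$source, "TEST")
  expect_gt(spec$series$test$zorder, spec$series$reference$zorder)
  expect_gt(spec$series$test$size, spec$series$reference$size)
  expect_equal(spec$tooltip_fields, c("gene", "position", "source", "count"))
})

test_that("a single-source count set builds a valid reference-only overlay", {
  tabs <- prepared_tables(small_fixture_spec(seed = 4L, background = 0))
  counts <- count_sites(tabs$reference)
  spec <- build_overlay(counts, genes = "GENEA")
  expect_equal(spec$series$reference$source, "REF")
  expect_null(spec$series$test)
})

test_that("without an explicit mapping the larger source becomes the reference", {
  counts <- tibble::tibble(
    gene = "G", position = c(1L, 2L, 3L),
    source = c("SMALL", "BIG", "BIG"), count = c(1L, 50L, 40L)
  )
  spec <- build_overlay(counts, genes = "G")
  expect_equal(spec$series$reference$source, "BIG")
  expect_equal(spec$series$test$source, "SMALL")
})

test_that("ambiguous or unknown role configurations are rejected", {
  counts <- tibble::tibble(
    gene = "G", position = 1:3, source = c("A", "B", "C"), count = 1:3
  )
  expect_error(build_overlay(counts, genes = "G"),
               class = "mutoverlay_arg_error")
  expect_error(
    build_overlay(counts, genes = "G",
                  roles = c(reference = "A", test = "NOPE")),
    class = "mutoverlay_arg_error"
  )
})

test_that("style overrides apply without breaking the z-order contract", {
  tabs <- prepared_tables(small_fixture_spec(seed = 9L, background = 0))
  counts <- count_sites(merge_tables(tabs$reference, tabs$test))
  spec <- build_overlay(
    counts, genes = "GENEA", roles = c(reference = "REF", test = "TEST"),
    style = list(reference = list(color = "#E6791E", size = 4),
                 test = list(color = "#3B6FB6", size = 10))
  )
  expect_equal(spec$series$reference$color, "#E6791E")
  expect_equal(spec$series$test$color, "#3B6FB6")
  expect_gt(spec$series$test$zorder, spec$series$reference$zorder)
})

test_that("SVG markers are in bijection with site counts and layered correctly", {
  spec <- overlay_fixture()
  path <- withr::local_tempfile(fileext = ".svg")
  render_static(spec, path, format = "svg")
  markers <- count_svg_markers(path)
  expect_length(markers$all, nrow(spec$data))
  expect_length(markers$reference, sum(spec$data$role == "reference"))
  expect_length(markers$test, sum(spec$data$role == "test"))

  # each marker carries its full site count as data attributes
  got <- data.frame(
    gene = xml2::xml_attr(markers$all, "data-gene"),
    position = as.integer(xml2::xml_attr(markers$all, "data-position")),
    source = xml2::xml_attr(markers$all, "data-source"),
    count = as.integer(xml2::xml_attr(markers$all, "data-count"))
  )
  want <- as.data.frame(spec$data[c("gene", "position", "source", "count")])
  key <- function(d) sort(paste(d$gene, d$position, d$source, d$count))
  expect_equal(key(got), key(want))

  # document order: within the raw text, the last reference marker
  # precedes the first test marker within each facet
  txt <- readLines(path)
  ref_lines <- grep("marker-reference", txt)
  test_lines <- grep("marker-test", txt)
  facet_starts <- grep("class=\"facet\"", txt)
  for (i in seq_along(facet_starts)) {
    lo <- facet_starts[i]
    hi <- if (i < length(facet_starts)) facet_starts[i + 1] else length(txt)
    r <- ref_lines[ref_lines >= lo & ref_lines < hi]
    t <- test_lines[test_lines >= lo & test_lines < hi]
    if (length(r) && length(t)) expect_lt(max(r), min(t))
  }
})

test_that("rendering the same spec twice is byte-identical", {
  spec <- overlay_fixture()
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_static(spec, p1, format = "svg")
  render_static(spec, p2, format = "svg")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  h1 <- withr::local_tempfile(fileext = ".html")
  h2 <- withr::local_tempfile(fileext = ".html")
  render_interactive(spec, h1)
  render_interactive(spec, h2)
  expect_identical(readBin(h1, "raw", file.size(h1)),
                   readBin(h2, "raw", file.size(h2)))
})

test_that("an empty spec renders labelled empty facets without markers", {
  empty_counts <- tibble::tibble(
    gene = character(), position = integer(),
    source = character(), count = integer()
  )
  spec <- build_overlay(empty_counts, genes = c("TP53", "PTEN"))
  path <- withr::local_tempfile(fileext = ".svg")
  render_static(spec, path, format = "svg")
  markers <- count_svg_markers(path)
  expect_length(markers$all, 0L)
  txt <- paste(readLines(path), collapse = "\n")
  expect_match(txt, "data-gene=\"TP53\"")
  expect_match(txt, "data-gene=\"PTEN\"")

  html <- withr::local_tempfile(fileext = ".html")
  render_interactive(spec, html)
  expect_false(any(grepl("class=\"marker ", readLines(html))))
})

test_that("interactive HTML embeds gene, position, source and count per marker", {
  spec <- overlay_fixture()
  path <- withr::local_tempfile(fileext = ".html")
  render_interactive(spec, path)
  txt <- paste(readLines(path), collapse = "\n")
  payload <- regmatches(
    txt,
    regexpr("<script type=\"application/json\" id=\"overlay-data\">.*?</script>",
            txt)
  )
  payload <- sub("^<script[^>]*>", "", sub("</script>$", "", payload))
  parsed <- jsonlite::fromJSON(payload)
  expect_equal(parsed$tooltip_fields, c("gene", "position", "source", "count"))
  expect_equal(nrow(parsed$points), nrow(spec$data))
  expect_setequal(
    paste(parsed$points$gene, parsed$points$position,
          parsed$points$source, parsed$points$count),
    paste(spec$data$gene, spec$data$position,
          spec$data$source, spec$data$count)
  )
  # hover data attributes present on every marker element too
  n_markers <- sum(lengths(regmatches(
    txt, gregexpr("class=\"marker marker-", txt))))
  n_payloads <- sum(lengths(regmatches(txt, gregexpr("data-count=", txt))))
  expect_equal(n_payloads, n_markers)
})

test_that("PNG rendering writes a non-empty raster file", {
  spec <- overlay_fixture()
  path <- withr::local_tempfile(fileext = ".png")
  render_static(spec, path, format = "png")
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
  expect_identical(readBin(path, "raw", 8L),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
})
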