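test_that("a single planted site yields exactly its records, all at its position", {
  spec <- fixture_spec(
    genes = c(G = 700L),
    planted_sites = data.frame(gene = "G", position = 600L,
                               source = "TEST", count = 3L),
    background = 0, seed = 1L,
    reference_source = "REF", test_source = "TEST"
  )
  tabs <- generate_fixture(spec)
  expect_equal(nrow(tabs$reference), 0L)
  expect_equal(nrow(tabs$test), 3L)
  parsed <- parse_mutation_aa(tabs$test[["Mutation AA"]])
  expect_true(all(parsed$status == "ok"))
  expect_true(all(parsed$position == 600L))
})

test_that("region hotspot counts cover every position and sum to the total", {
  spec <- fixture_spec(
    genes = c(G = 100L),
    region_hotspots = data.frame(gene = "G", start = 23L, end = 48L,
                                 source = "REF", count = 26L),
    background = 0, seed = 2L,
    reference_source = "REF", test_source = "TEST"
  )
  tabs <- generate_fixture(spec)
  expect_equal(nrow(tabs$reference), 26L)
  pos <- parse_mutation_aa(tabs$reference[["Mutation AA"]])$position
  expect_setequal(pos, 23:48)
  expect_equal(length(pos), 26L)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- small_fixture_spec(seed = 123L, background = 6)
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  expect_identical(bare_table(a$reference), bare_table(b$reference))
  expect_identical(bare_table(a$test), bare_table(b$test))
  c <- generate_fixture(small_fixture_spec(seed = 124L, background = 6))
  expect_false(identical(bare_table(a$reference),
                         bare_table(c$reference)))
})

test_that("invalid fixture specs are rejected", {
  expect_error(
    fixture_spec(genes = c(G = 100L),
                 planted_sites = data.frame(gene = "G", position = 101L,
                                            source = "REF", count = 1L)),
    class = "mutoverlay_arg_error"
  )
  expect_error(
    fixture_spec(genes = c(G = 100L),
                 region_hotspots = data.frame(gene = "G", start = 90L,
                                              end = 120L, source = "REF",
                                              count = 5L)),
    class = "mutoverlay_arg_error"
  )
  expect_error(
    fixture_spec(genes = c(G = 100L),
                 planted_sites = data.frame(gene = "OTHER", position = 5L,
                                            source = "REF", count = 1L)),
    class = "mutoverlay_arg_error"
  )
  expect_error(fixture_spec(genes = c(G = 100L), background = -1),
               class = "mutoverlay_arg_error")
})

test_that("every generated annotation parses ok at its planted position", {
  for (seed in c(1L, 2L, 3L)) {
    spec <- small_fixture_spec(seed = seed, background = 8)
    tabs <- generate_fixture(spec)
    for (role in c("reference", "test")) {
      parsed <- parse_mutation_aa(tabs[[role]][["Mutation AA"]])
      expect_true(all(parsed$status == "ok"))
    }
  }
})

test_that("with zero background the pipeline recovers exactly the planted counts", {
  for (seed in c(7L, 8L, 9L)) {
    spec <- small_fixture_spec(seed = seed, background = 0)
    tabs <- prepared_tables(spec)
    counts <- count_sites(merge_tables(tabs$reference, tabs$test))
    rep <- recover_planted(spec, counts, min_count = 1L)
    expect_true(rep$all_recovered)
    expect_equal(rep$n_false_survivors, 0L)
    expect_equal(rep$sites$observed, rep$sites$count)
  }
})

test_that("thresholding a zero-background fixture keeps only high-count plants", {
  spec <- small_fixture_spec(seed = 40L, background = 0)
  tabs <- prepared_tables(spec)
  counts <- count_sites(merge_tables(tabs$reference, tabs$test))
  rep <- recover_planted(spec, counts, min_count = 10L)
  # plants at 12 and 10 survive; 3, 2 and the 26-spread-over-26 region do not
  expect_equal(sum(rep$sites$survives), 2L)
  expect_equal(rep$n_false_survivors, 0L)
  expect_true(rep$all_recovered)
})

test_that("a low background rarely produces false survivors across a seed sweep", {
  # background Poisson rate 1 per gene per source spread over >=400
  # residues: P(any single site reaching 10 copies) is astronomically
  # small, so across 20 seeds no background site may pass min_count = 10
  false_survivors <- vapply(1:20, function(seed) {
    spec <- small_fixture_spec(seed = seed, background = 1)
    tabs <- prepared_tables(spec)
    counts <- count_sites(merge_tables(tabs$reference, tabs$test))
    recover_planted(spec, counts, min_count = 10L)$n_false_survivors
  }, numeric(1))
  expect_equal(sum(false_survivors), 0)
})

test_that("the bundled synthetic fixture files match in-code regeneration", {
  ref_path <- system.file("extdata", "synthetic_reference.tsv",
                          package = "mutoverlay")
  test_path <- system.file("extdata", "synthetic_test.tsv",
                           package = "mutoverlay")
  expect_true(nzchar(ref_path) && nzchar(test_path))
  tabs <- generate_fixture(default_fixture_spec())
  on_disk <- read_mutation_table(ref_path)
  expect_equal(nrow(on_disk), nrow(tabs$reference))
  expect_equal(on_disk[["Mutation AA"]], tabs$reference[["Mutation AA"]])
})
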