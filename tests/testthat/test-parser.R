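test_that("positions and classes are extracted with the first-affected-residue rule", {
  cases <- tibble::tribble(
    ~raw,                 ~status,               ~position, ~class,
    "p.V600E",            "ok",                  600L,      "substitution",
    "p.R132H",            "ok",                  132L,      "substitution",
    "p.E746_A750del",     "ok",                  746L,      "deletion",
    "p.G12fs*2",          "ok",                  12L,       "frameshift",
    "p.A767_V769dup",     "ok",                  767L,      "duplication",
    "p.E746_A750delinsQ", "ok",                  746L,      "complex",
    "p.R661*",            "ok",                  661L,      "nonsense",
    "p.*757L",            "ok",                  757L,      "other",
    "p.M1?",              "ok",                  1L,        "start_lost",
    "p.?",                "wildtype_or_unknown", NA,        NA,
    "p.del",              "no_position",         NA,        NA,
    "",                   "malformed",           NA,        NA
  )
  res <- parse_mutation_aa(cases$raw)
  expect_equal(res$status, cases$status)
  expect_equal(res$position, cases$position)
  expect_equal(res$mutation_class, cases$class)
  expect_equal(res$raw, cases$raw)
})

test_that("prefix, case and three-letter dialects normalize to the same result", {
  variants <- c("p.V600E", "V600E", "p.v600e", "p.Val600Glu", "p.VAL600GLU",
                "p.(V600E)")
  res <- parse_mutation_aa(variants)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$position == 600L))
  expect_true(all(res$mutation_class == "substitution"))
})

test_that("no-change and unknown annotations never yield a position", {
  res <- parse_mutation_aa(c("p.?", "p.unknown", "p.0", "p.0?", "p.=",
                             "p.V600=", "?"))
  expect_true(all(res$status == "wildtype_or_unknown"))
  expect_true(all(is.na(res$position)))
})

test_that("the parser is total over fuzzed printable-ASCII input", {
  withr::with_seed(99L, {
    chars <- strsplit(rawToChar(as.raw(32:126)), "")[[1]]
    fuzz <- vapply(seq_len(400), function(i) {
      paste(sample(chars, sample.int(64, 1), replace = TRUE), collapse = "")
    }, character(1))
  })
  res <- parse_mutation_aa(fuzz)
  expect_equal(nrow(res), length(fuzz))
  expect_true(all(res$status %in%
                    c("ok", "no_position", "wildtype_or_unknown", "malformed")))
  expect_true(all(res$position[res$status == "ok"] >= 1L))
  expect_true(all(is.na(res$position[res$status != "ok"])))
  expect_equal(res$raw, fuzz)
})

test_that("templated annotations with a known position parse back to it", {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  withr::with_seed(7L, {
    pos <- sample.int(2000L, 300L, replace = TRUE)
    r1 <- sample(aa, 300L, replace = TRUE)
    r2 <- sample(aa, 300L, replace = TRUE)
    kind <- sample(6L, 300L, replace = TRUE)
  })
  ann <- mapply(function(p, a, b, k) {
    switch(k,
           sprintf("p.%s%d%s", a, p, b),
           sprintf("p.%s%d*", a, p),
           sprintf("p.%s%d_%s%ddel", a, p, b, p + 3L),
           sprintf("p.%s%dfs*7", a, p),
           sprintf("p.%s%ddup", a, p),
           sprintf("p.%s%d_%s%dins%s", a, p, b, p + 1L, b))
  }, pos, r1, r2, kind)
  res <- parse_mutation_aa(ann)
  expect_true(all(res$status == "ok"))
  expect_equal(res$position, pos)
})

test_that("annotate_positions fills Position, reports tallies and is idempotent", {
  tbl <- as_mutation_table(tibble::tibble(
    `Gene name` = c("G1", "G1", "G2"),
    `Mutation AA` = c("p.V600E", "p.?", "p.E746_A750del")
  ))
  ann <- annotate_positions(tbl)
  expect_equal(ann$Position, c(600L, NA, 746L))
  expect_equal(unname(parse_report(ann)[c("ok", "wildtype_or_unknown")]),
               c(2L, 1L))
  twice <- annotate_positions(ann)
  expect_equal(bare_table(twice), bare_table(ann))

  empty <- annotate_positions(as_mutation_table(tibble::tibble(
    `Gene name` = character(), `Mutation AA` = character()
  )))
  expect_equal(nrow(empty), 0L)
  expect_true(all(parse_report(empty) == 0L))
})

test_that("annotation-level tallies match a record-wise parse loop", {
  tabs <- generate_fixture(small_fixture_spec(seed = 11L, background = 3))
  tbl <- tabs$reference
  ann <- annotate_positions(tbl)
  loopwise <- table(vapply(tbl[["Mutation AA"]], function(s) {
    parse_mutation_aa(s)$status
  }, character(1)))
  report <- parse_report(ann)
  for (status in names(loopwise)) {
    expect_equal(unname(report[[status]]), unname(loopwise[[status]]))
  }
  expect_equal(sum(report), nrow(tbl))
})

test_that("existing positions are trusted unless recompute is requested", {
  tbl <- as_mutation_table(tibble::tibble(
    `Gene name` = "G", `Mutation AA` = "p.V600E", Position = 99L
  ))
  expect_equal(annotate_positions(tbl)$Position, 99L)
  expect_equal(annotate_positions(tbl, recompute = TRUE)$Position, 600L)
})
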