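test_that("recode mini-grammar parses, serializes, and round-trips", {
  r <- parse_recode("1->1;5->0;6,96,97,98,99->NA")
  expect_s3_class(r, "recode_rule")
  expect_identical(apply_recode(5L, r), 0L)
  expect_identical(apply_recode(96L, r), NA_integer_)
  expect_identical(r$declared_range, c(0L, 1L))
  # canonical serialization round-trips
  r2 <- parse_recode(format_recode(r))
  expect_identical(sort(r2$raw), sort(r$raw))
  expect_identical(r2$harmonized[order(r2$raw)], r$harmonized[order(r$raw)])

  expect_error(parse_recode("1->1;x->0"), "non-integer raw code")
  expect_error(parse_recode("1=>0"), "unparseable")
  expect_error(parse_recode(""), "empty")
  expect_error(recode_rule(c(1L, 1L), c(0L, 1L)), "duplicate")
  expect_error(recode_rule(c(1L, 2L), c(1L, 2L)), "start at 0")
})

test_that("crosswalk files read and write losslessly with validation", {
  m1 <- item_mapping("delusion_danger", "adams", "npi_del",
                     instrument = "NPI",
                     question_stem = "Believes others plan to hurt them",
                     response_options = c(Yes = 1L, No = 5L),
                     missing_codes = c(6L, 96L, 97L, 98L, 99L),
                     recode = parse_recode("1->1;5->0;6,96,97,98,99->NA"))
  m2 <- binary_mapping("delusion_danger", "boup_study")
  cw <- crosswalk(list(m1, m2))
  expect_length(cw$mappings, 2L)
  expect_length(cw$constructs, 1L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_crosswalk(cw, path)
  cw2 <- read_crosswalk(path)
  expect_equal(cw2, cw)

  # duplicate (construct, study) is a structural error naming both rows
  expect_error(crosswalk(list(m1, m1)), "rows 1 and 2")
  # recode must cover every declared code
  expect_error(
    item_mapping("x", "s", "v", response_options = c(No = 0L, Yes = 1L),
                 missing_codes = 9L,
                 recode = recode_rule(c(0L, 1L), c(0L, 1L))),
    "not total")
  # a raw code may appear only once across options and missing codes
  expect_error(
    item_mapping("x", "s", "v", response_options = c(No = 0L, Yes = 1L),
                 missing_codes = 1L,
                 recode = recode_rule(c(0L, 1L), c(0L, 1L))),
    "more than once")
})

test_that("unparseable recode cells report their coordinates", {
  df <- data.frame(construct_id = "c1", study_id = "s1", source_variable = "v1",
                   instrument = "", question_stem = "",
                   response_options = "0=No;1=Yes", missing_codes = "",
                   gate_variable = "", is_summary_score = "FALSE",
                   recode = "0->0;1->oops", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_crosswalk(path), "row 1, column 'recode'")
})

test_that("item prevalence matches a brute-force membership tally", {
  # trivial cases
  cw <- crosswalk(list(binary_mapping("a", "s1"), binary_mapping("b", "s1"),
                       binary_mapping("c", "s1")))
  prev <- item_prevalence(cw)
  expect_identical(prev$n_constructs[prev$n_studies == 1L], 3L)

  cw <- crosswalk(list(binary_mapping("A", "s1"), binary_mapping("A", "s2"),
                       binary_mapping("B", "s1")))
  prev <- item_prevalence(cw)
  expect_identical(prev$n_constructs, c(1L, 1L))

  # randomized membership vs independent tally over membership sets
  set.seed(404)
  studies <- paste0("s", 1:4)
  for (rep in 1:5) {
    membership <- lapply(1:10, function(i) {
      sample(studies, sample(1:4, 1))
    })
    names(membership) <- paste0("c", 1:10)
    maps <- unlist(lapply(names(membership), function(con) {
      lapply(membership[[con]], function(s) binary_mapping(con, s))
    }), recursive = FALSE)
    prev <- item_prevalence(crosswalk(maps))
    truth <- table(factor(vapply(membership, length, integer(1)),
                          levels = 1:4))
    expect_identical(prev$n_constructs, as.integer(truth))
    expect_identical(sum(prev$n_constructs), 10L)
  }
})

test_that("crosswalk validation flags missing variables and undeclared codes", {
  cw <- crosswalk(list(binary_mapping("a", "s1", "v1"),
                       binary_mapping("b", "s1", "v_absent"),
                       binary_mapping("c", "s1", "v3")))
  ds <- study_dataset("s1", data.frame(id = 1:4, v1 = c(0L, 1L, 1L, 0L),
                                       v3 = c(0L, 1L, 7L, 1L)))
  flags <- validate_crosswalk(cw, list(ds))
  expect_setequal(flags$kind, c("missing_variable", "undeclared_code"))
  expect_identical(flags$construct_id[flags$kind == "missing_variable"], "b")
  expect_match(flags$evidence[flags$kind == "undeclared_code"], "7")

  # fully consistent pair yields no flags
  ds_ok <- study_dataset("s1", data.frame(id = 1:2, v1 = 0:1, v_absent = 0:1,
                                          v3 = 0:1))
  expect_identical(nrow(validate_crosswalk(cw, list(ds_ok))), 0L)
  expect_error(validate_crosswalk(cw, list()), "no dataset")
})
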