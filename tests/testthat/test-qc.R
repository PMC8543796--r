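test_that("sentinel missing codes are detected on raw values only", {
  f <- detect_missing_codes(c(1L, 5L, 96L, 1L), "del", "adams")
  expect_identical(f$kind, "missing_code")
  expect_match(f$evidence, "96")
  f2 <- detect_missing_codes(c(1L, 2L, -5L))
  expect_match(f2$evidence, "-5")
  expect_null(detect_missing_codes(c(0L, 1L, 0L, 1L)))
  # a 0-100 percent-style scale maxing inside [90, 100] is suspect by rule
  expect_identical(detect_missing_codes(c(10L, 95L))$kind, "missing_code")
})

test_that("no-variability detection ignores missing values", {
  expect_identical(detect_no_variability(c(0L, 0L, 0L))$kind,
                   "no_variability")
  expect_null(detect_no_variability(c(0L, 1L)))
  f <- detect_no_variability(c(1L, NA, 1L))
  expect_identical(f$value, 1)
  expect_match(detect_no_variability(c(NA, NA))$evidence, "all missing")
})

test_that("range cross-tabulation flags scale discrepancies across studies", {
  cw <- crosswalk(list(
    item_mapping("verbal_agg", "blessed_study", "v1",
                 response_options = 0:3,
                 recode = recode_rule(0:3, 0:3)),
    binary_mapping("verbal_agg", "boup_study", "v1"),
    binary_mapping("calm", "blessed_study", "v2"),
    binary_mapping("calm", "boup_study", "v2")))
  dsA <- study_dataset("blessed_study",
                       data.frame(id = 1:4, v1 = 0:3, v2 = c(0L, 1L, 0L, 1L)))
  dsB <- study_dataset("boup_study",
                       data.frame(id = 1:4, v1 = c(0L, 1L, 1L, 0L),
                                  v2 = c(1L, 0L, 1L, 0L)))
  out <- crosstab_ranges(list(dsA, dsB), cw)
  expect_identical(out$flags$construct_id, "verbal_agg")
  expect_identical(out$flags$study_id, "pooled")
  expect_identical(nrow(out$table), 4L)

  # planted mismatches are recovered exactly, none besides
  set.seed(31)
  n_con <- 30
  planted <- sort(sample(sprintf("c%02d", 1:n_con), 20))
  maps <- list(); d1 <- list(id = 1:50); d2 <- list(id = 1:50)
  for (i in 1:n_con) {
    con <- sprintf("c%02d", i)
    mismatched <- con %in% planted
    maps[[length(maps) + 1L]] <- binary_mapping(con, "s1", con)
    maps[[length(maps) + 1L]] <- if (mismatched) {
      item_mapping(con, "s2", con, response_options = 0:3,
                   recode = recode_rule(0:3, 0:3))
    } else binary_mapping(con, "s2", con)
    d1[[con]] <- sample(0:1, 50, replace = TRUE)
    d2[[con]] <- if (mismatched) sample(0:3, 50, replace = TRUE)
                 else sample(0:1, 50, replace = TRUE)
  }
  out2 <- crosstab_ranges(list(study_dataset("s1", as.data.frame(d1)),
                               study_dataset("s2", as.data.frame(d2))),
                          crosswalk(maps))
  expect_identical(sort(out2$flags$construct_id), planted)
})

test_that("reverse candidates follow the negative-correlation rule", {
  # hand-computed truth table: B copies A, C is the complement of A
  A <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  ds <- study_dataset("s1", data.frame(id = 1:8, A = A, B = A, C = 1L - A))
  flags <- detect_reverse_candidates(ds, min_overlap = 5L)
  expect_true("C" %in% flags$construct_id)
  expect_identical(min(flags$value), -1)

  # aligned polarity: no flags
  set.seed(32)
  y <- sim_2pl(300, rep(1.8, 4), c(-1, 0, 0.5, 1), seed = 320)
  ds2 <- study_dataset("s2", data.frame(id = 1:300, y))
  expect_identical(nrow(detect_reverse_candidates(ds2)), 0L)

  # planted reversals are all recovered
  y3 <- sim_2pl(500, seq(1, 2.2, length.out = 8),
                seq(-1, 1, length.out = 8), seed = 321)
  rev_items <- c("it02", "it05")
  y3[, rev_items] <- 1L - y3[, rev_items]
  ds3 <- study_dataset("s3", data.frame(id = 1:500, y3))
  flags3 <- detect_reverse_candidates(ds3)
  expect_true(all(rev_items %in% flags3$construct_id))

  # pure functions: identical reruns, respondent-order invariance
  expect_identical(detect_reverse_candidates(ds3), flags3)
  perm <- sample(500)
  ds3p <- study_dataset("s3", ds3$data[perm, ])
  expect_equal(detect_reverse_candidates(ds3p), flags3)

  # adding an item uncorrelated with all others leaves flags unchanged
  set.seed(33)
  ds3n <- study_dataset("s3", cbind(ds3$data,
                                    noise = sample(0:1, 500, replace = TRUE)))
  flags_n <- detect_reverse_candidates(ds3n)
  expect_identical(sort(unique(flags_n$construct_id[flags_n$construct_id !=
                                                      "noise"])),
                   sort(unique(flags3$construct_id)))
})

test_that("sparse overlap pairs are skipped in the correlation screen", {
  set.seed(34)
  y <- sim_2pl(100, c(1.5, 1.5, 1.5), c(0, 0, 0), seed = 340)
  y[1:90, 3] <- NA          # only 10 complete pairs with item 3
  y[, 2] <- 1L - y[, 2]     # reversed
  ds <- study_dataset("s1", data.frame(id = 1:100, y))
  flags <- detect_reverse_candidates(ds, min_overlap = 20L)
  # item 3's pairs fall below the floor, so no flag can cite item 3
  expect_false(any(grepl("it03", flags$evidence)))
})

test_that("conditional items are excluded via gate declarations", {
  cw <- crosswalk(list(
    binary_mapping("presence", "s1", "v_pres"),
    item_mapping("severity", "s1", "v_sev",
                 response_options = 0:2, gate_variable = "v_pres",
                 recode = recode_rule(0:2, 0:2)),
    binary_mapping("other", "s1", "v_oth")))
  ds <- study_dataset("s1", data.frame(
    id = 1:4, presence = c(0L, 1L, 1L, 0L), severity = c(NA, 1L, 2L, NA),
    other = c(1L, 0L, 1L, 0L)))
  out <- exclude_conditional(ds, cw)
  expect_false("severity" %in% names(out$dataset$data))
  expect_identical(out$flags$kind, "conditional_item")
  expect_identical(out$flags$construct_id, "severity")

  # no gates: identity
  cw2 <- crosswalk(list(binary_mapping("a", "s1", "a")))
  ds2 <- study_dataset("s1", data.frame(id = 1:2, a = 0:1))
  out2 <- exclude_conditional(ds2, cw2)
  expect_identical(out2$dataset$data, ds2$data)
  expect_identical(nrow(out2$flags), 0L)

  # gate cycles are structural errors
  cw3 <- crosswalk(list(binary_mapping("a", "s1", "va", gate = "vb"),
                        binary_mapping("b", "s1", "vb", gate = "va")))
  expect_error(exclude_conditional(ds2, cw3), "cycle")
})

test_that("endorsement report counts exactly and bounds rare items", {
  ds <- study_dataset("s1", data.frame(id = 1:4, x = c(0L, 0L, 1L, NA)))
  rep <- endorsement_report(ds)
  expect_identical(rep$counts, "0:2 1:1")
  expect_identical(rep$prop_missing, 0.25)
  expect_equal(rep$endorsement, 1 / 3)

  ds0 <- study_dataset("s1", data.frame(id = 1:5, x = rep(0L, 5)))
  expect_identical(endorsement_report(ds0)$endorsement, 0)

  set.seed(35)
  rare <- rbinom(1000, 1, 0.02)
  ds_rare <- study_dataset("s1", data.frame(id = 1:1000, rare = rare))
  obs <- endorsement_report(ds_rare)$endorsement
  expect_lt(abs(obs - 0.02), 3 * sqrt(0.02 * 0.98 / 1000))
})

test_that("flag digests tally records per study and kind", {
  flags <- rbind(qc_flag("conditional_item", "a", "sX", "e"),
                 qc_flag("conditional_item", "b", "sX", "e"),
                 qc_flag("no_variability", "c", "sY", "e"))
  digest <- summarize_flags(flags)
  expect_identical(digest$n[digest$study_id == "sX"], 2L)
  key <- paste(flags$study_id, flags$kind)
  expect_identical(sum(digest$n), nrow(flags))
  expect_identical(nrow(summarize_flags(flags[0, ])), 0L)
})
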