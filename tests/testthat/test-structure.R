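test_that("folding limit cases behave for both backends", {
  for (bk in c("bundled", "vienna")) {
    fd <- fold(strrep("A", 61), backend = bk)
    expect_identical(fd$structure, strrep(".", 61))
    expect_lte(fd$mfe, 0)
    expect_identical(fold("ACGUACGUAC", backend = bk),
                     fold("ACGUACGUAC", backend = bk))
  }
  expect_error(fold("ACGX"), "outside A/C/G/U")
})

test_that("a designed stem-loop folds into the expected helix on both backends", {
  sl <- paste0(strrep("G", 10), strrep("A", 5), strrep("C", 10))
  expected <- paste0(strrep("(", 10), ".....", strrep(")", 10))
  for (bk in c("bundled", "vienna")) {
    fd <- fold(sl, backend = bk)
    expect_identical(fd$structure, expected)
    expect_lt(fd$mfe, 0)
  }
  ## the two backends agree on this designed case (cross-validation of the
  ## bundled folder against the established one)
  expect_identical(fold(sl, backend = "bundled")$structure,
                   fold(sl, backend = "vienna")$structure)
})

test_that("bundled MFE is non-positive whenever pairs exist", {
  set.seed(31)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
               collapse = "")
    fd <- fold(s, backend = "bundled")
    if (grepl("\\(", fd$structure)) expect_lt(fd$mfe, 0)
    ## dot-bracket is balanced and consistent with its own pair table
    expect_silent(fungedit:::pair_table(fd$structure))
  }
})

test_that("element classification follows the five-class definitions", {
  ## edited A at the unpaired centre of a closed loop
  expect_identical(classify_element("((((.......))))", 8), "hairpin_loop")
  expect_identical(classify_element("((((.......))))", 2), "stem")
  expect_identical(classify_element(".....", 3), "exterior")
  ## internal loop: unpaired between two nested helices
  db <- "((..((...))..))"
  expect_identical(classify_element(db, 3), "internal_or_bulge_loop")
  expect_identical(classify_element(db, 13), "internal_or_bulge_loop")
  expect_identical(classify_element(db, 7), "hairpin_loop")
  ## bulge: same class by design
  expect_identical(classify_element("((.((...))))", 3),
                   "internal_or_bulge_loop")
  ## multibranch: loop with three emanating helices
  mb <- "((.((...)).((...)).))"
  expect_identical(classify_element(mb, 3), "multibranch_loop")
  expect_identical(classify_element(mb, 11), "multibranch_loop")
  expect_identical(classify_element(mb, 6), "hairpin_loop")
  expect_error(classify_element("((..)", 1), "unbalanced")
  expect_error(classify_element("(...)", 9), "outside structure")
})

test_that("every position of random structures gets exactly one class", {
  set.seed(17)
  classes <- c("hairpin_loop", "stem", "internal_or_bulge_loop",
               "multibranch_loop", "exterior")
  for (i in 1:300) {
    db <- random_dotbracket(sample(10:80, 1))
    cl <- classify_positions(db)
    expect_length(cl, nchar(db))
    expect_true(all(cl %in% classes))
    ## paired positions are stems, count matches bracket count
    expect_identical(sum(cl == "stem"),
                     nchar(db) - nchar(gsub("[()]", "", db)) +
                       0L * nchar(db))
  }
})

test_that("structure context extracts 61-nt windows and flags truncation", {
  sim <- shared_sim()
  cdna <- transcript_sequences(sim$genome, sim$models)
  tx <- map_sites_to_tx(sim$annotated, sim$models)
  tx <- tx[!is.na(tx$tx_pos), , drop = FALSE]
  ctx <- structure_context(tx[1:10, ], cdna, backend = "vienna")
  expect_identical(nrow(ctx), 10L)
  expect_true(all(nchar(ctx$window) <= 61))
  full <- !ctx$truncated
  expect_true(all(nchar(ctx$window)[full] == 61))
  expect_true(all(substr(ctx$window, ctx$site_offset, ctx$site_offset) == "A"))
  expect_true(all(ctx$element %in% c("hairpin_loop", "stem",
                                     "internal_or_bulge_loop",
                                     "multibranch_loop", "exterior")))
  hp <- ctx$element == "hairpin_loop"
  expect_true(all(!is.na(ctx$hairpin_mfe[hp])))
  expect_true(all(is.na(ctx$hairpin_mfe[!hp])))
})

test_that("hairpin strata recover designed loop placement against control", {
  ## place edited A's in the loops of designed hairpins
  win <- paste0(strrep("G", 12), "AAAAA", strrep("C", 12))
  cdna <- stats::setNames(rep(win, 30), paste0("h", 1:30))
  edited <- data.frame(tx_id = names(cdna), tx_pos = 15L, level = 0.8)
  ctx <- structure_context(edited, cdna, backend = "vienna", flank = 14L)
  expect_true(all(ctx$element == "hairpin_loop"))
  st <- hairpin_mfe_strata(ctx, control = ctx)
  expect_equal(st$by_bin$hairpin_fraction[st$by_bin$n > 0], 1)
  expect_equal(st$control$overall_hairpin_fraction,
               st$overall_hairpin_fraction)
  expect_true(all(unlist(st$hairpin_mfes) < 0))
})
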