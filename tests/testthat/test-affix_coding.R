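test_that("the shipped language satisfies the structural invariants", {
  expect_equal(nrow(tt_language$sentences), 12)
  expect_equal(nrow(tt_language$nouns), 4)
  expect_equal(as.vector(table(tt_language$nouns$harmony)), c(2, 2))
  expect_equal(nrow(tt_language$suffixes), 6)
  ines <- tt_language$suffixes[tt_language$suffixes$case == "inessive", ]
  expect_equal(parse_phonemes(ines$suffix[ines$harmony == "front"], tt_table),
               c("b", "ε", "n"))
  expect_equal(parse_phonemes(ines$suffix[ines$harmony == "back"], tt_table),
               c("b", "ɔ", "n"))
  # every sentence carries the harmony-appropriate suffix for its case
  for (i in seq_len(12)) {
    sen <- tt_language$sentences[i, ]
    expect_equal(sen$target_suffix,
                 tt_language$suffixes$suffix[
                   tt_language$suffixes$case == sen$case &
                     tt_language$suffixes$harmony == sen$harmony])
  }
})

test_that("invalid language configs are rejected", {
  dup <- write_language_variant(function(cfg) {
    cfg$cases[[2]]$front_suffix <- cfg$cases[[1]]$front_suffix
    cfg
  })
  expect_error(load_target_language(dup, tt_table), "pairwise distinct")
  imbalance <- write_language_variant(function(cfg) {
    cfg$nouns[[1]]$harmony <- "back"
    cfg
  })
  expect_error(load_target_language(imbalance, tt_table),
               "2 nouns per harmony")
  three <- write_language_variant(function(cfg) {
    cfg$nouns <- cfg$nouns[1:3]
    cfg
  })
  expect_error(load_target_language(three, tt_table), "exactly 4 nouns")
})

test_that("suffix distances are zero exactly at a matching suffix", {
  d <- suffix_distances("bEn", tt_language, tt_table, tt_scheme)
  expect_equal(unname(d["inessive.front"]), 0)
  expect_true(all(d[names(d) != "inessive.front"] > 0))
  expect_equal(unname(suffix_distances("", tt_language, tt_table, tt_scheme)),
               rep(1, 6))
})

test_that("affix coding reproduces the published coding examples", {
  expect_equal(unname(code_affix("bEm", "inessive", "front",
                                 tt_language, tt_table, tt_scheme)),
               c(1, 0, 0))
  expect_equal(unname(code_affix("bOn", "inessive", "front",
                                 tt_language, tt_table, tt_scheme)),
               c(1, 1, 0))
  expect_equal(unname(code_affix("bEn", "inessive", "front",
                                 tt_language, tt_table, tt_scheme)),
               c(1, 1, 1))
  expect_equal(unname(code_affix("", "inessive", "front",
                                 tt_language, tt_table, tt_scheme)),
               c(0, 0, 0))
})

test_that("the three measures nest and agree with a hand-coding predicate", {
  # exhaustive scan of short productions over a mixed mini-inventory
  productions <- all_strings_upto(c("b", "n", "ε", "ɔ"), 3)
  suff <- tt_language$suffixes
  suffix_syms <- lapply(suff$suffix, parse_phonemes, table = tt_table)
  for (prod in productions) {
    for (target in c(1L, 2L)) {  # inessive front, inessive back
      codes <- code_affix(prod, suff$case[target], suff$harmony[target],
                          tt_language, tt_table, tt_scheme)
      # nesting
      expect_true(codes[3] <= codes[2] && codes[2] <= codes[1])
      # independent hand-coding: exact string match for the accuracy
      # measures, argmin-case membership (via the recursion oracle) for
      # identification
      d <- vapply(suffix_syms, function(sf) {
        oracle_edit_distance(prod, sf, tt_table, tt_scheme) /
          max(length(prod), length(sf))
      }, numeric(1))
      in_case <- suff$case == suff$case[target]
      hand_ident <- as.integer(min(d[in_case]) < min(d[!in_case]) - 1e-12)
      hand_case <- as.integer(any(vapply(suffix_syms[in_case], identical,
                                         logical(1), prod)))
      hand_alt <- as.integer(identical(prod, suffix_syms[[target]]))
      expect_equal(unname(codes), c(hand_ident, hand_case, hand_alt))
    }
  }
})

test_that("training-set sampling satisfies all published constraints", {
  withr::with_seed(21, {
    for (k in 1:100) {
      ts <- sample_training_set(tt_language)
      expect_equal(nrow(ts), 8)
      expect_true(all(table(ts$stem) == 2))
      expect_true(all(table(factor(ts$case, unique(tt_language$sentences$case))) >= 2))
      expect_equal(length(unique(paste(ts$case, ts$harmony))), 6)
      # training covers all stems and alternations: the language is in
      # principle reconstructable, and the 4 held-out items are novel
      # combinations of seen parts
      expect_setequal(unique(ts$stem), tt_language$nouns$stem)
      held_out <- setdiff(tt_language$sentences$sentence_id, ts$sentence_id)
      expect_equal(length(held_out), 4)
    }
  })
  expect_identical(sample_training_set(tt_language, seed = 99)$sentence_id,
                   sample_training_set(tt_language, seed = 99)$sentence_id)
})
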