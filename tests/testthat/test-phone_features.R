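test_that("shipped feature tables reproduce the published values", {
  expect_equal(unname(tt_table$vowels["a", ]), c(0, 0.5))
  expect_equal(unname(tt_table$vowels["y", ]), c(1, 1))
  expect_equal(unname(tt_table$consonants["k", ]),
               c(1, 0.6, 0.6, 1, 0, 0, 0, 0))
  expect_equal(nrow(tt_table$vowels), 7)      # 6 published vowels + /i/
  expect_equal(nrow(tt_table$consonants), 21)
  expect_true(all(tt_table$vowels >= 0 & tt_table$vowels <= 1))
  expect_true(all(tt_table$consonants >= 0 & tt_table$consonants <= 1))
})

test_that("malformed feature CSVs are rejected with the offending row", {
  base <- data.frame(symbol = c("x", "w2"), category = "vowel",
                     Height = c(0.2, 0.4), Forwardness = c(0.1, 0.9))
  out_of_range <- base
  out_of_range$Height[2] <- 1.2
  expect_error(load_feature_table(write_feature_csv(out_of_range),
                                  aliases = NULL),
               "outside \\[0, 1\\].*row 2")
  dup <- base
  dup$symbol <- c("x", "x")
  expect_error(load_feature_table(write_feature_csv(dup), aliases = NULL),
               "duplicate symbol")
  wrong_cat <- base
  wrong_cat$category[1] <- "glide"
  expect_error(load_feature_table(write_feature_csv(wrong_cat), aliases = NULL),
               "category.*row 1")
  missing_cell <- base
  missing_cell$Forwardness[1] <- NA
  expect_error(load_feature_table(write_feature_csv(missing_cell),
                                  aliases = NULL),
               "missing or non-numeric.*row 1")
})

test_that("phoneme distances match the published worked arithmetic", {
  expect_equal(phoneme_distance("y", "a", tt_table), 1.5)
  expect_equal(phoneme_distance("n", "tʃ", tt_table), 3.35)
  expect_equal(phoneme_distance("k", "f", tt_table), 1.3)
  expect_equal(phoneme_distance("a", "a", tt_table), 0)
  expect_error(phoneme_distance("a", "k", tt_table), "within a category")
  expect_error(phoneme_distance("a", "qq", tt_table), "unknown phoneme")
})

test_that("phoneme distance is symmetric over the whole inventory", {
  for (m in list(tt_table$vowels, tt_table$consonants)) {
    syms <- rownames(m)
    for (a in syms) {
      for (b in syms) {
        expect_equal(phoneme_distance(a, b, tt_table),
                     phoneme_distance(b, a, tt_table))
      }
    }
  }
})

test_that("category normalizers recomputed from the tables equal 1.5 and 4.25", {
  expect_equal(max_category_distance(tt_table, "vowel"), 1.5)
  expect_equal(max_category_distance(tt_table, "consonant"), 4.25)
  single <- load_feature_table(
    write_feature_csv(data.frame(symbol = "x", category = "vowel",
                                 Height = 0.5, Forwardness = 0.5)),
    aliases = NULL)
  expect_equal(max_category_distance(single, "vowel"), 0)
})

test_that("cost scheme verifies configured normalizers against the table", {
  sch <- cost_scheme(tt_table, vowel_normalizer = 1.5,
                     consonant_normalizer = 4.25)
  expect_equal(sch$vowel_normalizer, 1.5)
  expect_error(cost_scheme(tt_table, vowel_normalizer = 2),
               "does not match")
})

test_that("substitution costs follow the published scheme", {
  expect_equal(substitution_cost("k", "f", tt_table, tt_scheme),
               1.3 / 4.25 * 0.8)
  expect_equal(substitution_cost("a", "i", tt_table, tt_scheme), 0.8)
  expect_equal(substitution_cost("a", "k", tt_table, tt_scheme), 1)
  expect_equal(substitution_cost("m", "m", tt_table, tt_scheme), 0)
})

test_that("substitution cost is bounded and satisfies the triangle inequality", {
  M <- tt_scheme$cost_matrix
  expect_true(all(M >= 0 & M <= 1))
  cats <- tt_table$category[rownames(M)]
  within <- outer(cats, cats, "==")
  expect_true(all(M[within] <= tt_scheme$within_category_scale + 1e-12))
  # exhaustive triple check: cost(a, b) <= cost(a, c) + cost(c, b)
  syms <- rownames(M)
  violations <- 0
  for (a in syms) {
    for (b in syms) {
      if (any(M[a, b] > M[a, ] + M[, b] + 1e-12)) violations <- violations + 1
    }
  }
  expect_equal(violations, 0)
})

test_that("transcriptions tokenise with aliases, tie bars and separators", {
  expect_equal(parse_phonemes("-bEn", tt_table), c("b", "ε", "n"))
  expect_equal(parse_phonemes("ʃyvεg", tt_table), c("ʃ", "y", "v", "ε", "g"))
  expect_equal(parse_phonemes("tS", tt_table), "tʃ")
  expect_equal(parse_phonemes("tʃ⌢", tt_table), "tʃ")
  expect_equal(parse_phonemes("t ʃ", tt_table), c("t", "ʃ"))
  expect_equal(parse_phonemes("", tt_table), character(0))
  expect_equal(parse_phonemes(c("b", "E", "n"), tt_table), c("b", "ε", "n"))
  expect_error(parse_phonemes("bqn", tt_table), "position 2")
})
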