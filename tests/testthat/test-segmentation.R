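test_that("the default lexicon has 12 CV syllables and 6 trisyllabic words", {
  lex <- cv_lexicon()
  expect_equal(length(lex$syllables), 12)
  expect_setequal(lex$words, c("babupu", "bupada", "dutaba",
                               "patubi", "pidabu", "tutibu"))
  expect_true(all(lengths(lex$word_syllables) == 3))
  expect_error(cv_lexicon(words = c("babupu", "kaka")), "outside the inventory")
})

test_that("adjacent-duplicate elimination is correct and idempotent", {
  elim <- speakvar:::eliminate_adjacent_duplicates
  expect_equal(elim(c("A", "A", "B", "B")), c("A", "B"))
  expect_equal(elim(c("a", "a", "a")), "a")
  expect_equal(elim(character(0)), character(0))
  withr::with_seed(31, {
    for (k in 1:50) {
      x <- sample(letters[1:4], 50, replace = TRUE)
      once <- elim(x)
      expect_false(any(once[-1] == once[-length(once)]))
      expect_identical(elim(once), once)
    }
  })
})

test_that("generated streams satisfy the published stream properties", {
  lex <- cv_lexicon()
  st <- generate_stream(lex, tokens_per_word = 300, seed = 101)
  expect_lte(length(st$word_sequence), 1800)
  expect_false(any(st$word_sequence[-1] ==
                     st$word_sequence[-length(st$word_sequence)]))
  expect_equal(length(st$syllable_sequence), 3 * length(st$word_sequence))
  sep <- speakvar:::tp_separation(st)
  expect_gt(sep$min_within, sep$max_cross)
  # boundary positions point at word-initial syllables
  first_syl <- vapply(lex$word_syllables[st$word_sequence], `[`, "", 1L)
  expect_equal(st$syllable_sequence[st$boundary_index], unname(first_syl))
  # determinism
  st2 <- generate_stream(lex, tokens_per_word = 300, seed = 101)
  expect_identical(st$syllable_sequence, st2$syllable_sequence)
  expect_error(generate_stream(cv_lexicon(words = "babupu")), "at least 2")
})

test_that("transitional probabilities follow the frequency definition", {
  tp <- transitional_probabilities(c("A", "B", "A", "B"))
  expect_equal(tp$tp[tp$from == "A" & tp$to == "B"], 1)
  tp <- transitional_probabilities(c("A", "B", "A", "C"))
  expect_equal(tp$tp[tp$from == "A"], c(0.5, 0.5))
  expect_error(transitional_probabilities("A"), "at least 2")
  # every row is a probability distribution over successors
  st <- generate_stream(cv_lexicon(), tokens_per_word = 50, seed = 102)
  sums <- tapply(st$tp_table$tp, st$tp_table$from, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("foils have zero internal TP and avoid the lexicon", {
  lex <- cv_lexicon()
  st <- generate_stream(lex, tokens_per_word = 300, seed = 103)
  foils <- generate_foils(st, seed = 104)
  expect_length(foils, 6)
  expect_length(unique(foils), 6)
  expect_length(intersect(foils, lex$words), 0)
  seq <- st$syllable_sequence
  for (f in foils) {
    syl <- substring(f, c(1, 3, 5), c(2, 4, 6))
    expect_true(all(syl %in% lex$syllables))
    expect_equal(count_bigram(seq, syl[1], syl[2]), 0)
    expect_equal(count_bigram(seq, syl[2], syl[3]), 0)
  }
  expect_equal(generate_foils(st, n_foils = 0), character(0))
  expect_error(generate_foils(st, n_foils = 1e6), "qualifying")
})

test_that("test blocks hold all 36 pairings with balanced voice plans", {
  lex <- cv_lexicon()
  foils <- c("bubidi", "tabidi", "tatupa", "dubati", "bitapi", "tupati")
  multi <- list(condition = "multiple", training_voices = c("en1", "us2", "de1"),
                novel_voice = "us1", familiar_first = TRUE)
  blocks <- build_test_blocks(lex, foils, multi, seed = 105)
  for (b in list(blocks$familiar, blocks$novel)) {
    expect_equal(nrow(b), 36)
    expect_true(all(table(b$word) == 6))
    expect_true(all(table(b$foil) == 6))
  }
  expect_equal(as.vector(table(blocks$familiar$voice)), rep(12L, 3))
  expect_true(all(blocks$novel$voice == "us1"))
  expect_equal(blocks$block_order, c("familiar", "novel"))
  single <- list(condition = "single", training_voices = "en1",
                 novel_voice = "de1", familiar_first = FALSE)
  sb <- build_test_blocks(lex, foils, single, seed = 106)
  expect_true(all(sb$familiar$voice == "en1"))
  expect_false(single$novel_voice %in% single$training_voices)
  bad <- list(condition = "single", training_voices = c("en1", "us2"),
              novel_voice = "de1", familiar_first = TRUE)
  expect_error(build_test_blocks(lex, foils, bad), "exactly 1 training voice")
})

test_that("speaker assignment is counterbalanced as published", {
  d1 <- assign_speakers("exp1", seed = 107)
  single <- d1[d1$condition == "single", ]
  multiple <- d1[d1$condition == "multiple", ]
  expect_equal(as.vector(table(single$training_voices)), rep(6L, 4))
  expect_equal(as.vector(table(multiple$training_voices)), rep(6L, 4))
  expect_equal(sum(d1$familiar_first), 24)
  expect_true(all(mapply(function(tr, nv) {
    !(nv %in% strsplit(tr, ",")[[1]])
  }, d1$training_voices, d1$novel_voice)))
  expect_error(assign_speakers("exp1", n_per_condition = 7), "multiple of 8")

  d2 <- assign_speakers("exp2", seed = 108)
  singles <- d2$participants[d2$participants$condition == "single", ]
  expect_equal(nrow(singles), 20)
  expect_true(all(table(singles$speaker) >= 6))
  per_part <- tapply(d2$sentence_assignments$speaker,
                     d2$sentence_assignments$participant,
                     function(s) min(table(factor(s, unique(d2$sentence_assignments$speaker)))))
  expect_true(all(per_part >= 2))
  expect_true(all(table(d2$sentence_assignments$participant) == 8))
})

test_that("pho export assigns 60 ms consonants and 218 ms vowels", {
  lines <- export_pho(c("ba", "bu", "pu"), f0 = 100)
  expect_length(lines, 6)
  expect_equal(lines[1], "b 60 0 100")
  expect_equal(lines[2], "a 218 0 100")
  durations <- as.integer(vapply(strsplit(lines, " "), `[`, "", 2L))
  expect_equal(sum(durations), 278 * 3)
  expect_equal(export_pho(character(0)), character(0))
  expect_error(export_pho(c("ba", "xyz")), "consonant\\+vowel")
  f <- tempfile(fileext = ".pho")
  export_pho(c("ba"), f0 = 200, path = f)
  expect_equal(readLines(f), c("b 60 0 200", "a 218 0 200"))
})
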