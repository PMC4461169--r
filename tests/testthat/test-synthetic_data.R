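test_that("segmentation simulation is deterministic and hits its logit targets", {
  design <- assign_speakers("exp1", seed = 41)
  a <- simulate_segmentation_experiment(design, seed = 42)
  b <- simulate_segmentation_experiment(design, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 48 * 72)
  expect_true(all(table(a$participant) == 72))

  # null learner: mean accuracy near 0.5
  null_params <- seg_sim_params(0, 0, 0, 0, 0, participant_sd = 0)
  null_resp <- simulate_segmentation_experiment(design, null_params, seed = 43)
  n <- nrow(null_resp)
  expect_lt(abs(mean(null_resp$correct) - 0.5), 3 * sqrt(0.25 / n))

  # intercept-only learner at 0.343 logits: accuracy near plogis(0.343)
  int_params <- seg_sim_params(0.343, 0, 0, 0, 0, participant_sd = 0)
  int_resp <- simulate_segmentation_experiment(design, int_params, seed = 44)
  p <- plogis(0.343)
  expect_lt(abs(mean(int_resp$correct) - p),
            qnorm(0.995) * sqrt(p * (1 - p) / n))
})

test_that("corrupt_string honours its boundary and calibration contracts", {
  target <- parse_phonemes("SyvEg", tt_table)
  expect_identical(corrupt_string(target, 1, tt_table, tt_scheme), target)
  expect_identical(corrupt_string(target, 0, tt_table, tt_scheme), character(0))
  expect_error(corrupt_string(target, 1.2, tt_table, tt_scheme), "\\[0, 1\\]")
  expect_error(corrupt_string(character(0), 0.5, tt_table, tt_scheme),
               "non-empty")
  # calibration: mean scored accuracy tracks the requested accuracy
  withr::with_seed(45, {
    for (a_target in c(0.7, 0.45)) {
      accs <- vapply(1:800, function(k) {
        tgt <- sample(names(tt_table$category), 6, replace = TRUE)
        prod <- corrupt_string(tgt, a_target, tt_table, tt_scheme)
        production_accuracy(prod, tgt, tt_table, tt_scheme)$accuracy
      }, numeric(1))
      expect_lt(abs(mean(accs) - a_target), 0.05)
    }
  })
})

test_that("production simulation respects degenerate profiles", {
  design <- assign_speakers("exp2", n_per_condition = 3, seed = 46)
  perfect <- prod_sim_params(
    base_accuracy = 1, round_slope = 0, novelty_penalty = 0,
    participant_sd = 0,
    affix_profile = c(exact = 1, wrong_harmony = 0, near_miss = 0,
                      unrelated = 0, silent = 0))
  prod <- simulate_production_experiment(tt_language, design, perfect,
                                         tt_table, tt_scheme,
                                         rounds = 1:2, seed = 47)
  scored <- score_productions(prod, tt_table, tt_scheme)
  expect_true(all(scored$stem_accuracy == 1))
  coded <- code_productions(scored, tt_language, tt_table, tt_scheme)
  expect_true(all(coded$case_identification == 1 & coded$case_accuracy == 1 &
                    coded$alternation_accuracy == 1))

  harmony_violator <- prod_sim_params(
    base_accuracy = 1, round_slope = 0, novelty_penalty = 0,
    participant_sd = 0, affix_round_slope = 0, affix_novelty_penalty = 0,
    affix_profile = c(exact = 0, wrong_harmony = 1, near_miss = 0,
                      unrelated = 0, silent = 0))
  prod2 <- simulate_production_experiment(tt_language, design, harmony_violator,
                                          tt_table, tt_scheme,
                                          rounds = 1, seed = 48)
  coded2 <- code_productions(prod2, tt_language, tt_table, tt_scheme)
  expect_true(all(coded2$case_identification == 1))
  expect_true(all(coded2$case_accuracy == 1))
  expect_true(all(coded2$alternation_accuracy == 0))
  expect_error(prod_sim_params(affix_profile = c(exact = 0.5,
                                                 wrong_harmony = 0.2,
                                                 near_miss = 0.2,
                                                 unrelated = 0.2,
                                                 silent = 0.1)),
               "sum to 1")
})

test_that("simulated learning improves over rounds and novel items lag", {
  design <- assign_speakers("exp2", n_per_condition = 6, seed = 49)
  params <- prod_sim_params(novelty_penalty = 0.15)
  prod <- simulate_production_experiment(tt_language, design, params,
                                         tt_table, tt_scheme, seed = 50)
  scored <- score_productions(prod, tt_table, tt_scheme)
  round_means <- tapply(scored$stem_accuracy, scored$round, mean)
  expect_gt(cor(seq_along(round_means), round_means, method = "spearman"), 0)
  nov_means <- tapply(scored$stem_accuracy, scored$novel, mean)
  expect_lt(nov_means[["TRUE"]], nov_means[["FALSE"]])
  # the affix-coding nesting invariant holds on all simulated productions
  coded <- code_productions(scored, tt_language, tt_table, tt_scheme)
  expect_true(all(coded$alternation_accuracy <= coded$case_accuracy))
  expect_true(all(coded$case_accuracy <= coded$case_identification))
})
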