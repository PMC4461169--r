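#' Parameters for the segmentation-learner simulator
#'
#' The synthetic learner's response model is deliberately identical in form
#' to the analysis model fitted downstream: a Bernoulli response whose
#' logit is a linear function of centred condition, speaker-identity,
#' test-order and condition-by-speaker terms plus a Normal participant
#' intercept.  The default fixed effects are the coefficients reported for
#' the original 48-participant sample; no variance component was reported,
#' so the participant standard deviation defaults to 0.5 logits.
#'
#' @param beta_intercept,beta_condition,beta_speaker_identity,beta_order,beta_interaction
#'   Fixed effects on the logit scale, for ±0.5 centred predictors.
#' @param participant_sd SD of the Normal participant random intercept.
#' @return A list of class `seg_sim_params`.
#' @export
seg_sim_params <- function(beta_intercept = 0.343,
                           beta_condition = 0.097,
                           beta_speaker_identity = -0.439,
                           beta_order = -0.258,
                           beta_interaction = -0.093,
                           participant_sd = 0.5) {
  stopifnot(participant_sd >= 0)
  structure(list(beta_intercept = beta_intercept,
                 beta_condition = beta_condition,
                 beta_speaker_identity = beta_speaker_identity,
                 beta_order = beta_order,
                 beta_interaction = beta_interaction,
                 participant_sd = participant_sd),
            class = "seg_sim_params")
}

#' Simulate forced-choice segmentation responses
#'
#' Generates the trial-level response table of the word-segmentation
#' experiment for every participant in a design table: 2 test blocks
#' (familiar and novel voice, in the participant's counterbalanced order)
#' of 36 word-foil trials each.  Each response is Bernoulli with
#' `plogis(eta)`, where `eta` sums the centred fixed effects of
#' [seg_sim_params()] and the participant's random intercept.  Predictors
#' are emitted uncentred (0/1) and centred at fit time.
#'
#' @param design Exp 1 design table from [assign_speakers()].
#' @param params A [seg_sim_params()] object.
#' @param trials_per_block Number of word-foil pairings per block.
#' @param seed Optional integer seed.
#' @return Data frame with one row per trial: `participant`, `condition`,
#'   `block_kind`, `block_pos`, `trial`, `condition_multiple`,
#'   `speaker_novel`, `second_block` and `correct`.
#' @export
simulate_segmentation_experiment <- function(design, params = seg_sim_params(),
                                             trials_per_block = 36L,
                                             seed = NULL) {
  needed <- c("participant", "condition", "familiar_first")
  if (!all(needed %in% names(design))) {
    stop("design table must have columns: ", paste(needed, collapse = ", "))
  }
  maybe_with_seed(seed, {
    u <- stats::rnorm(nrow(design), 0, params$participant_sd)
    rows <- lapply(seq_len(nrow(design)), function(i) {
      kinds <- if (design$familiar_first[i]) c("familiar", "novel")
      else c("novel", "familiar")
      df <- data.frame(
        participant = design$participant[i],
        condition = design$condition[i],
        block_kind = rep(kinds, each = trials_per_block),
        block_pos = rep(1:2, each = trials_per_block),
        trial = rep(seq_len(trials_per_block), 2L),
        stringsAsFactors = FALSE
      )
      df$condition_multiple <- as.integer(df$condition == "multiple")
      df$speaker_novel <- as.integer(df$block_kind == "novel")
      df$second_block <- as.integer(df$block_pos == 2L)
      xc <- df$condition_multiple - 0.5
      xs <- df$speaker_novel - 0.5
      xo <- df$second_block - 0.5
      eta <- params$beta_intercept +
        params$beta_condition * xc +
        params$beta_speaker_identity * xs +
        params$beta_order * xo +
        params$beta_interaction * xc * xs +
        u[i]
      df$correct <- stats::rbinom(nrow(df), 1L, stats::plogis(eta))
      df
    })
    do.call(rbind, rows)
  })
}

#' Parameters for the production-learner simulator
#'
#' Controls the synthetic learner of the morphology experiment.  The
#' expected stem accuracy of a trial is formed on the accuracy scale as
#' `base_accuracy + round_slope * (round - mean(rounds)) - novelty_penalty
#' * novel`, then perturbed by a Normal participant effect on the logit
#' scale; the produced stem is the target corrupted toward that expected
#' accuracy.  The produced affix is drawn from `affix_profile`, whose
#' exact-production probability is shifted on the logit scale by
#' `affix_round_slope` and `affix_novelty_penalty` and by the participant
#' effect.  The stem slopes default to the reported per-round and novelty
#' effects on the accuracy scale; the affix slopes default to round and
#' novelty effects of the size reported for the alternation-accuracy
#' logit model.
#'
#' @param base_accuracy Expected stem accuracy at the mid round for a
#'   trained item and an average participant.
#' @param round_slope Change in expected stem accuracy per round.
#' @param novelty_penalty Drop in expected stem accuracy for novel items.
#' @param participant_sd SD of the participant effect (logit scale).
#' @param affix_profile Probabilities over the five affix outcome types
#'   `exact`, `wrong_harmony`, `near_miss`, `unrelated`, `silent`; must sum
#'   to 1.
#' @param affix_round_slope,affix_novelty_penalty Logit-scale shifts of the
#'   exact-production probability per round and for novel items.
#' @return A list of class `prod_sim_params`.
#' @export
prod_sim_params <- function(base_accuracy = 0.65,
                            round_slope = 0.059,
                            novelty_penalty = 0.020,
                            participant_sd = 0.5,
                            affix_profile = c(exact = 0.55, wrong_harmony = 0.10,
                                              near_miss = 0.15, unrelated = 0.10,
                                              silent = 0.10),
                            affix_round_slope = 0.30,
                            affix_novelty_penalty = 1.2) {
  stopifnot(base_accuracy > 0, base_accuracy <= 1, participant_sd >= 0)
  wanted <- c("exact", "wrong_harmony", "near_miss", "unrelated", "silent")
  if (!setequal(names(affix_profile), wanted)) {
    stop("affix_profile must have exactly the outcomes: ",
         paste(wanted, collapse = ", "))
  }
  if (abs(sum(affix_profile) - 1) > 1e-9) {
    stop("affix_profile must sum to 1 (got ", sum(affix_profile), ")")
  }
  structure(list(base_accuracy = base_accuracy, round_slope = round_slope,
                 novelty_penalty = novelty_penalty,
                 participant_sd = participant_sd,
                 affix_profile = affix_profile[wanted],
                 affix_round_slope = affix_round_slope,
                 affix_novelty_penalty = affix_novelty_penalty),
            class = "prod_sim_params")
}

#' Simulate productions of the morphology experiment
#'
#' For every participant in an exp2 design, samples a constrained
#' 8-sentence training set, then emits one production of each of the 12
#' language sentences in each round: a stem transcription (the target stem
#' corrupted toward the trial's expected accuracy, see [corrupt_string()])
#' and an affix transcription drawn from the affix outcome profile.
#'
#' @param language A [load_target_language()] object.
#' @param design Exp 2 design from [assign_speakers()] (`experiment =
#'   "exp2"`), or `NULL` to build the default 40-participant design.
#' @param params A [prod_sim_params()] object.
#' @param table,scheme Feature table and cost scheme.
#' @param rounds Round indices (default `1:6`).
#' @param seed Optional integer seed.
#' @return Data frame with one row per production: `participant`,
#'   `condition`, `round`, `item_id`, `novel`, `case`, `harmony`,
#'   `stem_target`, `affix_target`, `stem_transcription`,
#'   `affix_transcription` (space-separated canonical symbols).
#' @export
simulate_production_experiment <- function(language,
                                           design = NULL,
                                           params = prod_sim_params(),
                                           table = load_feature_table(),
                                           scheme = cost_scheme(table),
                                           rounds = 1:6,
                                           seed = NULL) {
  maybe_with_seed(seed, {
    if (is.null(design)) design <- assign_speakers("exp2")
    participants <- design$participants
    calib <- corruption_calibration()
    prof <- params$affix_profile
    sen <- language$sentences
    rows <- list()
    for (i in seq_len(nrow(participants))) {
      pid <- participants$participant[i]
      training <- sample_training_set(language)
      is_novel <- !(sen$sentence_id %in% training$sentence_id)
      u <- stats::rnorm(1L, 0, params$participant_sd)
      for (r in rounds) {
        ord <- sample.int(nrow(sen))
        for (j in ord) {
          mu <- params$base_accuracy +
            params$round_slope * (r - mean(rounds)) -
            params$novelty_penalty * is_novel[j]
          mu <- min(max(mu, 1e-3), 1)
          expected_acc <- stats::plogis(stats::qlogis(mu) + u)
          stem <- parse_phonemes(sen$stem[j], table)
          stem_prod <- corrupt_string(stem, expected_acc, table, scheme,
                                      calibration = calib)
          affix_prod <- draw_affix(sen$case[j], sen$harmony[j], language,
                                   table, prof, r - mean(rounds), is_novel[j],
                                   u, params)
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pid,
            condition = participants$condition[i],
            round = r,
            item_id = sen$sentence_id[j],
            novel = is_novel[j],
            case = sen$case[j],
            harmony = sen$harmony[j],
            stem_target = sen$stem[j],
            affix_target = sen$target_suffix[j],
            stem_transcription = format_phonemes(stem_prod),
            affix_transcription = format_phonemes(affix_prod),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}

draw_affix <- function(case, harmony, language, table, prof, round_c, novel,
                       u, params) {
  p_exact <- stats::plogis(stats::qlogis(prof[["exact"]]) +
                             params$affix_round_slope * round_c -
                             params$affix_novelty_penalty * novel + u)
  others <- prof[setdiff(names(prof), "exact")]
  probs <- if (sum(others) == 0 || p_exact >= 1) {
    c(exact = 1, others * 0)
  } else {
    c(exact = p_exact, others / sum(others) * (1 - p_exact))
  }
  outcome <- sample(names(probs), 1L, prob = probs)
  suff <- language$suffixes
  target <- suff$suffix[suff$case == case & suff$harmony == harmony]
  target_p <- parse_phonemes(target, table)
  switch(outcome,
    exact = target_p,
    wrong_harmony = parse_phonemes(
      suff$suffix[suff$case == case & suff$harmony != harmony], table),
    near_miss = single_feature_error(target_p, table),
    unrelated = random_nonsuffix(language, table, length(target_p)),
    silent = character(0)
  )
}

# Replace one random position by its nearest same-category neighbour.
single_feature_error <- function(syms, table) {
  pos <- sample.int(length(syms), 1L)
  cat <- phoneme_category(syms[pos], table)
  pool <- names(table$category)[table$category == cat]
  pool <- setdiff(pool, syms[pos])
  d <- vapply(pool, function(p) phoneme_distance(syms[pos], p, table), numeric(1))
  nearest <- pool[d == min(d)]
  syms[pos] <- if (length(nearest) == 1L) nearest else sample(nearest, 1L)
  syms
}

random_nonsuffix <- function(language, table, len) {
  canon <- vapply(language$suffixes$suffix,
                  function(s) format_phonemes(parse_phonemes(s, table)), "")
  for (k in 1:100) {
    cand <- sample(names(table$category), len, replace = TRUE)
    if (!(format_phonemes(cand) %in% canon)) return(cand)
  }
  stop("could not draw a non-suffix string")  # unreachable for real inventories
}

#' Corrupt a phoneme string toward a target accuracy
#'
#' Applies per-position noise to `target`: with a calibrated rate each
#' position is substituted (by a same-category phoneme drawn with
#' probability proportional to its feature-space similarity) or deleted,
#' and new phonemes are inserted.  The noise rate is chosen from a
#' precomputed Monte-Carlo calibration grid (rate x target length ->
#' mean scored accuracy) so that the mean [production_accuracy()] of the
#' corrupted string is close to `expected_accuracy`.  Accuracies below the
#' lowest calibrated mean are reached by mixing in fully deleted (empty)
#' productions; `expected_accuracy = 1` returns the target unchanged and
#' `expected_accuracy = 0` always returns the empty string.
#'
#' @param target Phoneme string (symbols or a transcription string).
#' @param expected_accuracy Desired mean accuracy in \[0, 1\].
#' @param table,scheme Feature table and cost scheme.
#' @param calibration Calibration grid from [corruption_calibration()].
#' @param seed Optional integer seed.
#' @return Character vector of phoneme symbols (possibly empty).
#' @export
corrupt_string <- function(target, expected_accuracy, table, scheme,
                           calibration = corruption_calibration(),
                           seed = NULL) {
  if (expected_accuracy < 0 || expected_accuracy > 1) {
    stop("expected_accuracy must lie in [0, 1]")
  }
  syms <- parse_phonemes(target, table)
  if (length(syms) == 0L) stop("target string must be non-empty")
  if (expected_accuracy >= 1) return(syms)
  if (expected_accuracy <= 0) return(character(0))
  maybe_with_seed(seed, corrupt_string_impl(syms, expected_accuracy, table,
                                            scheme, calibration))
}

corrupt_string_impl <- function(syms, expected_accuracy, table, scheme,
                                calibration) {
  curve <- calibration_curve(calibration, length(syms))
  floor_acc <- min(curve$mean_accuracy)
  if (expected_accuracy < floor_acc) {
    # linear mixture with the empty (accuracy-0) production
    if (stats::runif(1) < 1 - expected_accuracy / floor_acc) {
      return(character(0))
    }
    rate <- curve$rate[which.min(curve$mean_accuracy)]
  } else {
    rate <- stats::approx(curve$mean_accuracy, curve$rate,
                          xout = expected_accuracy, rule = 2)$y
  }
  corrupt_once(syms, rate, table, scheme)
}

# One pass of per-position noise at rate r: substitution probability 0.6r,
# deletion 0.25r, insertion after each position 0.15r.
corrupt_once <- function(syms, rate, table, scheme) {
  out <- character(0)
  all_syms <- names(table$category)
  for (s in syms) {
    roll <- stats::runif(1)
    if (roll < 0.25 * rate) {
      # deleted
    } else if (roll < 0.85 * rate) {
      out <- c(out, similar_substitute(s, table, scheme))
    } else {
      out <- c(out, s)
    }
    if (stats::runif(1) < 0.15 * rate) {
      out <- c(out, sample(all_syms, 1L))
    }
  }
  out
}

# Same-category substitute, drawn with weight 1 - substitution cost.
similar_substitute <- function(s, table, scheme) {
  cat <- phoneme_category(s, table)
  pool <- names(table$category)[table$category == cat]
  pool <- setdiff(pool, s)
  w <- vapply(pool, function(p) 1 - substitution_cost(s, p, table, scheme),
              numeric(1))
  sample(pool, 1L, prob = pmax(w, 1e-6))
}

calibration_curve <- function(calibration, len) {
  lens <- sort(unique(calibration$length))
  len <- lens[which.min(abs(lens - len))]
  curve <- calibration[calibration$length == len, ]
  curve <- curve[order(curve$rate), ]
  # enforce monotone non-increasing accuracy in rate (smooths MC noise)
  curve$mean_accuracy <- cummin(curve$mean_accuracy)
  curve <- curve[!duplicated(curve$mean_accuracy), ]
  curve
}

#' Corruption calibration grid
#'
#' Loads (and caches) the shipped noise-rate calibration grid mapping
#' (target length, noise rate) to the Monte-Carlo mean accuracy of
#' [corrupt_once] productions.  The grid is produced by
#' [build_corruption_calibration()] with a fixed internal seed.
#'
#' @param path CSV path; default is the grid shipped with the package.
#' @return Data frame with columns `length`, `rate`, `mean_accuracy`.
#' @export
corruption_calibration <- function(path = speakvar_extdata("corruption_calibration.csv")) {
  key <- paste0("calib:", path)
  if (is.null(.speakvar_cache[[key]])) {
    .speakvar_cache[[key]] <- utils::read.csv(path, comment.char = "#",
                                              fileEncoding = "UTF-8")
  }
  .speakvar_cache[[key]]
}

#' Build the corruption calibration grid
#'
#' Monte-Carlo estimation of the mean scored accuracy of corrupted random
#' strings for every combination of target length and noise rate.  Run
#' once (with a fixed seed) to produce the grid shipped with the package.
#'
#' @param table,scheme Feature table and cost scheme.
#' @param lengths Target string lengths to calibrate.
#' @param rates Noise rates to calibrate.
#' @param n_draws Monte-Carlo draws per grid cell.
#' @param seed Seed for the whole grid construction.
#' @return Data frame with columns `length`, `rate`, `mean_accuracy`.
#' @export
build_corruption_calibration <- function(table = load_feature_table(),
                                         scheme = cost_scheme(table),
                                         lengths = 2:10,
                                         rates = seq(0, 1, by = 0.1),
                                         n_draws = 400L,
                                         seed = 20150609L) {
  all_syms <- names(table$category)
  withr::with_seed(seed, {
    grid <- expand.grid(length = lengths, rate = rates)
    grid$mean_accuracy <- vapply(seq_len(nrow(grid)), function(g) {
      len <- grid$length[g]
      rate <- grid$rate[g]
      accs <- vapply(seq_len(n_draws), function(k) {
        tgt <- sample(all_syms, len, replace = TRUE)
        prod <- corrupt_once(tgt, rate, table, scheme)
        production_accuracy(prod, tgt, table, scheme)$accuracy
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    grid[order(grid$length, grid$rate), ]
  })
}
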