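#' The CV lexicon of the segmentation experiment
#'
#' Twelve consonant-vowel syllables over consonants \{p, t, b, d\} and
#' vowels \{a, i, u\}, and six trisyllabic words built from them.  The
#' default word set is *babupu, bupada, dutaba, patubi, pidabu, tutibu*.
#'
#' @param words Character vector of trisyllabic words; each must decompose
#'   into three inventory syllables.
#' @param consonants,vowels Syllable inventory components.
#' @return An object of class `cv_lexicon` with `syllables`, `words` and
#'   `word_syllables` (a list of length-3 syllable vectors).
#' @export
cv_lexicon <- function(words = c("babupu", "bupada", "dutaba",
                                 "patubi", "pidabu", "tutibu"),
                       consonants = c("p", "t", "b", "d"),
                       vowels = c("a", "i", "u")) {
  syllables <- as.vector(outer(consonants, vowels, paste0))
  word_syllables <- lapply(words, function(w) {
    if (nchar(w) %% 2L != 0L) stop("word '", w, "' is not a CV concatenation")
    syl <- substring(w, seq(1L, nchar(w), 2L), seq(2L, nchar(w), 2L))
    bad <- setdiff(syl, syllables)
    if (length(bad) > 0L) {
      stop("word '", w, "' uses syllable(s) outside the inventory: ",
           paste(bad, collapse = ", "))
    }
    syl
  })
  if (anyDuplicated(words)) stop("duplicate words in the lexicon")
  structure(list(syllables = syllables, words = words,
                 word_syllables = stats::setNames(word_syllables, words),
                 consonants = consonants, vowels = vowels),
            class = "cv_lexicon")
}

#' @export
print.cv_lexicon <- function(x, ...) {
  cat("<cv_lexicon>", length(x$syllables), "syllables;", length(x$words),
      "words:", paste(x$words, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a TP-controlled continuous speech stream
#'
#' Randomly orders `tokens_per_word` tokens of each word, then removes
#' adjacent duplicate word tokens (each run of identical adjacent tokens is
#' collapsed to its first member, which is the fixpoint of deleting every
#' token equal to its surviving predecessor).  The syllable-level
#' transitional probability (TP) table is computed on the resulting
#' sequence, and the stream is accepted only if every word-internal bigram
#' has a strictly higher TP than every bigram type occurring only across a
#' word boundary; otherwise the stream is regenerated (bounded retries)
#' with fresh randomness.
#'
#' @param lexicon A [cv_lexicon()].
#' @param tokens_per_word Number of tokens of each word before duplicate
#'   elimination (default 300).
#' @param seed Optional integer seed.
#' @param max_retries Retry budget for the TP-separation property.
#' @return An object of class `speech_stream`: a list with `word_sequence`,
#'   `syllable_sequence`, `boundary_index` (positions in the syllable
#'   sequence at which a new word starts), `tp_table` (data frame `from`,
#'   `to`, `count`, `tp`), `token_counts` (post-elimination word counts)
#'   and `lexicon`.
#' @export
generate_stream <- function(lexicon, tokens_per_word = 300, seed = NULL,
                            max_retries = 25L) {
  stopifnot(inherits(lexicon, "cv_lexicon"), tokens_per_word >= 1)
  if (length(lexicon$words) < 2L) {
    stop("at least 2 distinct words are needed for an adjacent-duplicate-free stream")
  }
  maybe_with_seed(seed, generate_stream_impl(lexicon, tokens_per_word, max_retries))
}

generate_stream_impl <- function(lexicon, tokens_per_word, max_retries) {
  for (attempt in seq_len(max_retries)) {
    words <- sample(rep(lexicon$words, tokens_per_word))
    words <- eliminate_adjacent_duplicates(words)
    bundle <- build_stream_bundle(words, lexicon)
    sep <- tp_separation(bundle)
    if (sep$min_within > sep$max_cross) return(bundle)
  }
  stop("TP-separation property not attained within ", max_retries, " retries")
}

# Delete every token equal to its surviving predecessor, repeated to
# fixpoint; equivalent to collapsing runs of identical adjacent tokens.
eliminate_adjacent_duplicates <- function(x) {
  if (length(x) <= 1L) return(x)
  x[c(TRUE, x[-1L] != x[-length(x)])]
}

build_stream_bundle <- function(words, lexicon) {
  syl_list <- lexicon$word_syllables[words]
  lens <- lengths(syl_list)
  syllables <- unlist(syl_list, use.names = FALSE)
  boundary <- cumsum(c(1L, lens[-length(lens)]))
  structure(
    list(word_sequence = words,
         syllable_sequence = syllables,
         boundary_index = boundary,
         tp_table = transitional_probabilities(syllables),
         token_counts = table(factor(words, lexicon$words)),
         lexicon = lexicon),
    class = "speech_stream"
  )
}

#' @export
print.speech_stream <- function(x, ...) {
  sep <- tp_separation(x)
  cat("<speech_stream>", length(x$word_sequence), "word tokens,",
      length(x$syllable_sequence), "syllables; min within-word TP",
      round(sep$min_within, 3), "> max cross-boundary TP",
      round(sep$max_cross, 3), "\n")
  invisible(x)
}

#' Syllable-to-syllable transitional probabilities
#'
#' For every attested bigram XY, TP(X -> Y) = count(XY) / count(X), where
#' count(X) counts occurrences of X in all but the final position of the
#' sequence, so that each row of the table is a probability distribution
#' over successors.  Unattested bigrams have TP 0 (they are simply absent
#' from the table).
#'
#' @param syllable_sequence Character vector of at least 2 syllables.
#' @return Data frame with columns `from`, `to`, `count`, `tp`.
#' @export
transitional_probabilities <- function(syllable_sequence) {
  n <- length(syllable_sequence)
  if (n < 2L) stop("sequence must have at least 2 syllables")
  from <- syllable_sequence[-n]
  to <- syllable_sequence[-1L]
  key <- paste(from, to)
  counts <- table(key)
  first_tot <- table(from)
  out <- data.frame(
    from = sub(" .*", "", names(counts)),
    to = sub(".* ", "", names(counts)),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$tp <- out$count / as.integer(first_tot[out$from])
  rownames(out) <- NULL
  out
}

# TP of one bigram in a stream's table; 0 if unattested.
lookup_tp <- function(tp_table, from, to) {
  hit <- tp_table$from == from & tp_table$to == to
  if (any(hit)) tp_table$tp[hit] else 0
}

# Within-word vs cross-boundary TP summary.  A bigram type counts as
# within-word if it is internal to some lexical word; cross-boundary TPs
# are those of attested bigram types spanning boundaries only.
tp_separation <- function(bundle) {
  lex <- bundle$lexicon
  internal <- unique(unlist(lapply(lex$word_syllables, function(s) {
    paste(s[-length(s)], s[-1L])
  })))
  key <- paste(bundle$tp_table$from, bundle$tp_table$to)
  within <- bundle$tp_table$tp[key %in% internal]
  cross <- bundle$tp_table$tp[!(key %in% internal)]
  list(min_within = if (length(within)) min(within) else Inf,
       max_cross = if (length(cross)) max(cross) else -Inf)
}

#' Generate zero-TP foils for a stream
#'
#' Foils are trisyllables over the stream's syllable inventory that are not
#' lexical words and whose two internal syllable bigrams are both
#' unattested in the stream (transitional probability 0).  The requested
#' number is drawn uniformly without replacement from the full qualifying
#' set.
#'
#' @param bundle A [generate_stream()] result.
#' @param n_foils Number of foils (default 6).
#' @param seed Optional integer seed.
#' @return Character vector of foil words.
#' @export
generate_foils <- function(bundle, n_foils = 6, seed = NULL) {
  stopifnot(inherits(bundle, "speech_stream"), n_foils >= 0)
  if (n_foils == 0L) return(character(0))
  syl <- bundle$lexicon$syllables
  attested <- paste(bundle$tp_table$from, bundle$tp_table$to)
  triples <- expand.grid(s1 = syl, s2 = syl, s3 = syl,
                         stringsAsFactors = FALSE)
  ok <- !(paste(triples$s1, triples$s2) %in% attested) &
    !(paste(triples$s2, triples$s3) %in% attested)
  cand <- paste0(triples$s1, triples$s2, triples$s3)[ok]
  cand <- setdiff(cand, bundle$lexicon$words)
  if (length(cand) < n_foils) {
    stop("only ", length(cand), " qualifying zero-TP trisyllables exist; ",
         n_foils, " requested")
  }
  maybe_with_seed(seed, sample(cand, n_foils))
}

#' Build the two forced-choice test blocks
#'
#' Each block pairs every word with every foil exactly once (36 pairings
#' for the default 6 x 6 design), shuffled, with an independent random
#' within-pair presentation order.  In the familiar block, a single-speaker
#' participant hears their training voice throughout, while a
#' multiple-speaker participant hears each training voice on exactly one
#' third of the pairings; the novel block uses the held-out voice.
#'
#' @param lexicon A [cv_lexicon()].
#' @param foils Character vector of foils (from [generate_foils()]).
#' @param design List describing one participant's assignment:
#'   `condition` (`"single"` or `"multiple"`), `training_voices`
#'   (1 or 3 voice ids), `novel_voice` (a voice id not in training) and
#'   `familiar_first` (logical block order).
#' @param seed Optional integer seed.
#' @return List with `familiar` and `novel` test blocks (data frames with
#'   `trial`, `word`, `foil`, `word_first`, `voice`, `block_kind`) and
#'   `block_order` (the block kinds in presentation order).
#' @export
build_test_blocks <- function(lexicon, foils, design, seed = NULL) {
  stopifnot(inherits(lexicon, "cv_lexicon"))
  n_tr <- length(design$training_voices)
  if (design$condition == "single" && n_tr != 1L) {
    stop("single-speaker design requires exactly 1 training voice, got ", n_tr)
  }
  if (design$condition == "multiple" && n_tr != 3L) {
    stop("multiple-speaker design requires exactly 3 training voices, got ", n_tr)
  }
  if (design$novel_voice %in% design$training_voices) {
    stop("novel voice must not be one of the training voices")
  }
  pairs <- expand.grid(word = lexicon$words, foil = foils,
                       stringsAsFactors = FALSE)
  n <- nrow(pairs)
  maybe_with_seed(seed, {
    make_block <- function(kind) {
      b <- pairs[sample.int(n), ]
      b$trial <- seq_len(n)
      b$word_first <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (kind == "novel") {
        b$voice <- design$novel_voice
      } else if (design$condition == "single") {
        b$voice <- design$training_voices
      } else {
        if (n %% n_tr != 0L) {
          stop("pair count ", n, " not divisible across ", n_tr, " voices")
        }
        b$voice <- sample(rep(design$training_voices, n / n_tr))
      }
      b$block_kind <- kind
      rownames(b) <- NULL
      b[, c("trial", "word", "foil", "word_first", "voice", "block_kind")]
    }
    familiar <- make_block("familiar")
    novel <- make_block("novel")
    order_kinds <- if (isTRUE(design$familiar_first)) c("familiar", "novel")
    else c("novel", "familiar")
    list(familiar = familiar, novel = novel, block_order = order_kinds)
  })
}

#' Counterbalanced speaker assignment for an experiment
#'
#' For the segmentation experiment (`"exp1"`), participants in the
#' single-speaker condition are balanced over the 4 voices and those in
#' the multiple-speaker condition over the 4 possible 3-voice subsets,
#' with the familiar-first/novel-first test order counterbalanced within
#' each condition; single-speaker novel voices rotate so that each
#' familiar/novel voice combination is used equally often.  For the
#' morphology experiment (`"exp2"`), single-speaker participants are
#' balanced over the 3 speakers and each multiple-speaker participant gets
#' a random sentence-to-speaker map over their 8 training sentences with
#' at least 2 sentences per speaker, fixed across rounds.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_per_condition Number of participants per condition (defaults:
#'   24 for exp1, 20 for exp2).  exp1 requires a multiple of 8 so voices,
#'   novel voices and test orders balance.
#' @param voices Voice ids (4 for exp1, 3 for exp2).
#' @param seed Optional integer seed.
#' @return For exp1, a data frame with one row per participant:
#'   `participant`, `condition`, `training_voices` (comma-separated),
#'   `novel_voice`, `familiar_first`.  For exp2, a list with `participants`
#'   (rows: `participant`, `condition`, `speaker` for single-speaker
#'   participants) and `sentence_assignments` (rows: `participant`,
#'   `sentence_pos` 1..8, `speaker`, for multiple-speaker participants).
#' @export
assign_speakers <- function(experiment = c("exp1", "exp2"),
                            n_per_condition = NULL,
                            voices = NULL, seed = NULL) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    n_per_condition <- n_per_condition %||% 24L
    voices <- voices %||% c("en1", "us2", "de1", "us1")
    if (length(voices) != 4L) stop("exp1 requires 4 voices")
    if (n_per_condition %% 8L != 0L) {
      stop("exp1 counterbalancing requires a multiple of 8 participants ",
           "per condition (4 voices/voice-sets x 2 test orders); got ",
           n_per_condition)
    }
    maybe_with_seed(seed, assign_exp1(n_per_condition, voices))
  } else {
    n_per_condition <- n_per_condition %||% 20L
    voices <- voices %||% c("hu1", "hu2", "hu3")
    if (length(voices) != 3L) stop("exp2 requires 3 speakers")
    if (n_per_condition < length(voices)) {
      stop("exp2 requires at least one participant per speaker; got ",
           n_per_condition)
    }
    maybe_with_seed(seed, assign_exp2(n_per_condition, voices))
  }
}

assign_exp1 <- function(n, voices) {
  per_cell <- n / 4L
  single <- data.frame(
    participant = sprintf("s%02d", seq_len(n)),
    condition = "single",
    training_voices = rep(voices, each = per_cell),
    stringsAsFactors = FALSE
  )
  # rotate novel voices so each familiar/novel combination is used equally
  single$novel_voice <- unlist(lapply(seq_len(n), function(i) {
    others <- setdiff(voices, single$training_voices[i])
    others[((i - 1L) %% 3L) + 1L]
  }))
  subsets <- utils::combn(voices, 3L, simplify = FALSE)
  multiple <- data.frame(
    participant = sprintf("m%02d", seq_len(n)),
    condition = "multiple",
    training_voices = rep(vapply(subsets, paste, "", collapse = ","),
                          each = per_cell),
    stringsAsFactors = FALSE
  )
  multiple$novel_voice <- rep(vapply(subsets, function(s) setdiff(voices, s), ""),
                              each = per_cell)
  out <- rbind(single, multiple)
  out$familiar_first <- rep(c(TRUE, FALSE), length.out = nrow(out))
  # shuffle participant order without disturbing the counterbalancing cells
  out <- out[sample.int(nrow(out)), ]
  out$participant <- sprintf("p%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

assign_exp2 <- function(n, voices) {
  # single condition: balanced speaker assignment (each >= floor(n/3))
  speaker <- sample(rep(voices, length.out = n))
  participants <- rbind(
    data.frame(participant = sprintf("s%02d", seq_len(n)), condition = "single",
               speaker = speaker, stringsAsFactors = FALSE),
    data.frame(participant = sprintf("m%02d", seq_len(n)), condition = "multiple",
               speaker = NA_character_, stringsAsFactors = FALSE)
  )
  rownames(participants) <- NULL
  maps <- lapply(seq_len(n), function(i) {
    # 8 training sentences over 3 speakers, each speaker >= 2 sentences
    repeat {
      m <- sample(voices, 8L, replace = TRUE)
      if (all(table(factor(m, voices)) >= 2L)) break
    }
    data.frame(participant = sprintf("m%02d", i), sentence_pos = 1:8,
               speaker = m, stringsAsFactors = FALSE)
  })
  list(participants = participants,
       sentence_assignments = do.call(rbind, maps))
}

#' Export a syllable stream as MBROLA `.pho` text
#'
#' One phone per line: the consonant of each CV syllable gets 60 ms and the
#' vowel the remaining 218 ms of the 278 ms syllable, each with a single
#' constant-F0 pitch target at the start of the phone.  No pauses are
#' inserted at word boundaries.
#'
#' @param bundle A [generate_stream()] result, or a character vector of CV
#'   syllables.
#' @param f0 Fundamental frequency in Hz (100 for the male voices, 200 for
#'   the female voice).
#' @param syllable_ms,consonant_ms Syllable and consonant durations in ms.
#' @param path Optional output file; if `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the character
#'   vector of `.pho` lines.
#' @export
export_pho <- function(bundle, f0 = 100, syllable_ms = 278, consonant_ms = 60,
                       path = NULL) {
  syllables <- if (inherits(bundle, "speech_stream")) {
    bundle$syllable_sequence
  } else {
    as.character(bundle)
  }
  vowel_ms <- syllable_ms - consonant_ms
  lines <- character(0)
  if (length(syllables) > 0L) {
    bad <- syllables[nchar(syllables) != 2L]
    if (length(bad) > 0L) {
      stop("cannot map syllable(s) to a consonant+vowel phone pair: ",
           paste(unique(bad), collapse = ", "))
    }
    cons <- substring(syllables, 1L, 1L)
    vow <- substring(syllables, 2L, 2L)
    lines <- as.vector(rbind(
      sprintf("%s %d 0 %d", cons, consonant_ms, f0),
      sprintf("%s %d 0 %d", vow, vowel_ms, f0)
    ))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Expand one row of the exp1 design table for block construction
#'
#' Converts a row of the [assign_speakers()] exp1 table into the design
#' list consumed by [build_test_blocks()].
#'
#' @param row A single-row data frame from the exp1 design table.
#' @return List with `condition`, `training_voices`, `novel_voice` and
#'   `familiar_first`.
#' @export
exp1_participant_design <- function(row) {
  stopifnot(nrow(row) == 1L)
  list(condition = row$condition,
       training_voices = strsplit(row$training_voices, ",", fixed = TRUE)[[1]],
       novel_voice = row$novel_voice,
       familiar_first = row$familiar_first)
}
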