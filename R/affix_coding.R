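#' Load the vowel-harmony target language
#'
#' Reads a YAML (or JSON) description of the miniature case-marking
#' language: 4 noun stems, 2 per \[±back\] harmony class, and 3 locative
#' cases (inessive, adessive, superessive), each with a front and a back
#' suffix alternation.  The 12 sentences of the language are the full
#' noun-by-case cross, each carrying the harmony-appropriate target suffix.
#' Validation enforces the counts, the harmony balance, and pairwise
#' distinctness of the 6 suffixes (which guarantees the nesting of the
#' three affix-coding measures).
#'
#' @param path Path to the language config; default is the reconstruction
#'   shipped with the package.
#' @param table A [load_feature_table()] used to validate transcriptions.
#' @return An object of class `target_language`: a list with `nouns` (data
#'   frame: `stem`, `harmony`, `gloss`, `image_id`), `cases` (data frame:
#'   `name`, `front_suffix`, `back_suffix`), `suffixes` (data frame: `case`,
#'   `harmony`, `suffix`) and `sentences` (data frame of all 12
#'   noun-by-case items with `sentence_id`, `stem`, `harmony`, `case`,
#'   `target_suffix`, `image_id`).
#' @examples
#' lang <- load_target_language()
#' lang$sentences[1:3, c("stem", "case", "target_suffix")]
#' @export
load_target_language <- function(path = speakvar_extdata("language.yaml"),
                                 table = load_feature_table()) {
  if (!file.exists(path)) stop("language config does not exist: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$nouns) || is.null(cfg$cases)) {
    stop("language config must have 'nouns' and 'cases' entries: ", path)
  }
  nouns <- do.call(rbind, lapply(cfg$nouns, function(x) {
    data.frame(stem = x$stem, harmony = x$harmony,
               gloss = x$gloss %||% NA_character_,
               image_id = x$image_id %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  cases <- do.call(rbind, lapply(cfg$cases, function(x) {
    data.frame(name = x$name, front_suffix = x$front_suffix,
               back_suffix = x$back_suffix, stringsAsFactors = FALSE)
  }))
  if (nrow(nouns) != 4L) stop("language must have exactly 4 nouns, got ", nrow(nouns))
  if (!all(nouns$harmony %in% c("front", "back"))) {
    stop("noun harmony must be 'front' or 'back'")
  }
  if (!all(table(factor(nouns$harmony, c("front", "back"))) == 2L)) {
    stop("language must have 2 nouns per harmony class")
  }
  if (nrow(cases) != 3L || !setequal(cases$name, c("inessive", "adessive", "superessive"))) {
    stop("language must have exactly the inessive, adessive and superessive cases")
  }
  suffixes <- data.frame(
    case = rep(cases$name, each = 2L),
    harmony = rep(c("front", "back"), times = 3L),
    suffix = as.vector(rbind(cases$front_suffix, cases$back_suffix)),
    stringsAsFactors = FALSE
  )
  canon <- vapply(suffixes$suffix,
                  function(s) paste(parse_phonemes(s, table), collapse = " "), "")
  if (anyDuplicated(canon)) {
    stop("the 6 suffixes must be pairwise distinct as phoneme strings")
  }
  for (s in nouns$stem) parse_phonemes(s, table)  # validate stems
  sentences <- merge(nouns, data.frame(case = cases$name, stringsAsFactors = FALSE))
  sentences$target_suffix <- mapply(function(cs, h) {
    suffixes$suffix[suffixes$case == cs & suffixes$harmony == h]
  }, sentences$case, sentences$harmony)
  sentences$sentence_id <- paste(sentences$stem, sentences$case, sep = "-")
  sentences <- sentences[order(sentences$stem, sentences$case),
                         c("sentence_id", "stem", "harmony", "case",
                           "target_suffix", "image_id")]
  rownames(sentences) <- NULL
  if (nrow(sentences) != 12L) stop("expected 12 sentences, got ", nrow(sentences))
  structure(list(nouns = nouns, cases = cases, suffixes = suffixes,
                 sentences = sentences),
            class = "target_language")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.target_language <- function(x, ...) {
  cat("<target_language>", nrow(x$nouns), "nouns x", nrow(x$cases),
      "cases =", nrow(x$sentences), "sentences; suffixes:",
      paste(x$suffixes$suffix, collapse = ", "), "\n")
  invisible(x)
}

#' Normalised edit distances from a produced affix to every suffix
#'
#' @param production Transcription of the produced affix (may be empty).
#' @param language A [load_target_language()] object.
#' @param table,scheme Feature table and cost scheme.
#' @return Named numeric vector of length 6 (names `case.harmony`) of
#'   [normalized_distance()] values.
#' @export
suffix_distances <- function(production, language, table, scheme) {
  d <- vapply(seq_len(nrow(language$suffixes)), function(i) {
    normalized_distance(production, language$suffixes$suffix[i], table, scheme)
  }, numeric(1))
  names(d) <- paste(language$suffixes$case, language$suffixes$harmony, sep = ".")
  d
}

#' Code a produced affix on the three binary measures
#'
#' Each produced affix is coded against the target language on three
#' increasingly stringent measures:
#' * `case_identification` — 1 iff the production unambiguously identifies
#'   the target case: its minimum normalised edit distance over the 6
#'   suffixes is attained only by suffixes of the target case (a tie with
#'   any other-case suffix is ambiguous and codes 0).
#' * `case_accuracy` — 1 iff the production exactly reproduces one of the
#'   two alternations of the target case (distance 0).
#' * `alternation_accuracy` — 1 iff the production exactly reproduces the
#'   harmony-appropriate target suffix.
#'
#' Because the 6 suffixes are pairwise distinct, the measures nest:
#' alternation accuracy implies case accuracy implies case identification.
#' An empty production is distance 1 from every suffix and codes (0, 0, 0).
#'
#' @param production Transcription of the produced affix.
#' @param target_case,target_harmony Case and harmony class of the target
#'   sentence.
#' @inheritParams suffix_distances
#' @return Named integer vector `c(case_identification, case_accuracy,
#'   alternation_accuracy)`.
#' @examples
#' lang <- load_target_language()
#' tab <- load_feature_table()
#' sch <- cost_scheme(tab)
#' code_affix("bEm", "inessive", "front", lang, tab, sch)  # 1, 0, 0
#' @export
code_affix <- function(production, target_case, target_harmony,
                       language, table, scheme) {
  stopifnot(target_case %in% language$cases$name,
            target_harmony %in% c("front", "back"))
  d <- suffix_distances(production, language, table, scheme)
  in_case <- language$suffixes$case == target_case
  eps <- 1e-12
  ident <- as.integer(min(d[in_case]) < min(d[!in_case]) - eps)
  case_acc <- as.integer(any(d[in_case] < eps))
  target_i <- in_case & language$suffixes$harmony == target_harmony
  alt_acc <- as.integer(d[target_i] < eps)
  c(case_identification = ident, case_accuracy = case_acc,
    alternation_accuracy = alt_acc)
}

#' Code a table of produced affixes
#'
#' Applies [code_affix()] row-wise to a production table with
#' `affix_transcription`, `case` and `harmony` columns, appending the
#' three binary coding columns.
#'
#' @param productions Data frame of productions.
#' @inheritParams suffix_distances
#' @return The input with `case_identification`, `case_accuracy` and
#'   `alternation_accuracy` columns appended.
#' @export
code_productions <- function(productions, language, table, scheme) {
  stopifnot(all(c("affix_transcription", "case", "harmony") %in% names(productions)))
  codes <- t(vapply(seq_len(nrow(productions)), function(i) {
    code_affix(productions$affix_transcription[i], productions$case[i],
               productions$harmony[i], language, table, scheme)
  }, integer(3)))
  productions$case_identification <- codes[, 1]
  productions$case_accuracy <- codes[, 2]
  productions$alternation_accuracy <- codes[, 3]
  productions
}

# Cache of enumerated valid training sets, keyed by the sentence ids.
.speakvar_cache <- new.env(parent = emptyenv())

#' Enumerate all valid 8-sentence training sets
#'
#' A training set is valid when it contains exactly 2 sentences per noun,
#' at least 2 sentences per case, and every one of the 6 suffix
#' alternations at least once.  All `choose(12, 8) = 495` subsets are
#' scanned.
#'
#' @param language A [load_target_language()] object.
#' @return List of integer vectors, each a set of row indices into
#'   `language$sentences`.
#' @export
enumerate_training_sets <- function(language) {
  sen <- language$sentences
  key <- paste(sen$sentence_id, collapse = "|")
  if (!is.null(.speakvar_cache[[key]])) return(.speakvar_cache[[key]])
  combos <- utils::combn(nrow(sen), 8L)
  alt <- paste(sen$case, sen$harmony)
  valid <- list()
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    if (all(table(factor(sen$stem[idx], unique(sen$stem))) == 2L) &&
        all(table(factor(sen$case[idx], unique(sen$case))) >= 2L) &&
        length(unique(alt[idx])) == 6L) {
      valid[[length(valid) + 1L]] <- idx
    }
  }
  if (length(valid) == 0L) {
    stop("language admits no valid 8-sentence training set")
  }
  .speakvar_cache[[key]] <- valid
  valid
}

#' Sample a constrained training set
#'
#' Draws uniformly from the family of valid 8-sentence subsets of the 12
#' language sentences (see [enumerate_training_sets()] for the
#' constraints).  The 4 held-out sentences are the novel test items; the
#' training set always contains all 4 stems and all 6 alternations, so the
#' whole language is in principle reconstructable from training.
#'
#' @param language A [load_target_language()] object.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses
#'   the current RNG state.
#' @return Data frame of 8 rows of `language$sentences`, with the chosen
#'   row indices in attribute `"indices"`.
#' @export
sample_training_set <- function(language, seed = NULL) {
  valid <- enumerate_training_sets(language)
  pick <- maybe_with_seed(seed, sample.int(length(valid), 1L))
  idx <- valid[[pick]]
  out <- language$sentences[idx, ]
  rownames(out) <- NULL
  attr(out, "indices") <- idx
  out
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
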