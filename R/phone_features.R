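#' Articulatory feature tables
#'
#' A `feature_table` holds the per-category articulatory feature vectors used
#' to cost phoneme substitutions when scoring transcribed productions.
#' Vowels are described by two features (Height, Forwardness) and consonants
#' by eight (Aspiration, Place, Constrictor, Stop, Nasal, Lateral, Sulcal,
#' Double), every value lying in \[0, 1\].  The table shipped with the
#' package covers the transcription set used for the production data:
#' 7 vowels and 21 consonants, with an ASCII alias map so that symbols such
#' as /ʃ/ or /tʃ/ can be written `S` and `tS` in plain-ASCII files.
#'
#' @param vowels,consonants,aliases Paths to CSV files.  The feature CSVs
#'   have columns `symbol,category,<feature...>`; the alias CSV has columns
#'   `ascii,ipa`.  Defaults are the tables shipped with the package.
#' @return An object of class `feature_table` with components `vowels` and
#'   `consonants` (numeric matrices, one row per phoneme), `category`
#'   (named character vector mapping symbol to category) and `aliases`
#'   (named character vector mapping accepted alias to canonical symbol).
#' @examples
#' tab <- load_feature_table()
#' tab$vowels["a", ]
#' phoneme_distance("y", "a", tab)
#' @export
load_feature_table <- function(vowels = speakvar_extdata("vowels.csv"),
                               consonants = speakvar_extdata("consonants.csv"),
                               aliases = speakvar_extdata("aliases.csv")) {
  vow <- read_feature_csv(vowels, expected_category = "vowel")
  con <- read_feature_csv(consonants, expected_category = "consonant")
  overlap <- intersect(rownames(vow), rownames(con))
  if (length(overlap) > 0L) {
    stop("symbol(s) present in both categories: ", paste(overlap, collapse = ", "))
  }
  alias_map <- character(0)
  if (!is.null(aliases)) {
    al <- utils::read.csv(aliases, comment.char = "#", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
    if (!all(c("ascii", "ipa") %in% names(al))) {
      stop("alias file must have columns 'ascii' and 'ipa': ", aliases)
    }
    bad <- setdiff(al$ipa, c(rownames(vow), rownames(con)))
    if (length(bad) > 0L) {
      stop("alias target(s) not in the inventory: ", paste(bad, collapse = ", "))
    }
    if (anyDuplicated(al$ascii)) {
      stop("duplicate alias in ", aliases)
    }
    alias_map <- stats::setNames(al$ipa, al$ascii)
  }
  category <- stats::setNames(
    c(rep("vowel", nrow(vow)), rep("consonant", nrow(con))),
    c(rownames(vow), rownames(con))
  )
  structure(
    list(vowels = vow, consonants = con, category = category, aliases = alias_map),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$vowels), "vowels x", ncol(x$vowels), "features;",
      nrow(x$consonants), "consonants x", ncol(x$consonants), "features\n")
  invisible(x)
}

speakvar_extdata <- function(file) {
  path <- system.file("extdata", file, package = "speakvar")
  if (path == "") stop("shipped data file not found: ", file)
  path
}

read_feature_csv <- function(path, expected_category) {
  if (!file.exists(path)) stop("feature table file does not exist: ", path)
  df <- utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("symbol", "category") %in% names(df))) {
    stop("feature CSV must have 'symbol' and 'category' columns: ", path)
  }
  feats <- setdiff(names(df), c("symbol", "category"))
  if (length(feats) == 0L) stop("no feature columns in ", path)
  for (i in seq_len(nrow(df))) {
    row_id <- paste0(path, " row ", i, " (symbol '", df$symbol[i], "')")
    if (is.na(df$symbol[i]) || !nzchar(df$symbol[i])) {
      stop("missing symbol at ", row_id)
    }
    if (!identical(df$category[i], expected_category)) {
      stop("unknown or unexpected category '", df$category[i], "' at ", row_id)
    }
    vals <- suppressWarnings(as.numeric(df[i, feats]))
    if (anyNA(vals)) stop("missing or non-numeric feature cell at ", row_id)
    if (any(vals < 0 | vals > 1)) {
      stop("feature value outside [0, 1] at ", row_id)
    }
  }
  if (anyDuplicated(df$symbol)) {
    stop("duplicate symbol '", df$symbol[anyDuplicated(df$symbol)], "' in ", path)
  }
  m <- as.matrix(df[, feats, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$symbol
  m
}

# Strip affricate tie bars (U+2322, U+2040, U+0361) and apply the alias map.
resolve_symbol <- function(sym, table) {
  sym <- gsub("[⌢⁀͡]", "", sym)
  out <- ifelse(sym %in% names(table$aliases), unname(table$aliases[sym]), sym)
  unknown <- setdiff(out, names(table$category))
  if (length(unknown) > 0L) {
    stop("unknown phoneme symbol(s): ", paste(unique(unknown), collapse = ", "))
  }
  out
}

phoneme_category <- function(sym, table) {
  unname(table$category[resolve_symbol(sym, table)])
}

feature_vector <- function(sym, table) {
  sym <- resolve_symbol(sym, table)
  if (table$category[sym] == "vowel") table$vowels[sym, ] else table$consonants[sym, ]
}

#' Tokenise a transcription into phoneme symbols
#'
#' Splits a transcription string into the phonemes of the inventory by
#' greedy longest-match against the canonical symbols and their ASCII
#' aliases.  Spaces and hyphens act as hard separators (suffixes are
#' conventionally written with a leading hyphen, e.g. `"-bEn"`, and
#' space-separated symbols are never merged into an affricate).  A
#' character vector of length > 1 is taken to be already tokenised and is
#' only alias-resolved.
#'
#' @param x A transcription: a single string, or a character vector of
#'   symbols.
#' @param table A [load_feature_table()] object.
#' @return Character vector of canonical phoneme symbols (possibly empty).
#' @examples
#' tab <- load_feature_table()
#' parse_phonemes("-bEn", tab)
#' parse_phonemes("ʃyvεg", tab)
#' @export
parse_phonemes <- function(x, table) {
  if (length(x) == 0L) return(character(0))
  if (length(x) > 1L) return(resolve_symbol(x, table))
  if (is.na(x)) stop("transcription is NA")
  x <- gsub("[⌢⁀͡]", "", x)
  chunks <- strsplit(x, "[ -]+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) return(character(0))
  cand <- c(names(table$category), names(table$aliases))
  cand <- cand[order(-nchar(cand))]
  out <- character(0)
  for (chunk in chunks) {
    rest <- chunk
    while (nzchar(rest)) {
      hit <- NA_character_
      for (s in cand) {
        if (startsWith(rest, s)) { hit <- s; break }
      }
      if (is.na(hit)) {
        stop("cannot tokenise transcription at position ",
             nchar(chunk) - nchar(rest) + 1L, " of '", chunk, "'")
      }
      out <- c(out, hit)
      rest <- substring(rest, nchar(hit) + 1L)
    }
  }
  resolve_symbol(out, table)
}

# Inverse of parse_phonemes for table output: space-separated canonical
# symbols, safe for round-tripping affricates.
format_phonemes <- function(syms) paste(syms, collapse = " ")

#' Feature-space distance between two phonemes
#'
#' The distance between two phonemes of the same category is the L1 (city
#' block) distance between their articulatory feature vectors: the sum of
#' absolute differences over every feature.  Cross-category pairs have no
#' feature distance; they are costed only by the flat cross-category
#' substitution cost of the [cost_scheme()].
#'
#' @param a,b Phoneme symbols (aliases accepted).
#' @param table A [load_feature_table()] object.
#' @return Non-negative number; 0 iff the feature vectors are identical.
#' @examples
#' tab <- load_feature_table()
#' phoneme_distance("y", "a", tab)   # 1.5
#' phoneme_distance("n", "tS", tab)  # 3.35
#' @export
phoneme_distance <- function(a, b, table) {
  ca <- phoneme_category(a, table)
  cb <- phoneme_category(b, table)
  if (!identical(ca, cb)) {
    stop("phoneme_distance is defined within a category only (got ",
         ca, " vs ", cb, "); cross-category pairs are costed by the scheme")
  }
  sum(abs(feature_vector(a, table) - feature_vector(b, table)))
}

#' Maximum within-category feature distance
#'
#' Brute-force scan over all unordered pairs of phonemes in a category.
#' These maxima are the normalisers of the substitution cost; for the
#' shipped tables they are 1.5 (vowels) and 4.25 (consonants).
#'
#' @param table A [load_feature_table()] object.
#' @param category `"vowel"` or `"consonant"`.
#' @return The largest pairwise L1 feature distance in the category
#'   (0 for a single-phoneme category).
#' @export
max_category_distance <- function(table, category = c("vowel", "consonant")) {
  category <- match.arg(category)
  m <- if (category == "vowel") table$vowels else table$consonants
  if (nrow(m) == 0L) stop("category '", category, "' has no phonemes")
  if (nrow(m) == 1L) return(0)
  best <- 0
  for (i in seq_len(nrow(m) - 1L)) {
    d <- rowSums(abs(sweep(m[(i + 1L):nrow(m), , drop = FALSE], 2L, m[i, ])))
    best <- max(best, d)
  }
  best
}

#' Edit-cost scheme for phoneme-string alignment
#'
#' Bundles the cost parameters of the weighted Levenshtein distance:
#' insertions and deletions cost `indel_cost`; substituting a phoneme by
#' another of the same category costs the L1 feature distance divided by the
#' category's maximum pairwise distance and scaled by
#' `within_category_scale`, so that the worst same-category substitution
#' costs exactly `within_category_scale`; replacing a vowel by a consonant
#' or vice versa costs `cross_category_cost`.  The category normalisers are
#' always recomputed from `table`; if `vowel_normalizer` or
#' `consonant_normalizer` is supplied it is checked against the recomputed
#' value and a mismatch is an error, which guards against silently edited
#' feature tables.
#'
#' @param table A [load_feature_table()] object.
#' @param indel_cost Insertion/deletion cost (default 1).
#' @param within_category_scale Cost of the worst same-category substitution
#'   (default 0.8).
#' @param cross_category_cost Cost of any cross-category substitution
#'   (default 1).
#' @param vowel_normalizer,consonant_normalizer Optional expected values of
#'   the category maxima (1.5 and 4.25 for the shipped tables).
#' @return An object of class `cost_scheme`.
#' @examples
#' tab <- load_feature_table()
#' sch <- cost_scheme(tab)
#' substitution_cost("k", "f", tab, sch)  # (1.3 / 4.25) * 0.8
#' @export
cost_scheme <- function(table, indel_cost = 1, within_category_scale = 0.8,
                        cross_category_cost = 1,
                        vowel_normalizer = NULL, consonant_normalizer = NULL) {
  stopifnot(indel_cost > 0, within_category_scale > 0, cross_category_cost > 0)
  vn <- max_category_distance(table, "vowel")
  cn <- max_category_distance(table, "consonant")
  if (vn <= 0 || cn <= 0) stop("category normalizers must be strictly positive")
  check_norm <- function(stated, computed, what) {
    if (!is.null(stated) && abs(stated - computed) > 1e-9) {
      stop(what, " normalizer computed from the table (", computed,
           ") does not match the configured value (", stated, ")")
    }
  }
  check_norm(vowel_normalizer, vn, "vowel")
  check_norm(consonant_normalizer, cn, "consonant")
  scheme <- list(indel_cost = indel_cost,
                 within_category_scale = within_category_scale,
                 cross_category_cost = cross_category_cost,
                 vowel_normalizer = vn, consonant_normalizer = cn)
  # precomputed symbol-by-symbol substitution costs: the alignment DP and
  # the simulators do many lookups over a small inventory
  syms <- names(table$category)
  M <- matrix(cross_category_cost, length(syms), length(syms),
              dimnames = list(syms, syms))
  for (cat in c("vowel", "consonant")) {
    feats <- if (cat == "vowel") table$vowels else table$consonants
    norm <- if (cat == "vowel") vn else cn
    ss <- rownames(feats)
    for (a in ss) {
      d <- rowSums(abs(sweep(feats, 2L, feats[a, ])))
      M[a, ss] <- d / norm * within_category_scale
    }
  }
  diag(M) <- 0
  scheme$cost_matrix <- M
  structure(scheme, class = "cost_scheme")
}

#' @export
print.cost_scheme <- function(x, ...) {
  cat("<cost_scheme> indel", x$indel_cost,
      "| within-category scale", x$within_category_scale,
      "| cross-category", x$cross_category_cost,
      "| normalizers", x$vowel_normalizer, "/", x$consonant_normalizer, "\n")
  invisible(x)
}

#' Substitution cost between two phonemes
#'
#' Identical symbols cost 0; same-category pairs cost
#' `(phoneme_distance / category normalizer) * within_category_scale`;
#' cross-category pairs cost `cross_category_cost`.
#'
#' @param a,b Phoneme symbols (aliases accepted).
#' @inheritParams cost_scheme
#' @param scheme A [cost_scheme()] object.
#' @return A cost in \[0, 1\].
#' @export
substitution_cost <- function(a, b, table, scheme) {
  a <- resolve_symbol(a, table)
  b <- resolve_symbol(b, table)
  cm <- scheme$cost_matrix
  if (!is.null(cm) && a %in% rownames(cm) && b %in% rownames(cm)) {
    return(cm[a, b])
  }
  if (identical(a, b)) return(0)
  ca <- table$category[a]
  cb <- table$category[b]
  if (ca != cb) return(scheme$cross_category_cost)
  norm <- if (ca == "vowel") scheme$vowel_normalizer else scheme$consonant_normalizer
  phoneme_distance(a, b, table) / norm * scheme$within_category_scale
}
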