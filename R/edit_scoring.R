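#' Weighted Levenshtein distance between phoneme strings
#'
#' Minimum total cost of transforming `source` into `target` using
#' insertions and deletions at `scheme$indel_cost` and substitutions at
#' [substitution_cost()], computed by dynamic programming.  Because every
#' per-position cost is at most 1, the raw distance divided by the length
#' of the longer string lies in \[0, 1\].
#'
#' @param source,target Transcriptions: strings or character vectors of
#'   phoneme symbols (see [parse_phonemes()]); either may be empty.
#' @param table A [load_feature_table()] object.
#' @param scheme A [cost_scheme()] object.
#' @return Non-negative number; 0 iff the strings are identical.
#' @examples
#' tab <- load_feature_table()
#' sch <- cost_scheme(tab)
#' weighted_edit_distance("kam", "fi", tab, sch)  # 2.0447...
#' @export
weighted_edit_distance <- function(source, target, table, scheme) {
  edit_dp(parse_phonemes(source, table), parse_phonemes(target, table),
          table, scheme)$distance
}

# DP over the full cost matrix; returns the matrix for traceback.
edit_dp <- function(s, t, table, scheme) {
  n <- length(s)
  m <- length(t)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- (0:n) * scheme$indel_cost
  D[1L, ] <- (0:m) * scheme$indel_cost
  if (n > 0L && m > 0L) {
    cm <- scheme$cost_matrix
    if (!is.null(cm) && all(s %in% rownames(cm)) && all(t %in% rownames(cm))) {
      sub <- cm[s, t, drop = FALSE]
    } else {
      sub <- matrix(0, n, m)
      for (i in seq_len(n)) {
        for (j in seq_len(m)) {
          sub[i, j] <- substitution_cost(s[i], t[j], table, scheme)
        }
      }
    }
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        D[i + 1L, j + 1L] <- min(
          D[i, j] + sub[i, j],                  # substitute (or match)
          D[i, j + 1L] + scheme$indel_cost,     # delete s[i]
          D[i + 1L, j] + scheme$indel_cost      # insert t[j]
        )
      }
    }
  }
  list(distance = D[n + 1L, m + 1L], D = D, s = s, t = t)
}

#' Length-normalised edit distance
#'
#' The weighted edit distance divided by the length of the longer string.
#' When both strings are empty the distance is defined as 0 (identity); the
#' case never arises for real targets.
#'
#' @inheritParams weighted_edit_distance
#' @return A distance in \[0, 1\].
#' @examples
#' tab <- load_feature_table()
#' sch <- cost_scheme(tab)
#' round(normalized_distance("kam", "fi", tab, sch), 3)  # 0.682
#' @export
normalized_distance <- function(source, target, table, scheme) {
  s <- parse_phonemes(source, table)
  t <- parse_phonemes(target, table)
  L <- max(length(s), length(t))
  if (L == 0L) return(0)
  edit_dp(s, t, table, scheme)$distance / L
}

#' Score a production against its target
#'
#' Full alignment result for one transcribed production: the raw and
#' length-normalised weighted edit distances, the accuracy score
#' (1 minus the normalised distance), and one optimal edit script.  When
#' several alignments attain the minimum cost the traceback prefers
#' substitution over deletion over insertion, so scripts are reproducible.
#'
#' @inheritParams weighted_edit_distance
#' @return An object of class `alignment_result`: a list with
#'   `raw_distance`, `normalized_distance`, `accuracy` and `edit_script`
#'   (a data frame with columns `op`, `source_pos`, `target_pos`, `from`,
#'   `to`, `cost`).
#' @examples
#' tab <- load_feature_table()
#' sch <- cost_scheme(tab)
#' production_accuracy("kam", "fi", tab, sch)$accuracy
#' @export
production_accuracy <- function(source, target, table, scheme) {
  s <- parse_phonemes(source, table)
  t <- parse_phonemes(target, table)
  if (length(t) == 0L) stop("target string must be non-empty")
  dp <- edit_dp(s, t, table, scheme)
  L <- max(length(s), length(t))
  nd <- dp$distance / L
  script <- traceback_script(dp, table, scheme)
  structure(
    list(raw_distance = dp$distance,
         normalized_distance = nd,
         accuracy = 1 - nd,
         edit_script = script),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> raw %.4f | normalized %.4f | accuracy %.4f\n",
              x$raw_distance, x$normalized_distance, x$accuracy))
  ops <- x$edit_script$op
  cat("edits:", if (nrow(x$edit_script) == 0L) "none" else
    paste(ops[ops != "match"], collapse = ", "), "\n")
  invisible(x)
}

traceback_script <- function(dp, table, scheme) {
  s <- dp$s; t <- dp$t; D <- dp$D
  i <- length(s); j <- length(t)
  rows <- list()
  eps <- 1e-12
  while (i > 0L || j > 0L) {
    stepped <- FALSE
    if (i > 0L && j > 0L) {
      cost <- substitution_cost(s[i], t[j], table, scheme)
      if (abs(D[i + 1L, j + 1L] - (D[i, j] + cost)) < eps) {
        rows[[length(rows) + 1L]] <- data.frame(
          op = if (cost == 0) "match" else "substitute",
          source_pos = i, target_pos = j, from = s[i], to = t[j], cost = cost,
          stringsAsFactors = FALSE)
        i <- i - 1L; j <- j - 1L; stepped <- TRUE
      }
    }
    if (!stepped && i > 0L &&
        abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + scheme$indel_cost)) < eps) {
      rows[[length(rows) + 1L]] <- data.frame(
        op = "delete", source_pos = i, target_pos = j, from = s[i], to = NA,
        cost = scheme$indel_cost, stringsAsFactors = FALSE)
      i <- i - 1L; stepped <- TRUE
    }
    if (!stepped) {
      rows[[length(rows) + 1L]] <- data.frame(
        op = "insert", source_pos = i, target_pos = j, from = NA, to = t[j],
        cost = scheme$indel_cost, stringsAsFactors = FALSE)
      j <- j - 1L
    }
  }
  out <- do.call(rbind, rev(rows))
  if (is.null(out)) {
    out <- data.frame(op = character(0), source_pos = integer(0),
                      target_pos = integer(0), from = character(0),
                      to = character(0), cost = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Score a table of transcribed productions
#'
#' Adds stem scoring columns to a production table (see
#' [read_production_table()] for the schema): `stem_raw_distance`,
#' `stem_normalized_distance` and `stem_accuracy`, each computed against
#' the `stem_target` column.
#'
#' @param productions Data frame with at least `stem_transcription` and
#'   `stem_target` columns.
#' @inheritParams weighted_edit_distance
#' @return The input data frame with the three scoring columns appended.
#' @export
score_productions <- function(productions, table, scheme) {
  stopifnot(all(c("stem_transcription", "stem_target") %in% names(productions)))
  n <- nrow(productions)
  raw <- norm <- acc <- numeric(n)
  for (i in seq_len(n)) {
    res <- production_accuracy(productions$stem_transcription[i],
                               productions$stem_target[i], table, scheme)
    raw[i] <- res$raw_distance
    norm[i] <- res$normalized_distance
    acc[i] <- res$accuracy
  }
  productions$stem_raw_distance <- raw
  productions$stem_normalized_distance <- norm
  productions$stem_accuracy <- acc
  productions
}
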