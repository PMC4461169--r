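# Shared fixtures and independent oracles for the test suite.

tt_table <- load_feature_table()
tt_scheme <- cost_scheme(tt_table)
tt_language <- load_target_language(table = tt_table)

# Exhaustive-recursion oracle for the weighted edit distance: plain
# top-down recursion with no memoisation or tabulation, independent of the
# package's dynamic program.
oracle_edit_distance <- function(s, t, table, scheme) {
  if (length(s) == 0L) return(length(t) * scheme$indel_cost)
  if (length(t) == 0L) return(length(s) * scheme$indel_cost)
  min(
    oracle_edit_distance(s[-1L], t, table, scheme) + scheme$indel_cost,
    oracle_edit_distance(s, t[-1L], table, scheme) + scheme$indel_cost,
    oracle_edit_distance(s[-1L], t[-1L], table, scheme) +
      substitution_cost(s[1L], t[1L], table, scheme)
  )
}

# Independent bigram counter for TP re-verification.
count_bigram <- function(seq, x, y) {
  sum(seq[-length(seq)] == x & seq[-1L] == y)
}

# All strings (as lists of symbol vectors) over `symbols` up to `max_len`.
all_strings_upto <- function(symbols, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grids <- do.call(expand.grid,
                     c(rep(list(symbols), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grids)), function(i) {
      as.character(unlist(grids[i, ]))
    }))
  }
  out
}

# Small mixed-category inventory for exhaustive string scans.
tt_mini_symbols <- c("a", "ɔ", "m", "k")

# Write a modified copy of the shipped language config and return its path.
write_language_variant <- function(edit_fun) {
  cfg <- yaml::read_yaml(system.file("extdata", "language.yaml",
                                     package = "speakvar"))
  cfg <- edit_fun(cfg)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

# Write a small feature-table CSV and return its path.
write_feature_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  path
}
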