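#' Pipeline configuration
#'
#' Bundles everything one reproducible end-to-end run needs: which
#' experiment to emulate, the master seed (every stage derives its own
#' seed deterministically from it), the input table paths and the output
#' directory.
#'
#' @param experiment `"exp1"` (segmentation) or `"exp2"` (morphology).
#' @param master_seed Integer master seed.
#' @param output_dir Output directory (created if missing).
#' @param feature_tables List with `vowels`, `consonants`, `aliases` paths;
#'   defaults to the shipped tables.
#' @param language_path Language config path (exp2; default shipped).
#' @param n_per_condition Participants per condition (defaults: 24 exp1,
#'   20 exp2).
#' @param tokens_per_word Stream tokens per word (exp1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = c("exp2", "exp1"),
                            master_seed = 1L,
                            output_dir = tempfile("speakvar_run_"),
                            feature_tables = list(
                              vowels = speakvar_extdata("vowels.csv"),
                              consonants = speakvar_extdata("consonants.csv"),
                              aliases = speakvar_extdata("aliases.csv")),
                            language_path = speakvar_extdata("language.yaml"),
                            n_per_condition = NULL,
                            tokens_per_word = 300L) {
  experiment <- match.arg(experiment)
  for (p in c(unlist(feature_tables), if (experiment == "exp2") language_path)) {
    if (!file.exists(p)) stop("configured input file does not exist: ", p)
  }
  structure(list(experiment = experiment,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir,
                 feature_tables = feature_tables,
                 language_path = language_path,
                 n_per_condition = n_per_condition,
                 tokens_per_word = tokens_per_word),
            class = "pipeline_config")
}

# Deterministic per-stage seed below 2^31, derived from the master seed.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master_seed) * 10007L + h %% 10007L) %% .Machine$integer.max
}

#' Run an end-to-end pipeline
#'
#' Executes generate -> simulate -> score/code -> fit -> report for the
#' configured experiment, writes every artifact as CSV/JSON under the
#' output directory, and returns (and writes) a manifest listing each file
#' with its MD5 hash and the seeds used.  Runs are idempotent for a fixed
#' config: the same config produces byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- load_feature_table(config$feature_tables$vowels,
                              config$feature_tables$consonants,
                              config$feature_tables$aliases)
  scheme <- cost_scheme(table)
  files <- if (config$experiment == "exp1") {
    run_exp1_pipeline(config, table)
  } else {
    run_exp2_pipeline(config, table, scheme)
  }
  manifest <- list(
    experiment = config$experiment,
    master_seed = config$master_seed,
    created = "run",  # no timestamps: keeps reruns byte-identical
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_exp1_pipeline <- function(config, table) {
  seed_of <- function(stage) stage_seed(config$master_seed, stage)
  lexicon <- cv_lexicon()
  design <- assign_speakers("exp1", n_per_condition = config$n_per_condition,
                            seed = seed_of("design"))
  stream <- generate_stream(lexicon, config$tokens_per_word,
                            seed = seed_of("stream"))
  foils <- generate_foils(stream, seed = seed_of("foils"))
  responses <- simulate_segmentation_experiment(design,
                                                seed = seed_of("simulate"))
  fit <- fit_mixed_model(responses, model_spec(
    "correct", "binomial",
    c("condition_multiple", "speaker_novel", "second_block",
      "condition_multiple:speaker_novel")))
  out <- config$output_dir
  stream_df <- data.frame(position = seq_along(stream$syllable_sequence),
                          syllable = stream$syllable_sequence,
                          boundary = seq_along(stream$syllable_sequence) %in%
                            stream$boundary_index)
  paths <- c(
    write_csv_artifact(stream_df, file.path(out, "stream.csv")),
    write_csv_artifact(data.frame(foil = foils), file.path(out, "foils.csv")),
    write_csv_artifact(design, file.path(out, "design.csv")),
    write_csv_artifact(responses, file.path(out, "responses.csv")),
    write_model_artifact(fit, file.path(out, "model_segmentation.json"))
  )
  paths
}

run_exp2_pipeline <- function(config, table, scheme) {
  seed_of <- function(stage) stage_seed(config$master_seed, stage)
  language <- load_target_language(config$language_path, table)
  design <- assign_speakers("exp2", n_per_condition = config$n_per_condition,
                            seed = seed_of("design"))
  productions <- simulate_production_experiment(language, design,
                                                table = table, scheme = scheme,
                                                seed = seed_of("simulate"))
  scored <- score_productions(productions, table, scheme)
  coded <- code_productions(scored, language, table, scheme)
  stem_fit <- fit_mixed_model(coded, model_spec(
    "stem_accuracy", "gaussian",
    c("condition", "novel", "round", "condition:novel", "condition:round",
      "novel:round", "condition:novel:round")))
  out <- config$output_dir
  paths <- c(
    write_csv_artifact(productions, file.path(out, "productions.csv")),
    write_csv_artifact(scored, file.path(out, "scores.csv")),
    write_csv_artifact(coded, file.path(out, "codes.csv")),
    write_model_artifact(stem_fit, file.path(out, "model_stem_accuracy.json"))
  )
  for (measure in c("case_identification", "case_accuracy",
                    "alternation_accuracy")) {
    fit <- fit_mixed_model(coded, model_spec(
      measure, "binomial",
      c("condition", "novel", "round", "condition:novel", "condition:round",
        "novel:round", "condition:novel:round")))
    paths <- c(paths, write_model_artifact(
      fit, file.path(out, paste0("model_", measure, ".json"))))
  }
  paths
}

write_csv_artifact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

write_model_artifact <- function(summary, path) {
  out <- list(family = summary$family,
              n_obs = summary$n_obs,
              converged = summary$converged,
              note = summary$note,
              coefficients = summary$coefficients,
              lrt = summary$lrt,
              report = report_model(summary))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Read and validate a production table
#'
#' Reads the CSV interchange format for transcribed productions
#' (columns `participant`, `condition`, `round`, `item_id`, `novel`,
#' `stem_transcription`, `affix_transcription`, plus any scoring columns)
#' and validates every transcription against the inventory, reporting the
#' offending row on failure.  Empty transcriptions (silent productions)
#' are allowed.
#'
#' @param path CSV path.
#' @param table A [load_feature_table()] for symbol validation.
#' @return Data frame of validated productions.
#' @export
read_production_table <- function(path, table = load_feature_table()) {
  if (!file.exists(path)) stop("production table does not exist: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("participant", "condition", "round", "item_id", "novel",
                "stem_transcription", "affix_transcription")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("production table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$round <- as.integer(df$round)
  df$novel <- df$novel %in% c("1", "TRUE", "true", "T")
  for (col in c("stem_transcription", "affix_transcription")) {
    for (i in seq_len(nrow(df))) {
      val <- df[[col]][i]
      if (is.na(val)) val <- ""
      tryCatch(parse_phonemes(val, table), error = function(e) {
        stop("row ", i, ", column '", col, "': ", conditionMessage(e),
             call. = FALSE)
      })
    }
  }
  df
}

#' Write a scored production table
#'
#' @param records Data frame (e.g. from [score_productions()] or
#'   [code_productions()]).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_scored_table <- function(records, path) {
  write_csv_artifact(records, path)
  invisible(path)
}
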