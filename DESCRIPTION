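Package: speakvar
Title: Speaker Input Variability Experiments: Stimuli, Phonetic Scoring and
    Mixed-Effects Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing artificial-language learning
    experiments that manipulate speaker input variability. Provides
    articulatory-feature-weighted Levenshtein scoring of transcribed
    phoneme-string productions, three-tier coding of vowel-harmony case
    suffixes against a miniature Hungarian-based target language,
    transitional-probability-controlled speech-stream stimuli with zero-TP
    foils and counterbalanced forced-choice test designs, simulation of
    synthetic learners with the statistical structure the analyses assume,
    and mixed-effects logistic and linear analyses of trial-level responses
    with paper-style reporting of odds and accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
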