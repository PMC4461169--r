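# speakvar

Tools for building and analysing artificial-language learning experiments
that manipulate **speaker input variability** — how many speakers provide a
learner's input.  The package serves experimental psycholinguists who run
(or re-analyse) two classic paradigms:

1. **Statistical word segmentation.** Learners hear a continuous stream of
   synthesised CV syllables in which the only cue to word boundaries is the
   transitional probability (TP) between syllables, $TP(X \to Y) =
   n(XY)/n(X)$, and are then tested on 36 two-alternative forced choices
   between words and zero-TP foils.  The package generates the lexicon, the
   TP-controlled stream (300 tokens per word, adjacent duplicates
   eliminated, within-word TPs strictly above cross-boundary TPs), the
   foils, the counterbalanced speaker assignments and test blocks, and
   MBROLA `.pho` text for synthesis.

2. **Learning a vowel-harmony morphology.** Learners acquire a miniature
   Hungarian-based language: 4 container nouns crossed with the inessive,
   adessive and superessive cases, each case suffix alternating between a
   front and a back form under vowel harmony (e.g. /-bεn/ ~ /-bɔn/).
   Spoken productions are transcribed and scored with an
   articulatory-feature-weighted Levenshtein distance: same-category
   substitutions cost the L1 feature distance normalised by the category
   maximum (1.5 for vowels, 4.25 for consonants) times 0.8, cross-category
   substitutions and indels cost 1, the string distance is normalised by
   the longer length, and accuracy is one minus that.  Produced affixes are
   coded on three nested binary measures (case identification, case
   accuracy, alternation accuracy) against all six suffixes.

Both paradigms come with synthetic-learner simulators that share the exact
statistical structure of the analyses (Bernoulli responses under a logit
model with participant random intercepts; productions whose accuracy
improves across rounds and dips for novel items), and with lme4-based
mixed-effects analyses using centred fixed effects, likelihood-ratio tests
against null models, and odds/accuracy report rendering.

## Worked example

Score the production /kam/ against the target /fi/ under the shipped
feature tables:

```r
library(speakvar)
tab <- load_feature_table()
sch <- cost_scheme(tab, vowel_normalizer = 1.5, consonant_normalizer = 4.25)
production_accuracy("kam", "fi", tab, sch)
#> <alignment_result> raw 2.0447 | normalized 0.6816 | accuracy 0.3184
#> edits: substitute, substitute, delete
```

The raw distance 2.0447 decomposes as substituting /k/ for /f/ at
(1.3/4.25) × 0.8 ≈ 0.245, substituting /a/ for /i/ at the vowel maximum
(1.5/1.5) × 0.8 = 0.8, and deleting /m/ at 1; dividing by the longer
length 3 gives the normalised distance 0.682 and accuracy 0.318.

Code an affix production against the language (ASCII aliases: `E` = /ε/,
`O` = /ɔ/):

```r
lang <- load_target_language()
code_affix("bEm", "inessive", "front", lang, tab, sch)
#> case_identification        case_accuracy alternation_accuracy
#>                   1                    0                    0
```

/-bεm/ is closest to the inessive suffixes (so the case is identified) but
matches neither alternation exactly.

Generate segmentation stimuli and convert a fitted coefficient to report
form:

```r
stream <- generate_stream(cv_lexicon(), tokens_per_word = 300, seed = 42)
stream
#> <speech_stream> 1500 word tokens, 4500 syllables; min within-word TP 0.253 > max cross-boundary TP 0.236
generate_foils(stream, seed = 43)
#> [1] "bibipa" "pudida" "pipapu" "tudita" "dutupa" "badipu"
logit_to_odds_prob(0.343)
#> $odds       1.409169
#> $probability 0.5849191
```

A learner with a 0.343-logit intercept is 1.41 times as likely to answer
correctly as not — an accuracy of 58%.

End-to-end synthetic runs (simulate → score → code → fit → report) are
driven by `run_pipeline(pipeline_config("exp2", master_seed = 7))`, which
writes CSV/JSON artifacts plus a hash manifest and is byte-reproducible
from its configuration.

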