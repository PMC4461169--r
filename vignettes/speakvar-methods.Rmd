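---
title: "Scoring, stimuli and models for speaker-variability learning experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, stimuli and models for speaker-variability learning experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speakvar)
```

`speakvar` re-implements, as reusable and tested components, the
computational machinery behind a pair of artificial-language learning
experiments on *speaker input variability* — the heterogeneity in a
learner's input that arises from how many speakers provide it.  The first
experiment is a statistical word-segmentation task: learners hear a
continuous stream of synthesised CV syllables and are tested on
discriminating words from foils in two-alternative forced choice.  The
second is a morphology-learning task: learners acquire a miniature
Hungarian-based language in which three locative case suffixes each
alternate between a front and a back form under vowel harmony, and their
spoken productions are transcribed and scored.  Because the original
behavioural data come from human participants, the package pairs every
analysis component with a synthetic-learner simulator that has exactly the
statistical structure the analyses assume, so the full pipeline can be
exercised and validated end to end.

## Articulatory-feature-weighted edit distance

Transcribed stem productions are scored against their targets with a
weighted Levenshtein distance over phoneme strings.  The per-phoneme
substitution cost is grounded in articulatory feature vectors: vowels are
described by Height and Forwardness, consonants by Aspiration, Place,
Constrictor, Stop, Nasal, Lateral, Sulcal and Double, all on $[0, 1]$.
The distance between two phonemes of the same category is the L1 distance
between their feature vectors,

$$d(a, b) = \sum_k \lvert f_k(a) - f_k(b)\rvert,$$

and the substitution cost rescales this to

$$c(a, b) = \frac{d(a, b)}{\max_{x,y \in \text{cat}} d(x, y)} \times 0.8,$$

so the *worst* same-category substitution costs 0.8.  For the shipped
tables the category maxima are exactly 1.5 (vowels) and 4.25
(consonants); `cost_scheme()` always recomputes them from the loaded
table and, if the caller states expected values, treats a mismatch as an
error — an edited feature file cannot silently shift every downstream
score.  Replacing a vowel with a consonant (or vice versa) costs 1, as do
insertions and deletions.  The string distance is the usual
dynamic-programming minimum over edit scripts, then divided by the length
of the longer string; since every per-position cost is at most 1 the
normalised distance lies in $[0, 1]$, and the production's *accuracy* is
one minus it.

```{r}
tab <- load_feature_table()
sch <- cost_scheme(tab, vowel_normalizer = 1.5, consonant_normalizer = 4.25)
production_accuracy("kam", "fi", tab, sch)
```

Numerical conventions worth stating: distances are computed in double
precision and reported unrounded; ties between equal-cost alignments do
not affect the distance, and the edit-script traceback breaks them
deterministically (substitution over deletion over insertion) so scripts
are reproducible.  When both strings are empty the normalised distance is
defined as 0; the case cannot arise for real targets, which are never
empty.  The vowel table carries one extension beyond the published
values: /i/ appears in the worked scoring example but not in the vowel
table, so the shipped file assigns it Height 1, Forwardness 1 — the only
assignment consistent with the /a/–/i/ distance of 1.5 that the example
uses.  /u/ is retained even though it is absent from the transcription
set; inventories may subset the table harmlessly.  Vowel length is not
represented at all (length distinctions were not transcribable in the
source data), so long-vowel symbols are rejected rather than silently
mapped.

## The target language and affix coding

The miniature language crosses 4 container nouns (2 with front-harmony
initial vowels, 2 back) with 3 cases — inessive, adessive, superessive —
whose suffixes each have a front and a back alternation, giving 12
sentences.  The inessive pair is /-bεn/ ~ /-bɔn/.  The adessive and
superessive surface forms shipped in `language.yaml` are a
*reconstruction* following standard Hungarian two-way harmony pairs
(adessive *-nál/-nél*, superessive *-on/-en*) transcribed into the
study's phoneme set; the original figure's exact forms are not
recoverable from text, so the whole suffix inventory is config-driven and
the default is labelled a reconstruction.  Validation enforces 2 nouns
per harmony class, the three cases, and pairwise-distinct suffixes.

Each produced affix is coded on three nested binary measures:

* **case identification** — the production's minimum normalised edit
  distance over the 6 suffixes is attained *only* by suffixes of the
  target case;
* **case accuracy** — the production exactly reproduces (distance 0) one
  of the two alternations of the target case;
* **alternation accuracy** — it exactly reproduces the
  harmony-appropriate suffix.

"Unambiguously identified" is read strictly: a distance tie between a
target-case suffix and any other-case suffix codes 0.  An empty (silent)
production is distance 1 from every suffix and codes (0, 0, 0) without
special-casing.  Case identification compares *normalised* distances;
with unequal suffix lengths raw distances can order candidates
differently, so the normalised form is fixed for determinism.  The test
suite mirrors the original double-coding protocol by checking the
edit-distance coding against an independent hand-coding predicate (exact
string match for the accuracy measures, argmin-case membership computed
with a separate recursion oracle for identification) over an exhaustive
set of short productions.

Training sets of 8 of the 12 sentences are sampled uniformly from the
family of subsets satisfying the published constraints: exactly 2
sentences per noun, each case at least twice, each of the 6 alternations
at least once.  The package enumerates all $\binom{12}{8} = 495$
subsets (36 are valid for the shipped language) and samples from that
family, which makes uniformity exact and lets a test verify that the
sampler's support equals an independently enumerated family.

## Segmentation stimuli

The segmentation experiment uses 12 CV syllables (consonants p, t, b, d;
vowels a, i, u) and six trisyllabic words.  A training stream orders 300
tokens of each word at random and removes adjacent duplicate word tokens;
the removal pass ("delete any token equal to its surviving predecessor,
repeat to fixpoint") is implemented as run collapsing, whose idempotence
is tested.  Token counts are *not* restored after elimination, matching
the stated construction; a stream therefore has at most 1800 word tokens.
Syllable-to-syllable transitional probabilities are computed as
$TP(X \to Y) = n(XY) / n(X)$ with $n(X)$ counting $X$ in all but the
final position, so each row of the TP table sums exactly to 1.  A stream
is accepted only if every word-internal bigram type has a strictly higher
TP than every bigram type occurring only across word boundaries,
regenerating on failure with a bounded retry budget (for this lexicon the
expected minimum within-word TP is about 0.25 against cross-boundary TPs
of about 0.2, so a handful of retries suffices).

Foils are trisyllables over the same inventory whose two internal bigrams
are both *unattested* in the stream — the strongest reading of "internal
TP of 0" — and which are not lexical words; the requested six are drawn
uniformly from the full qualifying set, and a test re-verifies their TPs
with an independently coded bigram counter.  Test blocks pair each of the
6 words with each of the 6 foils exactly once (36 pairings), shuffled,
with independent within-pair order flips.  Speaker assignment is
counterbalanced: single-speaker participants are balanced over the 4
voices (with familiar/novel voice combinations rotated), multiple-speaker
participants over the 4 three-voice subsets with the held-out voice used
in the novel-voice block, and familiar-first/novel-first block order
counterbalanced within condition — hence the requirement that each
condition's participant count be a multiple of 8.  `export_pho()` writes
the stream as MBROLA `.pho` text with 60 ms consonants, 218 ms vowels
(278 ms per syllable) and a constant F0 of 100 Hz (male voices) or 200 Hz
(female); synthesis itself is out of scope.

## Synthetic learners

The simulators are intentionally *correctly specified* for the analysis
models — the point of the synthetic data is to validate the pipeline and
its inferences, not to model cognition, and no behavioural model is
available to imitate.  The segmentation learner produces Bernoulli
responses whose logit sums centred (±0.5) effects of condition, speaker
novelty, test-block position and the condition-by-novelty interaction,
plus a Normal participant intercept.  The default coefficients (0.343,
0.097, −0.439, −0.258, −0.093) are the values estimated from the original
48-participant sample.  The reported test-order effect is coded here as
the within-participant position of the test block (first vs second),
which directly expresses the fatigue/interference interpretation; the
simulator and the analysis use the same definition, so parameter recovery
is well defined.  No variance component was reported, so the participant
SD defaults to 0.5 logits — an arbitrary but conventional desk value,
exposed as a parameter.

The production learner forms a trial's expected stem accuracy on the
accuracy scale, `base + round_slope * (round − 3.5) − novelty_penalty *
novel` (defaults 0.65, 0.059 and 0.020; the slopes are the reported
per-round and novelty effects of the gaussian stem analysis, and the base
is a desk choice near the observed mid-experiment level), then perturbs
it by the participant effect on the logit scale.  The stem production is
the target corrupted toward that expected accuracy by
`corrupt_string()`: per-position substitution (toward feature-similar
same-category phonemes), deletion and insertion at rates looked up in a
precomputed Monte-Carlo calibration grid (length × rate → mean scored
accuracy, shipped as `corruption_calibration.csv`, 400 draws per cell,
fixed internal seed).  Expected accuracies below the grid's floor are
reached by mixing in fully deleted productions, which makes the
calibration exact in expectation on $[0, 1]$.  Affix productions are
drawn from a five-way outcome profile — exact alternation, wrong-harmony
alternation, a near-miss single-substitution error, an unrelated string,
or silence — whose exact-production probability is shifted on the logit
scale by round and novelty (defaults 0.30 and 1.2, the magnitudes of the
alternation-accuracy analysis).

What passing tests on synthetic data do and do not show: they demonstrate
that the scoring, coding, design and model-fitting code do what they
claim under data with the assumed structure, including recovering
generating coefficients at the published effect sizes.  They cannot
validate the behavioural claims themselves — real productions have
phonotactically structured errors, hesitations and length distinctions
that the corruption model does not emulate.

## Mixed-effects analyses

`fit_mixed_model()` fits lme4 models by maximum likelihood with every
fixed-effect predictor mean-centred (binary predictors become exactly
±0.5 under balance, $\{+1/3, -2/3\}$ at 2:1 imbalance) and a participant
random intercept.  A "maximal" random-slope structure over the
within-participant terms can be requested and falls back to the intercept
structure on non-convergence, with the fallback recorded; the default is
intercept-only, because at these sample sizes maximal logistic fits
frequently fail to converge and the inferential targets are the fixed
effects.  Every fit carries a likelihood-ratio test against the matched
null (random effects only, intercept retained): $\chi^2 = 2\,(\ell_1 -
\ell_0)$ with the parameter-count difference as degrees of freedom.
Gaussian p-values use the t statistic with `df_for_t` degrees of freedom,
taken verbatim as observations minus fixed parameters rather than a
Satterthwaite approximation; logistic p-values use the Wald z.
Coefficients convert to report form via `exp(beta)` (odds) and
`plogis(beta)` (accuracy), and rendered p-values below $10^{-3}$ print as
"<0.001" while exact values stay in the machine-readable summary.
Degenerate inputs — a constant response, complete separation — yield a
flagged summary rather than an error.

## Problem sizes and reproducibility

Every stochastic function takes an explicit `seed`; the pipeline driver
derives one seed per stage from a master seed, so a configuration
reproduces its outputs byte for byte.  The test suite validates the
dynamic program against a plain exhaustive-recursion oracle over all
string pairs up to length 2 on a 4-phoneme mini-inventory plus a seeded
sample of pairs up to length 5 (the full cross of length-5 strings is
combinatorially out of proportion to what the check needs); checks 24
independently seeded full-scale streams; verifies the training-set
sampler's support over 10,000 draws against the enumerated family; and
runs the parameter-recovery suite at the original scale (48 participants
× 72 trials, 100 replicates), requiring each generating coefficient to
fall inside its Wald 95% interval in at least 90% of replicates.

## Known limitations

The package neither processes audio nor models learning: speech synthesis
stops at `.pho` text, and the synthetic learners are generative mirrors
of the analysis models, not segmentation or morphology learners.  The
adessive/superessive suffix forms are a labelled reconstruction.  The
corruption calibration is built over uniformly random targets, so for a
specific stem the realised mean accuracy can deviate slightly from the
requested value.  One published companion number is deliberately not
reproduced: the worked example prints an accuracy of "0.328" alongside a
normalised distance of 0.682, but the defining formula $1 - 0.682 =
0.318$ contradicts it; the package follows the formula and treats the
printed 0.328 as an arithmetic slip, using only 0.682 as the anchored
value.
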