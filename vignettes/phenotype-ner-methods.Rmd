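---
title: "Phenotype NER: models, evaluation protocol, and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype NER: models, evaluation protocol, and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoNER)
```

## The task

phenoNER recognises mentions of phenotype concepts related to congestive
heart failure (CHF) in two styles of text: telegraphic, sectioned
discharge summaries from electronic health records, and full-sentence
scientific articles. Four entity classes are used throughout:

* **Cause** — any medical problem that contributes to the occurrence of
  CHF (e.g. *coronary artery disease*);
* **RiskFactor** — a condition increasing the chance of developing CHF
  (e.g. *hypertension*, *obesity*);
* **SignSymptom** — an observable manifestation of disease experienced
  by the patient (e.g. *chest pain*, *orthopnea*);
* **NonTraditionalRiskFactor** — kidney-function-related conditions
  that elevate the risk of CHF signs, symptoms and causes (e.g.
  *proteinuria*, *renal insufficiency*).

A mention is a labeled character span; offsets are 0-based and
end-exclusive everywhere in the package. Three families of extractors
share one document model (tokens with offsets, POS, chunk and optional
semantic tags, grouped into sentences): a token-pattern rule engine, a
gazetteer (dictionary) tagger, and three BIO sequence labelers.

## The rule engine

Rules are sequences of token specifications, each a bracketed constraint
list with an optional quantifier:

```
SignSymptom => [syn=NN|NNP]{1,3}, [sem=beverb]?, [syn=VBN|JJ, token!="normal"|"regular"|"stable"]
```

This reads: one to three (proper) nouns, an optional copula, then a past
participle or adjective that is not a normal-condition word. It accepts
*heart is enlarged*, *leg swollen*, or *chest pain is worse*, rejects
*chest is normal*, and — deliberately kept as a documented false
positive — accepts *abdomen is benign*, since syntax alone cannot
separate that from *abdomen is distended*.

Design choices the rule language needed beyond the pattern syntax
itself:

* each rule names its output class with a `LABEL =>` prefix (the pattern
  syntax after the arrow is unchanged);
* iterators expand greedily with backtracking and, at each start token,
  the longest successful expansion wins (leftmost-longest); the scan
  resumes after a reported match, so a single rule never overlaps
  itself;
* overlaps between different rules are resolved by earlier start, then
  longer span, then lower source line — deterministic and order-free;
* `sem=beverb` is satisfied by a small closed copula list
  (`is/are/was/were/be/been/being/'s`), so the worked example runs
  without any lexicon pass;
* token literals compare case-insensitively (EHR capitalisation is
  erratic); POS and semantic tags compare exactly;
* matches never cross sentence boundaries.

The bundled starter pack (`starter_rules()`) contains the documented
pattern plus a handful of gazetteer-style variants. It is a worked
example for tests and demos, not a reconstruction of any production
rule set.

## The dictionary baseline

`tag_with_lexicon()` scans each sentence greedily left-to-right for the
longest case-insensitive token-sequence match against a term → semantic
type lexicon, then filters by an allowed set of semantic types before
emitting mentions (disallowed entries still occupy their span, as a
concept recogniser would, so restricting the allowed types can only
remove output — never create new matches). Two known failure modes of
dictionary lookup are intentionally preserved, because they are
properties the evaluation should surface rather than bugs to fix:
misspelled surfaces (*aneamia* for *anaemia*) are missed, and a
multiword expression absent from the lexicon is matched only through
whatever sub-spans the lexicon contains (*worsened renal function*
splits into *worsened* + *renal function*).

## The shared feature layer

All sequence labelers use the same binary indicator features, extracted
per token over a symmetric context window (default ±2): lowercased
token identity, POS tag, chunk tag, compressed word shape
(`Hypertension` → `Xx`, `12mg` → `dx`), and affix features at the focus
position. Off-sentence positions contribute boundary markers so the
feature arity is constant.

The affix registry is compiled from the training gold standard: for
every token inside a gold mention, all prefixes and suffixes of lengths
2–5 are stored (lowercased). During extraction an affix feature fires
only if the token's affix is in the registry — a closed look-up list,
not an open-vocabulary affix space. This captures morphology like
*hyper-* (hypertension, hypercholesterolemia) and *-emia* (anemia,
lipidemia) without exploding the feature space.

Window width 2 is the package default; clinical NER systems rarely
benefit beyond that, and the window is configurable. Bag-of-words
features are windowed by default (whether context words enter the
feature set at all is a configuration switch, `use_bow` + `window`).

## The three labelers

Annotations are converted to per-token BIO tags (`B-`/`I-` per class
plus `O`, nine tags for four classes). Mention boundaries that fall
inside a token are snapped outward to token boundaries with a warning —
annotators mark character spans, labelers need token alignment, and
outward snapping never loses annotated characters. All three models
decode with Viterbi in log space; ties break toward the
lexicographically smallest tag, so decoding is deterministic.

**HMM** (`hmm_tagger`). Transitions and initial probabilities are
add-α smoothed counts (α = 0.1 by default). The emission integrates
multiple features by factorizing naive-Bayes style across feature
families, each family an add-α smoothed multinomial over its observed
values plus an explicit unseen-value outcome. Two consequences of the
generative reading are deliberate:

* only focus-position families (offset-0 and affix features) enter the
  emission — folding windowed context features in would emit the same
  observation several times, breaking the chain's independence
  structure (context is the transition model's job);
* a tag never observed in training is unreachable at decode. Without
  this, the smoothing floor makes an untrained state's uniform emission
  *more* attractive than a trained state's for unseen tokens.

**MEMM** (`memm_tagger`). The classical locally normalized formulation:
one L2-penalized multinomial logistic model per source state, trained
only on positions whose previous gold tag is that state (sentence-initial
positions belong to a synthetic START state). Decoding multiplies local
conditionals along the chain. The per-source fragmentation of training
data and the local normalization are what make MEMMs data-hungry and
subject to label bias. λ = 1.0 per sub-model by default.

**CRF** (`crf_tagger`). A linear-chain conditional random field with
per-state weights for every feature plus transition and initial-state
weights, trained by minimizing the L2-penalized negative log-likelihood
(λ = 0.1) with L-BFGS; the forward–backward gradient is computed in
compiled code. The objective is convex, so the fit is
optimizer-independent up to the gradient tolerance.

Structurally illegal BIO transitions (`O → I-x`, `B-x → I-y`) are
hard-masked at decode time for the HMM and MEMM, guaranteeing valid
output from the generative/local models; the CRF is left soft and
relies on learned transition weights, with `from_bio()` repairing any
orphan `I-` continuation (treated as `B-`). Unknown features at decode
time simply drop out for the discriminative models; the HMM backs off
to the smoothed unseen-value mass.

Numerical settings: MEMM convergence is checked at projected-gradient
tolerance 1e-4; the CRF uses 1e-2 because with weak regularization the
objective's tail is flat while the decoded argmax is long since stable;
both error if the iteration cap (200) is reached while the gradient is
still large. Training is deterministic given input order, so repeated
fits are bit-for-bit reproducible.

## Evaluation protocol

`span_prf()` scores predictions in two modes. **Exact**: a true
positive must match a gold mention's document, boundaries and label.
**Relaxed**: one shared character with a same-label gold mention
suffices; the recall side counts gold mentions with at least one
overlapping prediction, and the precision side counts predictions with
at least one overlapping gold mention, so many-to-one overlaps behave
monotonically (adding a correct prediction never lowers recall; adding
a spurious one never raises precision). Relaxed matching here requires
label agreement — overlap alone would make per-class score rows
meaningless. F1 is always the harmonic mean of its own row's precision
and recall, and empty denominators score 0 with the support column
making the degenerate condition visible.

Three aggregates are reported side by side — micro (pooled counts),
macro (unweighted class mean), and support-weighted — because
agreement and system scores are often quoted as a single "average"
whose definition varies; reporting all three avoids committing to one
reading. Note two deliberate properties: the macro row averages over
*all* configured classes, including ones with zero support; and the
weighted row is not symmetric under swapping gold and prediction (its
weights come from the gold side), while per-class, micro and macro F1
are exactly swap-symmetric.

Inter-annotator agreement (`iaa()`) treats one annotation set as gold
and computes the same F-scores — the appropriate protocol when the
total number of annotatable items is unknown, which rules out
chance-corrected coefficients. Experiment splitting is always at
document level: random 80/20 holdout, k-fold with fold sizes differing
by at most one, and a cross-text-type regime that trains on one style
and tests on the other in both directions.

## The synthetic benchmark

The real corpora this class of system is trained on are
access-restricted, so the package ships a generator
(`generate_corpus()`) that emulates the structural properties the
methods actually depend on, with exact gold offsets and
generator-assigned POS/chunk tags (no external tagger anywhere in the
test path):

* two text styles — sectioned telegraphic discharge text
  (`HISTORY OF PRESENT ILLNESS:` headers, verb-initial fragments) and
  full-sentence article text;
* style-skewed class mixes: sign/symptom-heavy for discharge summaries
  (0.45/0.20/0.20/0.15 over SignSymptom/Cause/RiskFactor/
  NonTraditionalRiskFactor), cause- and kidney-marker-heavy for
  articles (0.35 Cause, 0.35 NonTraditionalRiskFactor);
* ~10% single-character misspellings on non-mention word tokens for the
  discharge style (EHR text is reported to carry roughly this load);
  article text defaults to 0. Mentions are never misspelled by default
  (a separate switch), so extraction floors are stable;
* mention counts per document are truncated-Poisson (mean 8 by
  default); an adjectival modifier precedes a planted mention with
  probability 0.25 and stays *outside* the gold span;
* two surface forms (*hypertension*, *diabetes mellitus*) appear under
  both Cause and RiskFactor depending on the sentence template —
  encoding the fact that class membership depends on context, not on
  the surface form alone.

The simulated second annotator reproduces the dominant human
disagreement pattern — whether modifiers belong inside a span — by
extending a mention over its preceding modifier, shrinking it by its
leading modifier token, or occasionally dropping it (per-mention
probability 0.2 by default, 45/45/10 among available actions).

What passing tests on this corpus do and do not show: they verify the
machinery — BIO round trips, scorer correctness against brute-force
oracles, Viterbi optimality against exhaustive enumeration, parameter
recovery on separable-with-ambiguity data — not clinical performance.
The generator has a closed vocabulary, clean sentence structure, gold
tags, and no abbreviation/negation/section-scope phenomena; absolute
F-scores on it are ceilings, not estimates of real-corpus behavior.

One empirical property deserves honesty: in this clean closed-vocabulary
regime the locally normalized MEMM and the globally normalized CRF make
essentially the same predictions, while the context-blind HMM emission
pays exactly for the context-ambiguous vocabulary. The label-bias
pathology that separates MEMMs from CRFs on real clinical text needs
either data scarcity or class evidence arriving outside the feature
window; the test suite demonstrates it directly on a dedicated
branch-structured corpus (mentions sharing their first token, the
deciding token invisible to a window-0 model at commit time, branch
priors unbalanced) where the MEMM follows the majority branch and the
CRF and HMM recover.

Problem sizes used by the test suite and the acceptance script — 200
training and 50 held-out discharge documents for labeler benchmarks,
500 documents for round-trip sweeps, 1000 random configurations for
scorer-oracle equivalence, sentences up to length 6 for exhaustive
Viterbi enumeration — were chosen as the smallest scales at which the
checked properties are non-trivial and stable across seeds.

## Worked example

```{r example, eval = FALSE}
library(phenoNER)

train <- generate_corpus(generator_config(200, "discharge", seed = 1001))
test  <- generate_corpus(generator_config(50,  "discharge", seed = 1002))

fit <- crf_tagger(train$documents, train$annotations)
pred <- predict(fit, test$documents)
span_prf(test$annotations, pred, mode = "both")

ann2 <- simulate_second_annotator(test$annotations, test$documents,
                                  noise = 0.2, seed = 7)
iaa(test$annotations, ann2, mode = "both")
```

## Known limitations

* No discontinuous or overlapping mentions; no concept normalization
  (mapping spans to terminology identifiers) — out of scope.
* The tokenizer and sentence splitter are deterministic and
  dependency-free, tuned to the telegraphic EHR style (every newline
  ends a sentence); pre-tagged CoNLL input bypasses them entirely and
  is the recommended path for real text.
* The starter rule pack covers only the documented pattern family.
* Generator class mixes emulate the reported style skew qualitatively;
  exact real-corpus proportions are not published as numbers and no
  claim is made to reproduce them.
* POS/chunk tags must come from the input (or the generator); the
  package bundles no tagger.
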