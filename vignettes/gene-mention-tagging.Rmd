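---
title: "Bidirectional CRF tagging of gene and protein mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional CRF tagging of gene and protein mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitagger)
```

## The problem

Gene and protein names in the biomedical literature have no enforced
nomenclature: the same entity appears as `p53`, `TNF-alpha`, `HNF-3`,
`brown adipose tissue (BAT)` or `factor II`, often several variants in one
abstract.  Mention-level named-entity recognition — finding the exact span
of every gene/protein name in a sentence — is the prerequisite for any
downstream relation or pathway extraction.  `bitagger` implements a hybrid
tagger for this task: a feature-rich second-order conditional random field
(CRF) run in both reading directions, the two directional models merged
into a single weight vector refined with the margin-infused relaxed
algorithm (MIRA), followed by three families of rule-based repairs.

The package reads and writes the BioCreative II gene-mention (BC2GM) file
conventions: a sentence file of `<id> <text>` lines and an annotation file
of `id|start end|text` lines, where `start`/`end` are 0-based inclusive
indices that count only non-whitespace characters.  Because real corpora
of this kind are distributed separately, the package also ships a
deterministic synthetic corpus generator so that the entire pipeline is
exercised end to end by the test suite alone.

## Sequence model

Sentences are tokenized (whitespace first, then isolation of brackets,
commas, slashes, hyphens and trailing periods; hyphenated names such as
`HNF-3` therefore span three tokens, while `p53` and digit-bearing slash
compounds like `P42/44` stay whole) and labeled per token with the BIO
scheme: `B` begins a mention, `I` continues it, `O` is outside.

The tagger is a linear-chain CRF,

$$P(A \mid B, \lambda) = \frac{1}{Z(B)}
  \exp\Big(\sum_k \lambda_k F_k(A, B)\Big),$$

where the global features $F_k$ sum per-position indicator functions and
$Z(B)$ normalizes over all label sequences.  The chain is second order:
transition features condition on the two previous labels, realized as
label-trigram weights (with a begin-of-sentence context) alongside
(feature, label) state weights.  Training maximizes the L2-regularized
conditional log-likelihood by batch L-BFGS; the gradient is computed by a
forward–backward recursion over the nine (previous, current) label pair
states, implemented in C++ for speed.  Decoding is Viterbi over the same
dynamics with deterministic tie-breaking in the fixed label order
B < I < O.  Single-token sentences use state weights only — there is no
transition context to condition on.

Correctness of the dynamic programs is not taken on faith: the test suite
compares Viterbi output and $\log Z$ against exhaustive enumeration over
all $3^n$ label sequences for sentences up to length 5, and the analytic
gradient against central finite differences.

## Token features

Each token receives sparse binary string features:

* The 32 basic orthographic/morphologic/affix types (`INITCAPS`,
  `ALLCAPS`, `ENDCAPS`, `MIXEDCAPS`, `HASDIGIT`, `GREEK`, `ROMAN`,
  `HAS_SLASH`, value-bearing 2/3/4-character prefixes and suffixes, and so
  on).  The published registry gives exemplar tokens, not formal
  definitions, so each predicate is fixed here by its exemplar and
  documented in `basic_features()`: e.g. `TWOCAPS`/`THREECAPS`/`MORECAPS`
  count uppercase letters exactly 2 / exactly 3 / 4 or more;
  `MIXEDCAPS` requires case interleaving in both directions (`EcoRI`).
  Predicates are pure functions of the surface and deliberately not
  mutually exclusive (`p53` fires `ALPHANUMERIC`, `HASDIGIT`, `ENDDIGIT`
  and `NUMBERS_LETTERS` together).
* Character N-grams from a sliding window of width 4 (`fibrin` yields
  `fibr`, `ibri`, `brin`); shorter tokens emit their whole surface.  The
  phrase "window from the beginning to four characters" also admits a
  prefix reading, so `char_ngrams(mode = "prefixes")` exposes prefixes of
  length 1–4 as a config switch; the all-windows reading is the default.
  Single-character and pure-punctuation tokens emit no N-grams — they
  carry no generalizable substring signal and inflate the vocabulary.
* Offset conjunctions: the basic features of the two preceding and two
  following tokens, prefixed `@-2:`, `@-1:`, `@+1:`, `@+2:`; positions
  beyond the sentence contribute boundary markers.
* A corpus-frequency feature: `CORPUS_FREQ` fires on noun tokens whose
  surface was annotated as a gene mention between 1 and
  $\theta_{freq} = 10$ times in the training corpus.  The band keeps
  *rare* names: a name seen a handful of times should be tagged
  consistently everywhere it recurs, which raw context features fail to
  guarantee.  The counting unit is the full mention surface,
  case-sensitive.  The complementary band (counts above the threshold) is
  available via `freq_invert` for experimentation.

### PCA feature selection

With N-grams and conjunctions the feature space grows into the tens of
thousands, many columns near-duplicated.  `pca_select()` ranks the
original sparse indicators by their maximum absolute loading over the
first $L$ principal components of the mean-centered sentence-by-feature
occurrence matrix ($T = XW$, eigenvectors of the feature covariance) and
keeps the top $K$.  Selection operates on the *original* features rather
than projecting tokens into dense component space, because the CRF needs
sparse indicators; the projection is only the ranking device.  Rows are
sentences rather than tokens — occurrence profiles across sentences are
what distinguishes informative from redundant indicators.  Selection is
off by default (`pca_keep = NULL`): the right $K$ is corpus-dependent,
and on the small synthetic corpora every feature family contributes.
The implementation (SVD via `prcomp`) is tested against an independent
dense eigendecomposition of the covariance matrix to $10^{-8}$.

## Bidirectional training and model combination

A backward model is trained on the same corpus read right to left:
token order reversed, conjunction prefixes mirrored (`@-k` ↔ `@+k`), and
BIO labels re-encoded so each mention's first token *in reversed reading
order* carries `B` — reversing labels verbatim would produce `I` before
`B` and violate the BIO grammar.  Forward and backward taggers make
partially independent errors; three combination modes are provided:

* **union** of the two mention sets (recall up, precision down),
* **intersection** (precision up, recall down),
* **MIRA**: the two weight vectors are summed into one forward-oriented
  vector — backward state weights carry over with mirrored prefixes,
  transition trigrams reverse $(a,b,c) \mapsto (c,b,a)$, and
  boundary-context weights remain boundary weights (sentence-initial
  context in backward reading is sentence-final in forward reading, for
  which this parameterization has no slot; retaining them as boundary
  weights keeps the mapping an involution) — and then refined with
  single-best MIRA sweeps over the training corpus.  For each sentence,
  decode $\hat y$; if $\hat y \ne y$, apply the minimal update
  $\omega \leftarrow \omega + \tau\,(\Phi(x,y) - \Phi(x,\hat y))$ with
  $$\tau = \max\!\Big(0,
    \frac{L(y,\hat y) - (score(x,y) - score(x,\hat y))}
         {\lVert \Phi(x,y) - \Phi(x,\hat y)\rVert^2}\Big),$$
  which is exactly the smallest change satisfying the margin constraint
  $score(x,y) - score(x,\hat y) \ge L(y,\hat y)$ for that pair.  The loss
  $L$ is the Hamming label loss (the published description says only
  "number of errors"; per-label counting is the minimal reading, as
  opposed to mention-level errors).  Instances are visited in corpus
  order without shuffling and the final iterate is kept, so combination
  is deterministic; epochs default to 5.  The degenerate case
  $\Phi(x,y) = \Phi(x,\hat y)$ with $y \ne \hat y$ carries no update
  direction and is skipped with a warning.

## Rule-based post-processing

Three rule families run in a fixed order (contextual clues, then
parenthesis repair, then abbreviation handling); each is idempotent, and
only the parenthesis repair may shrink a mention.

1. **Contextual clues.**  Around connective words (`and`, `or`) first and
   interaction keywords (`binds`, `activates`, ...) second, the nearest
   non-punctuation neighbor on each side is checked against the
   post-keyword list (pkl) — gene surfaces annotated at least 3 times in
   training.  A neighbor labeled `O` whose surface is in the pkl becomes
   a single-token `B` mention.  Both neighbors are checked
   unconditionally (the alternative reading — only neighbors of
   already-tagged genes — is narrower; the keyword-neighbor reading
   covers it).  Single-token tagging is deliberate: the rule's canonical
   case tags exactly one coordinated name (`C1q and C4`).  The full
   ~400-word interaction lexicon used with the original system is not
   published; the package ships a seed list
   (`inst/extdata/relation_keywords.txt`) and accepts a replacement file
   via `read_keyword_lexicon()`.
2. **Parenthesis repair.**  A mention must not contain one member of a
   bracket pair without the other.  Matched pairs inside the same mention
   stay (`( BAT )` fully tagged is legitimate); a bracket whose partner
   lies outside the mention — or in a different mention, or nowhere — is
   ejected: relabeled `O`, with the next token re-headed to `B` if the
   bracket led the mention.  The repair iterates to a fixed point so no
   mention ever retains an unbalanced bracket.
3. **Two-tier abbreviation handling.**  First, `Long Form ( SF )`
   constructs are detected with the classical right-to-left character
   pairing test: every short-form character must appear in order in the
   preceding text, the first one at the start of a word; the long-form
   window is capped at $\min(|SF|+5,\ 2|SF|)$ words and never crosses
   another bracket.  Short-form candidates are parenthesized spans of at
   most 10 non-space characters containing a letter (constants exposed in
   the config).  When the model tagged only one member of a pair, the
   label is propagated to the other (`B I ... I` over the missing span);
   the rule never creates a pair from nothing and never removes one.
   Second, ambiguous short forms (`ACE`) are resolved against a
   user-supplied sense inventory by bag-of-words context overlap, with an
   in-sentence long form winning outright and ties going to inventory
   order.  Sense selection is informational — it does not move labels —
   and the inventory format is plain TSV; concept-identifier resources
   (UMLS/MeSH) are licensed and out of scope, which is why the
   disambiguator is pluggable rather than built in.

## Evaluation

`evaluate_mentions()` scores exact-span matches on non-space offsets:
TP/FP/FN with $P = TP/(TP+FP)$, $R = TP/(TP+FN)$,
$F = 2PR/(P+R)$, zero-guarded.  No partial credit is given; the BC2GM
convention of acceptable alternate spans is supported through an optional
ALTGENE-style file, where a prediction matching an alternate of an
unmatched gold mention counts as its true positive (each side credited at
most once).  Offsets are taken as 0-based inclusive at both ends, the
convention of the corpus distribution (the prose sources never state
inclusivity).

## The synthetic corpus

`generate_corpus()` emits BC2GM-format corpora that are a pure function
of their configuration.  Gene surfaces are drawn from a generated lexicon
covering the orthographic shapes the registry keys on (all-caps symbols,
`p53`-style alphanumerics, mixed-case enzyme names, Greek-suffixed
compounds, slash/plus/quote variants, multi-token roman-numeral factors);
filler vocabulary is lowercase common words disjoint from the gene
shapes.  Configurable fractions of sentences embed abbreviation
constructs (long forms built from a dedicated word pool with short forms
from their initials), parenthesized synonym mentions, relation-keyword
and connective contexts.  Defaults: 20% abbreviation sentences, 15%
parenthesized, 25% relation-keyword, 20% connective, and a held-out
companion corpus draws 20% of its gene surfaces fresh, so generalization
must come from orthography rather than memorization.

The toy language is learnable by construction — labels are nearly
determined by surface shape plus local context — so a trained tagger
recovering held-out mentions at high F demonstrates that the pipeline's
plumbing (offsets, features, training, decoding, rules, scoring) is
correct, *not* that comparable accuracy would be reached on real
literature, whose sentence structure, vocabulary overlap between gene
and common words, and annotation inconsistencies are far harsher.  On
these near-separable corpora the directional models already decode the
training data almost perfectly, so MIRA refinement has little room to
help and the combination modes score within a few points of each other;
the mode ranking reported on real corpora should not be expected to
reproduce here.  The test suite trains on 300 generated sentences and
evaluates 100 held-out ones (sizes chosen to exercise every stage while
keeping the default run fast) and asserts F ≥ 0.9 for the MIRA-combined
configuration, with the worked single-sentence examples pinned exactly.

## Numerical and design choices

* L2 regularization with strength 1.0 and L-BFGS are defaults, not
  published facts: the original description names neither regularizer nor
  optimizer.  Both are config-exposed; the training contract is the
  objective, not the optimizer.
* Viterbi ties break toward B < I < O at every backtrack step;
  enumeration oracles in the tests share this order.
* Orphan `I` labels (after `O` or at sentence start), which rule edits
  could otherwise leave behind, are healed to `B` during decoding to
  mentions, so every label sequence is decodable.
* Model dumps are JSON with weights printed via `%.17g`, which
  round-trips IEEE-754 doubles bit-exactly.
* Tokens attach digits to letters; slash compounds stay whole only when
  both halves are alphanumeric and a digit is present (`P42/44`), an
  interpretive choice implied by the `HAS_SLASH` feature existing at all.
* Empty sentences decode to empty label sequences; empty corpora yield
  empty tables rather than errors, except where training data is
  required (`train_crf` on zero sequences is an error).

## Limitations

* The built-in POS/lemma/chunk backend is a deliberately small
  suffix-rule tagger sufficient for the noun gate of the corpus-frequency
  feature; for real corpora, plug a full NLP toolchain into the backend
  contract (a function from surfaces to equal-length `pos`/`lemma`/
  `chunk` vectors).
* Nested and discontinuous mentions are unsupported, as in the source
  annotation scheme.
* The sense inventory for abbreviation disambiguation must be supplied by
  the user; no concept-identifier resources ship with the package.
* Benchmark-scale corpora (tens of thousands of sentences) train in
  minutes-to-hours, not seconds; the package is single-threaded.
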