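# bitagger

Trainable named-entity recognition for gene and protein mentions in
biomedical text, for text-mining practitioners who need a
self-contained, inspectable tagger rather than a black box.  Gene names
have no enforced nomenclature (`p53`, `TNF-alpha`, `HNF-3`,
`brown adipose tissue (BAT)`), so the tagger combines three layers:

1. **Feature-rich second-order CRFs, run in both directions.**  Tokens
   carry 32 orthographic/morphologic/affix indicator types, character
   4-grams, offset conjunctions of the two neighbors on each side, and a
   corpus-frequency feature (`CORPUS_FREQ` on noun tokens annotated
   1–θ_freq times in training, θ_freq = 10).  The label sequence model is
   a linear-chain CRF

   P(A | B, λ) = Z(B)⁻¹ exp( Σₖ λₖ Fₖ(A, B) )

   with second-order (label-trigram) transitions, trained by
   L2-regularized maximum conditional likelihood, decoded by Viterbi.
   One model reads left to right, a second reads right to left with BIO
   labels re-encoded.
2. **Model combination.**  Mention-set union or intersection, or —
   the default — a single weight vector ω initialized as the sum of the
   forward and orientation-mapped backward weights and refined with
   single-best MIRA: on each misdecoded training sentence the minimal
   update ω ← ω + τ·(Φ(x,y) − Φ(x,ŷ)),
   τ = max(0, [L(y,ŷ) − (score(x,y) − score(x,ŷ))] / ‖ΔΦ‖²),
   enforcing score(x,y) − score(x,ŷ) ≥ Hamming loss.
3. **Rule-based post-processing.**  Contextual clues (pkl lookups beside
   connective and interaction keywords), parenthesis-mismatch repair, and
   two-tier abbreviation handling (long-form/short-form pairing plus a
   pluggable sense disambiguator).

I/O uses the BioCreative II gene-mention conventions: sentence files of
`<id> <text>` lines, annotation files of `id|start end|text` lines with
0-based inclusive offsets over non-whitespace characters.  Exact-span
precision/recall/F evaluation (with optional alternate-span credit) is
built in, as is a deterministic synthetic corpus generator so everything
above is testable without external downloads.

## Worked example

```r
library(bitagger)

# generate a toy corpus and train
cfg <- toy_corpus_config(seed = 1, n_sentences = 300)
corpora <- generate_train_test(cfg, n_test = 100)
tagger <- train_tagger(corpora$train$sentences, corpora$train$mentions,
                       pipeline_config(mode = "mira"), verbose = TRUE)
#> tokenized 300 sentences [0.4s]
#> extracted features for 300 sequences
#> forward model: nll 2681.71 -> 41.38
#> backward model: nll 2681.71 -> 38.76
#> MIRA updates per epoch: 18 0 0 0 0
#> training done [6.0s]

# tag the held-out sentences and score them
pred <- tag_corpus(tagger, corpora$test$sentences)
evaluate_mentions(corpora$test$mentions, pred)
#> TP 167  FP 10  FN 6
#> precision 0.9435  recall 0.9653  F-score 0.9543
```

The negative log-likelihood lines show both directional CRFs fitting the
300-sentence corpus (2681.7 is the uniform-model starting objective);
MIRA needs 18 corrective updates in its first pass and none afterwards.
On the 100 held-out sentences — 20% of whose gene surfaces were never
seen in training — the combined tagger recovers mentions at F = 0.954
by exact span match.

The rule layer is usable piecemeal; for instance abbreviation pairing:

```r
ts <- annotate(tokenize("Brown adipose tissue ( BAT ) and UCP1 were absent", "S1"))
extract_abbreviation_pairs(ts)
#>   sentence_id sf_start sf_end lf_start lf_end short_form            long_form
#> 1          S1        5      5        1      3        BAT Brown adipose tissue
```

`propagate_abbreviation_labels()` then copies a mention label from the
tagged member of such a pair to the untagged one, and
`fix_parentheses()` repairs labelings that capture one bracket of a pair
without its partner.

## Vignette

`vignettes/gene-mention-tagging.Rmd` documents the model, every tunable
parameter with its default and rationale, the feature predicate
definitions, what the synthetic corpus does and does not demonstrate,
and the package's numerical choices and limitations.
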