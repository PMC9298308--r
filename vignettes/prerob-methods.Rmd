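---
title: "Methods: models, parameters and design choices in prerob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in prerob}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prerob)
```

## The problem

Risk-of-bias assessment asks, for each full-text publication describing an
animal experiment, whether it *reports* a set of methodological safeguards:
random allocation to group, blinded assessment of outcome, a
conflict-of-interest statement, compliance with animal welfare regulations,
and accounting for excluded animals. Annotation is done at the document
level (1 = reported, 0 = not reported), item by item; `prerob` treats each
item as an independent binary text-classification problem and trains one
model per item. Reporting prevalence differs sharply between items (from
roughly 12% for animal exclusions to 78% for conflict-of-interest
statements), which is why class-imbalance handling is a first-class
training option rather than an afterthought.

## Preprocessing

`clean_text()` applies, in order: retention from the first heading line
matching optional numbering plus "introduction" (if such a heading exists —
when it does not, nothing is dropped, since conflict-of-interest statements
often precede the introduction and deleting an unrecognised front matter
would silently destroy them); truncation at the last "references" /
"bibliography" heading; removal of URLs, bracketed numeric citations,
parenthesised author–year citations, digits and non-ASCII characters;
lower-casing and whitespace collapsing. The exact regular expressions are
this package's own declared approximations — no published rule set exists
at that level of detail — and the whole map is idempotent, which the test
suite checks on 1,000 generated articles.

Tokenization is deterministic and rule-based (sentence breaks after
`.!?` + space; punctuation split into separate tokens). It is deliberately
pluggable: any tokenizer that maps a string to a list of token vectors can
feed `clean_document()` directly.

`split_corpus()` allocates exactly `floor(0.8 n)` documents to training and
`floor(0.1 n)` to validation, with the remainder going to the test set.
This floor-train/floor-valid/rest-to-test rule is what reproduces the
published split sizes of the two annotated corpora (7840 → 6272/784/784 and
7089 → 5671/708/710); a largest-remainder scheme that distributes one unit
each to validation and test would instead give 709/709 for the second
corpus. Splitting is uniform random and unstratified.

## Representations

*TF-IDF*: `weight(t, d) = tf(t, d) · ln(N / df(t))`, computed with document
frequencies from the training split only. We use the bare natural-log
inverse with no +1 smoothing — a term present in every training document is
exactly uninformative and gets weight 0 — and no normalisation by default
(an `l2` flag is provided, since the best-performing variant is an
empirical matter). Vocabulary admission requires document frequency ≥ 2,
which bounds memory without measurably changing the feature space.

*Word embeddings*: embeddings are an input (word2vec text format via
`read_word2vec()`), never trained here; `random_embedding_table()` supplies
seeded Gaussian rows of standard deviation 1/√d — approximately unit norm,
the scale at which pretrained vectors typically arrive — for fully
self-contained experiments. Out-of-vocabulary tokens share a single
zero-initialised unknown vector; the padding row is identically zero, which
makes "padded rows have zero norm" a checkable invariant of
`embed_document()`. The default document cap `s_max = 5000` matches the
average full-text length of the corpora this tool targets.

*Paragraph vectors*: `train_doc_vectors()` concatenates a
distributed-memory variant (document vector plus mean context-window vector
predicts the centre word) and a distributed bag-of-words variant (document
vector alone predicts each word), both trained by negative sampling against
*frozen*, seeded random word projections. Freezing the word side makes the
per-document objective convex, so document vectors are deterministic,
identical documents converge to identical vectors, and the same routine
(`infer_doc_vector()`) embeds unseen documents. This trades representational
richness for reproducibility — a deliberate choice for a component whose
role here is a baseline feature, not the contribution.

## Classic baselines

`fit_baseline()` delegates to the standard implementations: a linear-kernel
SVM minimising hinge loss, logistic regression minimising log loss, and a
random forest of (by default) 500 trees on bootstrap sub-samples. Default
`C = 1`; all knobs are exposed through `hyperparams` rather than fixed,
because no definitive published grid exists for this task. SVM
probabilities are the logistic map of the decision value: sign-preserving
(so hard labels equal margin signs) and stable on the small fixtures where
cross-validated Platt scaling is unreliable. The decision threshold is 0.5
everywhere, with ties classed positive.

## Neural classifiers

All three are implemented natively with manual backpropagation; every
gradient path is verified against central finite differences in the test
suite (relative error < 1e-4).

**CNN.** Filters f ∈ ℝ^{h×d} slide over the document matrix; position *i*
contributes Σ(x_{i:i+h−1} ⊙ f). ReLU, max-over-time pooling per filter,
dropout on the pooled vector (training only — matching the
pool → dropout → linear ordering), then a linear map to two logits whose
softmax gives the reporting probability. Defaults: filter sizes 3/4/5,
32 filters each, dropout 0.5.

**RNN with attention.** A bidirectional GRU (or LSTM) produces hidden
states h_t; additive attention scores u_t = vᵀ tanh(W h_t + b) are
softmax-normalised over the real tokens only — padding is masked out of
the normalisation, because unmasked padding would leak probability mass —
and the document vector is Σ α_t h_t. The shared context *vector* v is our
resolution of an ambiguity: a per-position context matrix is also
expressible (scores gain a learned per-position term) but the shared-vector
form is the standard formulation and the default.

**HAN.** Word-level BiGRU plus word attention builds one vector per
sentence; a sentence-level encoder plus sentence attention builds the
document vector. The sentence-level encoder defaults to a
position-independent projection tanh(W s + b) rather than a second
recurrent layer: evidence ranking should depend on what a sentence says,
not where it sits, and with the projection encoder the sentence-attention
scores are exactly permutation-equivariant (a property the tests assert).
A `sentence_encoder = "gru"` option restores the fully recurrent variant
for users who want positional context at the sentence level.

**Training.** Per-document Adam (defaults lr 1e-3, gradient accumulation
32; the synthetic-recovery experiments use lr 5e-3 and batch 8, which suit
their smaller scale), softmax cross-entropy, and a checkpoint kept at the
epoch with the highest validation F1 — F1 is the model-selection metric
throughout, with ties broken by recall then key so selection is
deterministic. Class imbalance options: none, inverse-prevalence loss
weighting (balanced classes get weights (1, 1)), or per-epoch majority
undersampling to the minority count. A validation split with no positives
triggers a warning and loss-based selection instead. Embeddings stay
frozen during training; the classifier, not the representation, is what is
being fit.

## Long-document strategies

Contextual encoders accept ≤ 512 tokens; the target documents average
~5000. Two strategies are provided, both behind an adapter interface
(`encode(ids)` → list of layer matrices; `embed(tokens)` → vector) so that
any encoder — or a deterministic stub — can be injected. The bundled stubs
(`stub_chunk_encoder()`, `bow_sentence_encoder()`) are synthetic: seeded
random projections and hashed bag-of-words counts carrying no pretrained
knowledge. They exist so the full pipeline runs and is testable offline.

**Document chunk pooling.** `chunk_document()` splits s tokens into
m = ⌈s/510⌉ chunks of 510 payload tokens plus the two specials. The
ceiling is deliberate: a floor would silently discard up to 509 tokens of
the last chunk. Hidden states are averaged over a configurable encoder-layer
subset (default: the last four — the usual feature-extraction choice;
no canonical subset exists), collapsed across tokens by one of five options
(max, average, both concatenated, first token, all tokens), and passed to a
linear, convolutional or LSTM head over the chunk sequence. The fixed
composition is layer-average → token-pool → chunk-head; the linear head
applies one extra pooling step across chunks, and the all-tokens option is
rejected for it because it has no fixed dimension. The encoder is never
updated.

**Sentence extraction.** Each sentence is embedded and scored by cosine
similarity against the embedded one-sentence item description; the top
k = 5 (configurable — no canonical k exists) form the passage. Extraction
is unsupervised and entirely independent of classifier training. Zero-norm
vectors score 0; ties break toward the earlier sentence; ranked sentences
are re-sorted into document order before classification to preserve
discourse flow (a flag keeps rank order). The passage classifier
(`se_model()`) is a trainable projection ("compact encoder") plus
linear/conv/LSTM head, and unlike chunk pooling its encoder weights *are*
updated during training.

## Evaluation

Confusion counts follow the standard reported/not-reported definitions;
recall, precision, F1 and specificity use the 0/0 ≡ 0 convention so
degenerate synthetic cases stay finite. `mcnemar_test()` builds the paired
2×2 on *correctness* (b = A correct & B wrong, c = the reverse) — the
standard paired-classifier construction — and defaults to the exact
doubled-binomial-tail p, equal to full enumeration of the 2^(b+c)
discordance outcomes under the symmetric null; test-set discordant counts
are routinely small enough that the chi-square approximation (provided as
`method = "chisq"`, with continuity correction) is not trustworthy.
Percentages are reported to one decimal place.

## The synthetic corpus: what it does and does not show

`generate_corpus()` plants, in exactly `round(n · prevalence)` documents
per item, one evidence sentence drawn from a per-item phrase bank (with a
configurable paraphrase rate mixing in harder variants such as "unaware of
the treatment" for blinding), positions it uniformly at random, and fills
the rest with seeded template sentences from a neutral laboratory
vocabulary; item-negative documents can carry near-miss distractors
("animals were randomly selected for testing") at a configurable rate, and
a junk-token rate emulates residual conversion noise. Default prevalences
are 27.5 / 30.6 / 78.0 / 31.5 / 12.2 per cent and default document shape is
180 sentences of 28 tokens — the statistics of the annotated corpora this
package targets.

What passing the recovery experiments shows: the models can learn planted
lexical evidence at realistic prevalences and localise it with attention;
the pipeline is wired correctly end to end. What it does not show: real
reporting language is far more varied than a phrase bank, real documents
carry correlated section structure the generator lacks, and a
bag-of-words stub cannot represent paraphrase similarity (a planted
paraphrase like "group assignment was determined by random allocation" has
zero lexical overlap with the item description — exactly the failure mode
that motivates contextual sentence encoders). Synthetic performance
therefore bounds plumbing correctness, not real-world accuracy.

## Problem sizes and numerical choices

The bundled experiments are scaled to desk hardware as the package's own
choice of problem size: CNN recovery uses 500 documents of ~20 sentences ×
12 tokens with 24-dimensional embeddings (held-out F1 ≥ 0.9 in the
acceptance suite); HAN evidence ranking uses 300 documents of ~15
sentences; the RNN attention experiment uses 150 documents. Training full
180-sentence documents works identically but proportionally slower.

Numerical details: softmax is computed with max-subtraction; attention
rows that are fully masked yield all-zero weights rather than NaN;
probabilities are clamped at 1e-12 inside log-losses; Adam uses the
standard bias correction with β = (0.9, 0.999), ε = 1e-8. All randomness —
generation, splitting, initialisation, shuffling, dropout — flows through
explicit integer seeds, and the generator scrambles its seed internally so
that reusing one seed for generation and splitting cannot correlate the
label draw with the split draw.

## Known limitations

One model per item (no multi-task sharing); no "unclear" category —
reporting is binary; no PDF-to-text conversion or section-structure
recovery (text is assumed already extracted, and structure loss is a known
noise source); stub encoders bound what the long-document strategies can
demonstrate without injected pretrained encoders; the paragraph-vector
trainer favours determinism over expressiveness; and the synthetic
generator's template text makes vocabulary-level tasks easier than real
literature, which is why its results are read as correctness checks rather
than performance claims.
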