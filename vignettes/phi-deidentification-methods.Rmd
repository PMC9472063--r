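---
title: "Deidentifying clinical text with a compact encoder, a CRF head, and hybrid data augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deidentifying clinical text with a compact encoder, a CRF head, and hybrid data augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phideid)
```

## The problem

Electronic health records carry protected health information (PHI) —
personal names, dates, locations, organization names — that must be located
and replaced before the text can be used for secondary research. Casting
deidentification as named-entity recognition over four PHI categories
(PER, LOC, ORG, DAT) turns it into BIO sequence tagging: each surface unit
of a sentence receives `O`, `B-<cat>` or `I-<cat>`, and detected spans are
substituted with synthetic surrogates. Two practical obstacles dominate in
the clinical setting this package targets: annotated corpora are small
(labeling is expensive and the records are private), and the language of
interest may lack word delimiters, which motivates character-level units.

`phideid` implements the full method as reusable, tested components:

1. a **linear-chain CRF** prediction head with exact inference,
2. a compact **multi-head self-attention encoder** producing the CRF's
   emission scores,
3. **transformer-layer knowledge distillation** from a deeper teacher
   encoder into a shallower student,
4. a **hybrid data-augmentation engine** (generation-based augmentation
   plus mention replacement), and
5. a seeded **synthetic corpus generator** so that every component is
   exercisable end-to-end without access to any real record.

## Tokens, tags, and validity

A `labeled_sentence` holds surface units and their BIO tags; spans are
always derived from tags (`bio_to_spans()`), never stored separately, so the
two views cannot drift apart. Surface units are characters in
character-mode corpora and whitespace tokens otherwise; the package is
agnostic, and the synthetic generator uses closed pseudo-token alphabets so
no PHI-like strings ever appear in test data.

Validity is the strict BIO contract: no sentence-initial `I-`, no `I-`
after `O`, and no category switch within a span (`B-PER I-ORG` is the
canonical error). `validate_bio()` returns the violated rule and position;
readers of CoNLL-style files can either reject invalid gold tags (default)
or repair them to `O` — silent repair is opt-in because it hides annotation
bugs. Spans use 0-based, half-open indexing for unambiguous length
arithmetic.

## The tagger: emissions plus transitions

The encoder embeds each position as the sum of a word, a position, and a
token-type embedding, runs `n_layers` self-attention blocks (multi-head
attention and a position-wise feed-forward network, each with a residual
connection), and projects the final features to one score per (position,
label): the emission matrix. Padded positions are masked out of every
attention softmax, which makes emissions at real positions invariant to the
amount of padding — a property the test suite checks directly.

The CRF scores a whole label path as

    score(y) = sum_i x[i, y_i] + x[START -> y_1]
             + sum_i x[y_i -> y_{i+1}] + x[y_L -> END]

with a learned `(K+2) x (K+2)` transition matrix over the labels plus
explicit START/END boundary states. Training minimizes the negative
log-likelihood `log Z - score(gold)`, where the partition function `log Z`
is computed exactly by the forward recursion in `O(L K^2)`; gradients come
from forward–backward marginals. Decoding is Viterbi under a BIO
constraint mask that forbids exactly the invalid transitions
(`START/O -> I-*`, cross-category `B-X -> I-Y` and `I-X -> I-Y`), so
predictions are valid BIO by construction.

Numerical choices worth knowing:

* all path arithmetic is in log space with log-sum-exp stabilization;
* masked transitions receive a finite additive penalty of `-1e4` rather
  than `-Inf`, keeping every intermediate finite (a fully masked instance
  is still detected and reported as "no feasible path");
* Viterbi ties break toward the lowest label index, for determinism across
  runs and platforms;
* the emission head passes **unnormalized logits** to the CRF by default.
  A per-position softmax before a globally normalized model would normalize
  twice; because descriptions of such systems sometimes say
  "probabilities", a `softmax` emission mode is still available behind the
  `emissions_mode` flag.
* the BIO constraint is applied at decode time by default; a
  `constrain_train` option applies it during training too. Decode-time
  masking is the common practice and keeps the training objective smooth.

Everything is trained jointly (encoder and transitions) with Adam. No
pretrained weights are used anywhere: all experiments train from random
initialization at desk scale, which is what makes the whole package
runnable in minutes on one CPU.

## Knowledge distillation

A deeper `M`-layer teacher transfers its internal behavior to a shallower
`N`-layer student with `M = k N`. Student layer `n` is paired with teacher
layer `k·n` (plus the embedding pair), and three losses are summed:

* **transformer-layer loss** — per mapped pair, the mean-squared error
  between attention maps (averaged over heads) plus the MSE between the
  projected student hidden state `H_S W_h` and the teacher hidden state;
* **embedding loss** — `MSE(E_S, E_T W_e)` between the student embedding
  output and the projected teacher embedding output;
* **prediction loss** — cross-entropy of student emission logits against
  the teacher's softmax distribution, whose minimum is the teacher's own
  entropy (reached at `Z_S = Z_T`), optionally temperature-scaled
  (default temperature 1, since none is specified for the original system).

The printed form of the embedding term in the source literature is
notationally ambiguous between an L2 norm and an MSE; the package uses MSE
for consistency with the hidden-state term, and the projection directions
follow the loss definitions (`W_h` student→teacher, `W_e` teacher→student;
both reduce to trainable identities when widths match). The transformer-layer
composition follows the standard TinyBERT-style scheme, which is what the
symbols in the source define. The published recipe also mentions feeding
length-1 sequences during distillation; `distill(length_one = TRUE)`
reproduces that mode, but whole sentences are the default because they
carry the attention structure the student is supposed to inherit.

The distilled student inherits the teacher's transition matrix (its
emission head is trained by the prediction loss), so it is immediately a
working tagger.

**Distillation-benefit protocol.** `distillation_benefit()` trains the
teacher once, then per seed compares a distilled student against a
same-shape randomly initialized student, both given an identical, short
supervised fine-tuning schedule (default one epoch) before evaluation on
the held-out split. The short budget is deliberate: it probes the value of
the distilled initialization under limited adaptation, which is the regime
distillation is for. At the packaged study scale (500 synthetic sentences,
4-layer teacher, 2-layer student, width 32) the distilled student wins by a
wide margin in all three seeds.

## Hybrid data augmentation

Small training sets overfit; the package combines two complementary
augmentation strategies and keeps per-sentence provenance throughout.

**Generation-based augmentation.** Each labeled sentence is *linearized*
into a mixed stream in which every non-`O` token is immediately preceded by
its tag marker (`B-PER t1 I-PER t2 t3 ...`); `O` tokens appear bare. A
next-token language model is fit on these streams over the joint
marker/token vocabulary: each symbol is embedded (`e_t`), mapped through a
learned matrix (`h_t = M e_t`), and projected to a softmax over the
vocabulary. As printed, this recurrence conditions on the current symbol
only, so the generator is a learned low-rank bigram model — simple, fast,
and sufficient for streams whose local structure (marker–token adjacency,
span continuation) is what matters. New streams are sampled from `<bos>`
until `<eos>` (temperature-controlled; temperature → 0 is argmax) and
*delinearized* back into labeled sentences. Malformed samples — dangling
markers, invalid BIO — are rejected with reason codes rather than repaired,
so 100% of accepted sentences are valid by construction. Sampling stops
after 10x the requested count of attempts.

**Mention replacement.** Every entity in every sentence gets an independent
Bernoulli(`p`) decision (default `p = 0.5`, the published rule's
threshold); chosen entities are replaced by a uniformly drawn same-category
mention from the training pool, excluding the identical mention when
alternatives exist. Tags re-expand to the replacement's length, so outputs
stay valid.

**Hybrid set.** The augmented training set is the union
original ∪ generated ∪ replaced, with a per-category, per-source entity
summary. The default volumes — generated sentences ≈ 2x the corpus and two
replacement passes — mirror the roughly 2–3x entity-count expansion
reported for this family of methods. Evaluation and test splits are never
augmented, and `hybrid_benefit()` enforces that by splitting first
(6:2:2, the conventional ratio) and augmenting only the training part.

## The synthetic corpus generator

The generator emulates the structure of a 4-type PHI training corpus
without containing any real-language content:

* **type proportions** default to PER .258, LOC .054, ORG .151, DAT .537 —
  the composition of the original training corpus this line of work reports
  (a DAT-dominant, LOC-scarce mix);
* **entity density** defaults to 1.5 expected entities per sentence, with
  30% of sentences *entity-sparse* (density scaled to 15%), reflecting the
  observation that clinical sentences are often mostly `O`;
* **mention structure**: each category draws from its own pseudo-token
  alphabet, with DAT mentions longer (4–7 units) and internally templated
  with a separator unit, so a learnable type signal exists; 30% of
  non-DAT mention units come from a shared ambiguous alphabet that also
  appears in background text, so single-token lookup is not sufficient and
  context matters;
* **sentence lengths** are uniform on 5–18 units by default, and all
  generation is deterministic per seed (byte-identical CoNLL output).

Surrogate pools for deidentification come from a dedicated alphabet the
generator never uses, making pool/gold disjointness structural.

What passing tests on this data do *not* show: robustness to real clinical
language (orthographic variety, abbreviations, genuinely ambiguous
mentions, annotation noise) or to PHI types beyond the four modeled here.
The generator measures whether the machinery — inference, distillation,
augmentation, evaluation — behaves as specified, not field performance.

## Evaluation

Entity-level scoring uses exact (start, end, category) matching — no
partial credit, matching how results in this area are reported. Precision,
recall and F1 (`2PR/(P+R)`) are reported in percent per category and
pooled (micro). Zero denominators yield 0 by convention. The suite checks
the implementation against hand-computed fixtures and an independently
written scorer on random corpora. Micro metrics here are entity-level;
token-level accuracy is deliberately not a headline metric.

## Study scales and runtime

All packaged experiments are sized for a single CPU: encoders of width
32 with 2 attention heads, sequence length capped at 24 units, corpora of
500 synthetic sentences split 6:2:2, three seeds per comparison. The
distillation-benefit and hybrid-benefit experiments complete in a few
minutes each; the exact CRF oracle checks enumerate up to `5^6` paths per
instance. With these sizes the full test suite and the acceptance script
each run end-to-end in well under half an hour.

```{r, eval = FALSE}
co <- generate_corpus(generator_spec(n_sentences = 500, seed = 1))
parts <- split_corpus(co, seed = 42)
cfg <- encoder_config(n_layers = 2, hidden_dim = 32, n_heads = 2,
                      ffn_dim = 64, max_len = 24)
model <- train_tagger(parts$train, cfg,
                      tagger_train_config(epochs = 8, lr = 5e-3, seed = 1),
                      eval = parts$eval)
pred <- predict_corpus(model, parts$test)
score_entities(match_entities(parts$test, pred))
```

## Known limitations

* The encoder omits layer normalization; at the packaged widths and depths
  training is stable with Adam at the default learning rates, and the
  omission keeps the padding-invariance property exact, but very deep
  configurations would want it.
* The generation model is a bigram over linearized streams; it cannot
  capture long-range sentence structure. It is pluggable (`daga_augment()`
  accepts any pre-trained `lm_params`-compatible generator).
* Annotation bootstrapping flags sentences by normalized Viterbi path
  probability; the threshold is a pragmatic review dial, not a calibrated
  probability of error.
* No nested or discontinuous entities, no BIOES dialect, and no support
  for loading pretrained transformer weights.
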