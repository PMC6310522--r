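---
title: "Chemical–protein relation extraction with shortest-path LSTM ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical–protein relation extraction with shortest-path LSTM ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprex)
```

## The scientific problem

Biomedical abstracts describe interactions between chemical compounds and
proteins ("aspirin *inhibits* COX-2"). The extraction task addressed here is:
given an abstract with pre-annotated CHEMICAL and GENE entity mentions and a
dependency parse of each sentence, classify every same-sentence
(CHEMICAL, GENE) candidate pair into one of ten grouped chemical–protein
relation (CPR) classes or an explicit `negative` class. Five of the ten CPR
classes count towards the official metric — CPR:3 (upregulation), CPR:4
(downregulation), CPR:5 (agonist), CPR:6 (antagonist) and CPR:9
(substrate/product) — giving the micro-averaged F-score over that subset as
the headline number.

`cprex` implements this stack end to end in plain R: corpus I/O,
shortest-dependency-path (SDP) feature extraction, two hand-implemented
LSTM classifier architectures trained as ensembles, two-system combination,
the evaluation protocol, and a seeded synthetic-corpus generator that makes
the whole pipeline testable at desk scale without any external data.

## The model

### Shortest dependency paths over augmented parse graphs

For each sentence an undirected weighted graph is built: one node per
token, one weight-1 edge per dependency arc, plus a weight-5
*word-adjacency* edge between every pair of linearly adjacent tokens. The
adjacency edges guarantee connectivity when the parser emits fragments and
add robustness to attachment errors; their heavier weight makes the search
prefer genuine syntax. The SDP between the chemical head token and the gene
head token is found with Dijkstra's algorithm under a fully deterministic
ordering: minimum total weight, then fewest edges, then the
lexicographically smallest token-index sequence. The path is always
reported chemical→gene and yields three parallel sequences: surface words,
POS tags, and dependency-type labels. Dependency labels carry a traversal
direction marker (`↑` dependent-to-head, `↓` head-to-dependent); adjacency
edges contribute the reserved label `ADJ`.

```{r sdp}
# "Rapamycin allosterically inhibits the proteasome"
sent <- list(
  tokens = data.frame(index = 1:5,
                      surface = c("Rapamycin", "allosterically", "inhibits",
                                  "the", "proteasome"),
                      pos = c("NN", "RB", "VBZ", "DT", "NN")),
  heads = c(3L, 3L, 0L, 5L, 3L),
  deplabels = c("nsubj", "advmod", "root", "det", "dobj"))
chem <- data.frame(tok_first = 1L, tok_last = 1L)
gene <- data.frame(tok_first = 5L, tok_last = 5L)
pair_sdp(sent, chem, gene)[c("words", "dt_labels")]
```

### Input encoding

Tokens are mapped to rows of a pretrained word-embedding matrix
(case-sensitive lookup with a lowercase fallback). Entity tokens missing
from the vocabulary are substituted by the reserved words `"chemical"` /
`"protein"`, keeping a generic type signal for the frequent exotic entity
surfaces; all remaining unknown words share a zero UNK row that doubles as
padding. Sentence tokens additionally carry two fixed 10-bit
relative-position encodings (sign bit plus 9 magnitude bits, distances to
the two entity heads, clipped at 511 — injective on [−511, 511]) and a
five-way token type (inside chemical span / inside gene span / before /
between / after). POS and dependency-type vocabularies are built from the
training split only, with a reserved UNK id for unseen values.

### Two architectures, one decision layer

* **ST-ANN** (SDP-only): three unidirectional LSTM chains read the SDP word,
  POS and dependency-type sequences; their final hidden states are
  concatenated.
* **I-ANN** (SDP + sentence): additionally a bidirectional LSTM reads the
  full sentence (word + POS embeddings + both position vectors + token-type
  embedding per token) and its per-token states are max-pooled over time.

Either representation feeds a 1024-unit `tanh` dense layer with dropout
0.2 and an 11-way softmax. Training minimizes categorical cross-entropy
with the Nadam optimizer, reshuffling the training set before every epoch;
when a dev split is supplied, training stops once the dev micro-F has
failed to improve for `patience` consecutive epochs and the best epoch's
parameters are kept. Reference hyperparameters (embedding and LSTM sizes,
batch 16 / learning rate 0.0005 / 4 epochs for I-ANN, batch 32 / 0.002 / 3
for ST-ANN) are the defaults of `model_config()`; every field can be
overridden.

The LSTMs, pooling, backpropagation and Nadam are implemented in base R
matrix code. That is deliberate: the recurrent feature learner *is* the
scientific core of the package, no deep-learning runtime is available in
the target environment, and an explicit implementation makes the numeric
contracts testable (the test suite checks analytic gradients against
finite differences, padding invariance, and determinism).

### Ensembles and system combination

An ensemble trains `n` architecture-identical networks that differ only in
their seeded initialization/shuffling (member *i* uses seed
`base_seed + i − 1`); per-class confidences are summed across members and
the argmax class is selected (ties to the lowest class index). The summed
confidence of the winning class is exported as the raw score. Two systems'
prediction sets are combined after per-set min–max normalization into
[0, 1] (a degenerate range maps to 0.5) and optional class filtering
(`all` / `positive` / `eval`): **OR** keeps the union of pair keys, **AND**
the intersection, and where both systems predict, the higher normalized
confidence wins (ties go to the first argument).

### Evaluation protocol

Scoring builds an 11×11 confusion matrix (rows = gold, columns =
predicted, canonical CPR order) from the candidate pairs: unpredicted
pairs default to `negative`, multi-label gold pairs contribute one count
per gold label with the same predicted label, and cross-sentence gold
annotations — which same-sentence classifiers can never recover — are
forced false negatives. Micro precision/recall/F over a class subset are
percentages at two decimals; the exact integer counts stay available. Over
all 11 classes the micro-F equals accuracy.

The package ships, as plain-text fixtures, two published reference
confusion matrices of an SVM and an LSTM-ensemble system on the CHEMPROT
test set plus the per-class annotation counts; the evaluation module
reproduces their printed summary metrics exactly (micro-F 60.10 / 75.39
and 60.15 / 72.15), which pins the protocol down to rounding.

## The synthetic corpus generator

Real headline numbers require the CHEMPROT corpus, external parsers,
pretrained PubMed vectors and GPU-scale training, none of which are
reproducible at desk scale. Instead `generate_corpus()` writes a fully
synthetic corpus with a *planted trigger rule*: each positive sentence
contains a class-specific trigger word (`activates` → CPR:3, `inhibits` →
CPR:4, `metabolizes` → CPR:9). In the default **on-SDP** variant the
dependency tree is constructed so the trigger lies on the chemical–gene
dependency path; a rule-based oracle (`sdp_trigger_oracle()`) then
classifies perfectly, upper-bounding the task. In the **off-SDP** variant
the chemical and gene are linked by a direct edge and the trigger hangs
elsewhere, so SDP-only models are blind to it while sentence-reading
models are not — reproducing, qualitatively, the motivation for the
sentence-augmented architecture. Extra (negative) gene mentions, entity
surfaces missing from the word vectors, and cross-sentence gold relations
exercise the corresponding pipeline branches. Output is byte-deterministic
given the spec and seed.

Limitations are intentional: tiny vocabulary, fixed sentence skeletons,
one chemical per sentence, and a noiseless label rule. The generator
validates mechanism, not linguistic realism; learned F-scores on it say
nothing about CHEMPROT performance.

## A worked desk-scale experiment

```{r experiment}
spec <- synthetic_spec(n_documents = 40, seed = 7)
dir <- tempfile()
generate_corpus(spec, dir)
corpus <- read_synthetic_corpus(dir)
vectors <- generate_word_vectors(synth_vocabulary(spec), dim = 16, seed = 7)

config <- model_config_tiny("i")
train <- encode_split(corpus, vectors, config)

dev_dir <- tempfile()
generate_corpus(synthetic_spec(n_documents = 15, seed = 8), dev_dir)
dev <- encode_split(read_synthetic_corpus(dev_dir), vectors, config,
                    vocabs = train$vocabs)

ens <- train_ensemble(train$examples, config, vectors, train$vocabs,
                      n = 2, base_seed = 7, dev_examples = dev$examples)
pred <- predict_ensemble(ens, dev$examples)
res <- evaluate_predictions(dev$pairs, pred, dev$cross_sentence,
                            classes = "target")
res$micro
```

`model_config_tiny()` is a pre-hoc reduced configuration (16-unit LSTMs,
32-unit dense layer, 8-d feature embeddings, learning rate 0.005, up to 10
epochs with best-epoch selection) sized so that a full train/evaluate
cycle on a few hundred sentences takes seconds to minutes on one CPU; the
learning rate is raised relative to the reference configuration because
the reduced network is far from the regime the published rates were tuned
for. The corpus sizes in this vignette and in the acceptance script are
the package's own choices for desk-scale validation.

## Numerical choices worth knowing

* **Path tie-breaking** is fully specified (weight, edge count,
  lexicographic token order), so SDP features are reproducible across
  platforms; where a dependency edge parallels an adjacency edge the
  dependency label is reported.
* **Entity heads**: the unique span token whose head lies outside the span;
  if none or several, the last span token.
* **Direction markers** on dependency labels default to on
  (`directed_dt = TRUE`); the DT vocabulary is collected from actual
  training SDPs so marked labels and `ADJ` appear exactly as consumed.
* **Truncation**: SDPs keep their start (chemical end); sentences keep a
  window that covers both entity spans.
* **Nadam** uses the Nesterov-momentum bias-correction variant
  (`m̂ = μ m_t/(1−μ^{t+1}) + (1−μ) g_t/(1−μ^t)`) with μ = 0.9, ν = 0.999,
  ε = 1e-8.
* **Word embeddings are fine-tuned** (they receive gradient updates);
  position bits are fixed encodings with no trainable parameters.
* **Normalization order**: class filtering happens before min–max
  normalization in the CLI pipeline; `combine_predictions()` refuses
  unnormalized inputs rather than guessing.
* **Rounding**: reported percentages use R's `round()` (half-to-even) at
  two decimals; tests compare exact counts where exactness matters.

## Reproducing the acceptance quantities

`scripts/acceptance.R` recomputes every headline quantity — fixture metric
reproduction, annotation-count arithmetic, SDP-vs-enumeration agreement,
the worked path, planted-rule recovery with the on-/off-path architecture
contrast, combination algebra and forward-pass contracts — and writes them
as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run takes about a minute on one
CPU.
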