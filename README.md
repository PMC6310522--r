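# cprex

Chemical–protein relation extraction with shortest-path LSTM ensembles,
implemented end to end in base R.

## The problem

Biomedical abstracts state interactions between chemicals and proteins
("aspirin *inhibits* COX-2"). Given an abstract with annotated CHEMICAL and
GENE mentions and a dependency parse of each sentence, the task is to
classify every same-sentence (CHEMICAL, GENE) candidate pair into one of
ten grouped chemical–protein relation (CPR) classes or an explicit
`negative` class. The headline metric is the micro-averaged F-score over
the five officially evaluated classes: CPR:3 (upregulation), CPR:4
(downregulation), CPR:5 (agonist), CPR:6 (antagonist) and CPR:9
(substrate/product).

## The model

For each sentence an undirected graph is built from the dependency parse
(weight-1 edges) plus *word-adjacency* edges between consecutive tokens
(weight 5), which guarantee connectivity and soften parse errors. The
shortest dependency path (SDP) from the chemical head token to the gene
head token — Dijkstra with deterministic tie-breaking — yields word, POS and
direction-marked dependency-label sequences.

Two classifier architectures share an 11-way softmax decision layer behind
a 1024-unit `tanh` dense layer with dropout:

- **ST-ANN** — three LSTM chains over the SDP word/POS/dependency-type
  sequences, final states concatenated;
- **I-ANN** — ST-ANN plus a bidirectional sentence LSTM (word + POS
  embeddings, two 10-bit relative-position encodings, token-type
  embedding per token) with max-over-time pooling.

Networks train with categorical cross-entropy and Nadam, and are deployed
as ensembles: members differ only in their seeded initialization,
per-class confidences are summed and the argmax class wins. Two systems'
prediction sets can be combined as a union (OR) or intersection (AND)
after min–max confidence normalization, resolving conflicts by the higher
normalized score. Evaluation builds an 11×11 confusion matrix with
generated negatives, multi-label gold duplication and cross-sentence gold
annotations as forced false negatives.

The LSTM forward/backward passes, pooling and Nadam are written in plain R
matrix code on purpose: the recurrent feature learner is the scientific
core, and an explicit implementation keeps every numeric contract
testable (finite-difference gradient checks, padding invariance,
determinism).

## Worked example

Everything below runs offline in seconds, using the built-in synthetic
corpus generator with its planted trigger-word rule (`activates` → CPR:3,
`inhibits` → CPR:4, `metabolizes` → CPR:9).

```r
library(cprex)

spec <- synthetic_spec(n_documents = 40, seed = 7)
dir <- tempfile()
generate_corpus(spec, dir)                      # abstracts/entities/relations TSV + CoNLL-U
corpus <- read_synthetic_corpus(dir)
vectors <- generate_word_vectors(synth_vocabulary(spec), dim = 16, seed = 7)

config <- model_config_tiny("i")                # reduced I-ANN configuration
train <- encode_split(corpus, vectors, config)

dev_dir <- tempfile()
generate_corpus(synthetic_spec(n_documents = 15, seed = 8), dev_dir)
dev <- encode_split(read_synthetic_corpus(dev_dir), vectors, config,
                    vocabs = train$vocabs)

ens <- train_ensemble(train$examples, config, vectors, train$vocabs,
                      n = 2, base_seed = 7, dev_examples = dev$examples)
pred <- predict_ensemble(ens, dev$examples)
evaluate_predictions(dev$pairs, pred, dev$cross_sentence,
                     classes = "target")$micro
```

```
$precision
[1] 90.91

$recall
[1] 90.91

$f
[1] 90.91

$tp
[1] 20

$predicted
[1] 22

$gold
[1] 22
```

(40 training documents are deliberately few; the acceptance script trains
on 250 documents and reaches dev micro-F 100.)

The SDP of a worked sentence:

```r
sent <- list(
  tokens = data.frame(index = 1:5,
                      surface = c("Rapamycin", "allosterically", "inhibits",
                                  "the", "proteasome"),
                      pos = c("NN", "RB", "VBZ", "DT", "NN")),
  heads = c(3L, 3L, 0L, 5L, 3L),
  deplabels = c("nsubj", "advmod", "root", "det", "dobj"))
pair_sdp(sent, data.frame(tok_first = 1L, tok_last = 1L),
               data.frame(tok_first = 5L, tok_last = 5L))[c("words", "dt_labels")]
#> $words
#> [1] "Rapamycin"  "inhibits"   "proteasome"
#> $dt_labels
#> [1] "nsubj↑" "dobj↓"
```

A thin command-line front end over the same functions lives at
`inst/cli/cprex-cli.R` (subcommands `synth`, `train`, `predict`,
`combine`, `evaluate`).

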