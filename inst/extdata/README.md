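# Reference fixtures

Plain-text reference tables for the evaluation module:

- `chemprot_test_confusion_svm.tsv`,
  `chemprot_test_confusion_lstm_ensemble.tsv` — published 11x11 confusion
  matrices (rows = true labels, columns = predicted labels, canonical CPR
  order) of an SVM system and an LSTM-ensemble system evaluated on the
  CHEMPROT test set under the internal protocol (generated negatives,
  multi-label duplication, cross-sentence false negatives).
- `chemprot_test_annotation_counts.tsv` — per-class annotation counts of
  the CHEMPROT test set under the same protocol.

These are inputs for metric-reproduction checks; nothing in the package is
fitted to them.
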