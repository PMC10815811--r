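# contactfuse

Structure-plus-sequence feature engineering for supervised protein
classification, entirely in R.

Many protein classes are defined jointly by fold and by sequence: neither
a structural descriptor nor a sequence descriptor alone recovers them.
`contactfuse` builds both kinds of per-protein feature vector from the
same PDB files, fuses them by concatenation, and evaluates the result with
a repeated-split classification harness:

* **Contact-map embedding** — from the C-alpha trace
  $x_1,\dots,x_n \in \mathbb{R}^3$ of a structure, the distance matrix
  $D_{ij}=\lVert x_i-x_j\rVert$ is thresholded into a binary contact map
  $C_{ij}=\mathbf{1}[D_{ij}\le 8\,\text{Å}]$ (inclusive), reduced with a
  principal-component projection retaining ≥ 99% of the variance, and
  flattened into a fixed-length vector. By default one projection is
  fitted across the corpus so embedding coordinates are comparable
  between proteins; the literal per-protein projection is also available.
* **k-mer embedding (Spike2Vec)** — counts of all sliding windows of
  length $k=3$ over the 21-letter alphabet `ACDEFGHIKLMNPQRSTVWXY`
  ($21^3 = 9261$ entries, lexicographic order).
* **External embeddings** — precomputed language-model vectors (e.g.
  SeqVec-style, 1024-dimensional) loaded from delimited tables; the
  language model itself is never run here.
* **Evaluation harness** — stratified 70/30 split with a 10% tuning
  holdout, seven classifiers (SVM, NB, MLP, KNN, RF, LR, DT), accuracy /
  weighted precision–recall–F1 / macro F1 / one-vs-rest ROC-AUC, five
  repeated runs with mean ± sd, and Welch t-tests between methods.
* **Synthetic structures** — a generator of idealized helix/extended
  PDB files with controllable coordinate noise and implanted sequence
  motifs, so the whole pipeline is testable without downloading anything.

## Worked example

A corpus where class identity requires both channels: "binder" proteins
are helical *and* carry a `WWW` motif; "non-binder" mixes helical
proteins without the motif and extended proteins with it.

```r
library(contactfuse)

components <- tibble::tibble(
  label    = c("binder", "non-binder", "non-binder"),
  geometry = c("helix",  "helix",      "extended"),
  n        = c(50,       25,           25),
  motif    = c("WWW",    NA,           "WWW")
)
corpus <- synthetic_corpus(components, length_range = c(30, 60),
                           noise_sd = 0.2, seed = 42)
traces <- read_ca_traces(attr(corpus, "dir"))
labels <- corpus[c("id", "label")]

structure_emb <- embed_contact_maps(traces)                # 42 dims here
sequence_emb  <- embed_spike2vec(trace_sequences(traces))  # 9261 dims
fused         <- fuse_embeddings(structure_emb, sequence_emb)

reports <- lapply(list(structure = structure_emb, sequence = sequence_emb,
                       fused = fused), function(e)
  repeat_experiment(e, labels, classifiers = "LR", n_runs = 5, base_seed = 7))
```

The run prints (logistic regression, mean ± sd over 5 random splits):

```
structure LR accuracy 0.720 +- 0.069  ROC-AUC 0.759
sequence  LR accuracy 0.707 +- 0.076  ROC-AUC 0.670
fused     LR accuracy 0.900 +- 0.085  ROC-AUC 0.989
```

Either channel alone tops out near its theoretical ceiling of ~0.75
(each sees only half the rule); the fused embedding recovers the joint
rule. The difference is significant across runs:

```r
compare_methods(reports$fused, reports$structure)
#>   classifier metric   mean_a mean_b statistic p_value
#>   LR         accuracy    0.9   0.72      3.67 0.00673
```

`tidy()`, `glance()` and `autoplot()` work on every report, and
`plot_contact_map()` draws the map itself.

A command-line front end mirrors the same steps
(`inst/cli/contactfuse.R`): `simulate`, `extract` (PDB → FASTA),
`embed --mode contact-map|spike2vec|external`, and `evaluate`, all
reading and writing plain delimited tables.

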