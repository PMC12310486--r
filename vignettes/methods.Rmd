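---
title: "Predicting miRNA-mRNA interactions from sequence and graph embeddings"
author: "mirtarnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-mRNA interactions from sequence and graph embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MicroRNAs (miRNAs) are ~22 nt non-coding RNAs that repress messenger RNAs
by partial base pairing, with specificity dominated by the *seed region*
(miRNA positions 2--8) binding sites that concentrate in the 3' UTR of the
target. Experimentally validating miRNA--mRNA pairs is slow and expensive,
so computational ranking of candidate pairs is a standard first step.
`mirtarnet` scores candidate pairs by fusing two complementary views:

* a **sequence view** -- both RNAs are embedded at the 6-mer level and
  passed through a CNN--BiLSTM encoder whose outputs interact through a
  multi-head *mutual attention* layer (miRNA positions query mRNA
  positions), and
* a **graph view** -- each RNA is a node of the bipartite graph of known
  interactions, embedded with GraRep so that multi-step random-walk
  structure is available to the classifier.

A small backpropagation ("BP") fusion network maps the concatenated
sequence and node feature vectors to an interaction probability.

## Sequence preprocessing

FASTA input may use the DNA or RNA alphabet; `normalize_sequence()`
uppercases, strips whitespace and maps T to U. Ambiguity codes are
rejected rather than imputed: the 4^k vocabulary has no slot for them.

mRNAs are **reversed** (character reversal, no complementation) before any
tokenization, so the encoder sees the mRNA in the orientation in which a
miRNA physically pairs with it; complementarity itself is left for the
model to learn. Reversal is applied before both pretraining fragmentation
and downstream encoding, so the two stages see the same orientation.

Sequences are tokenized into overlapping 6-mers (a length-L sequence gives
L - 5 tokens) over the 4096-token lexicographic vocabulary.

## Pretrained 6-mer embeddings

`train_embeddings()` learns 64-dimensional 6-mer vectors with skip-gram and
negative sampling (the standard estimator of the softmax co-occurrence
objective), optionally with FastText-style character n-gram subwords (range
3--5 over the boundary-marked token; `subword_ngrams = "off"` recovers
plain skip-gram). The corpus is built by `build_corpus()`: every miRNA
contributes one sentence; every (reversed) mRNA is cut by
`fragment_mrna()` into 200--400 nt windows overlapping by 100 nt so that
potential binding sites are never split across windows, one sentence per
window. Window lengths are drawn uniformly from [200, 400] with a seeded
generator; the final window is truncated at the sequence end and always
kept -- it is necessarily longer than the overlap, so it always contributes
new sequence. Defaults (window 5, 10 epochs, 5 negative samples, initial
learning rate 0.025 with linear decay) follow common word2vec/FastText
practice. Tokens absent from the corpus keep zero rows so they stay inert
downstream. Training is single-threaded and bit-reproducible for a fixed
seed.

## GraRep node features

`grarep_embed()` implements the matrix-factorization recipe: transition
matrix $A = D^{-1}S$ from the symmetric 0/1 adjacency $S$; for each step
$k \le K$ the PPMI-style matrix
$X^k_{ij} = \max\!\big(0,\ \log(A^k_{ij}/\Gamma^k_j + \varepsilon) - \log\beta\big)$
with $\Gamma^k_j$ the column sums of $A^k$; truncated SVD
$W^k = U_d \Sigma_d^{1/2}$; and concatenation $W = [W^1 \mid \dots \mid W^K]$.
Defaults: $K = 4$, $d = 16$ (so the node feature is 64-dimensional,
matching the sequence embedding width), $\beta = 1/N$, $\varepsilon =
10^{-9}$. The $\Gamma$ normalization can be disabled
(`normalize_gamma = FALSE`) to take the log of the raw k-step probability
instead; the normalized variant is the default because it reproduces the
published GraRep matrix and makes $\Gamma$ meaningful. Numerical choices:
isolated nodes keep all-zero transition rows (with a warning); all-zero
columns stay zero through the $\varepsilon$ guard; each singular vector is
sign-fixed so its largest-magnitude entry is positive, making runs
bit-comparable; ties in singular values fall back to LAPACK ordering, so
only the factorization subspace (not individual columns) is unique in
degenerate graphs. Nodes absent from the embedded graph receive zero
vectors (`node_features()`), the standard transductive cold-start
fallback.

## The encoder

Per side (miRNA / mRNA, separate weights): embedding lookup (initialized
from the pretrained table and fine-tuned), 1-D convolution with odd kernel
(default 5) and 'same' zero padding, ReLU, non-overlapping max-pool
(default 2), then a bidirectional LSTM (default 32 units per direction,
forget-gate bias 1) whose forward/backward states are concatenated. Token
capacities default to 25 (miRNA) and 400 (mRNA) tokens; mRNAs keep the
first `mrna_len` tokens of the *reversed* sequence, i.e. the 3' end of the
original transcript, where binding sites concentrate. Padding uses a
dedicated index with a zero embedding row; padded positions are masked out
of the LSTM state updates, the attention keys (score $-\infty$ before the
softmax) and all pooled means.

Mutual attention (default 4 heads): per head,
$Q = H^{\text{mi}} W_Q$, $K = H^{\text{m}} W_K$, $V = H^{\text{m}} W_V$,
$A = QK^\top/\sqrt{d_k}$, $\alpha = \text{row-softmax}(A)$, output
$\alpha V$; heads are concatenated. In the default `mi_queries_m` mode the
miRNA vector is the masked mean of the attended output and the mRNA vector
is a pooled summary of the BiLSTM output; a `bidirectional` mode adds a
role-swapped attention pass with its own projections.

Ablation variants mirror the architecture study: `noatt` removes
attention, `lstm` uses a unidirectional LSTM, `nolstm` feeds the pooled
CNN map straight into attention. Fusion variants: `concat_bp`
(concatenate the four feature vectors, one ReLU hidden layer, sigmoid),
`add` / `average` (element-wise combination, same head), `dnn` (three
hidden layers), `no_bp` (a single linear layer into the sigmoid).

Training minimizes binary cross-entropy with Adam (default lr $10^{-3}$,
batch 64) over seeded shuffled minibatches; a stratified validation split
selects the best epoch. The numerical core is single-precision C++ (the
workload is BLAS-bound on one CPU), which, together with single-threaded
execution, makes runs bit-reproducible for a fixed seed.

## Two shortcuts, and the regularizers that close them

Working with leak-free per-fold node embeddings (below) exposes a subtle
failure mode that we consider one of the package's more important lessons.

**The transductive shortcut.** GraRep features are functions of the graph
that is embedded. During cross-validation the graph is built from
*training-fold positive edges only* -- held-out edges must not leak into
node features. But then every training positive *is* an edge of the
embedded graph, so raw node features separate the training labels
essentially perfectly while carrying no information about held-out
(non-edge) pairs: gradient descent happily memorizes topology and never
trains the sequence pathway. `node_dropout` (default 0.5) stochastically
hides the pair's node vectors during training (with inverted scaling), so
the loss cannot be minimized through the node view alone.

**Pair memorization.** With a few hundred distinct sequences, the encoder
can also memorize transcript identities and the training pair table
through the sequence view. `augment_crop` (default 0.5) re-encodes every
mRNA each epoch from a random window covering at least that fraction of
its tokens: transcript-identity features become unstable across epochs
while local binding-site content survives.

Related choices: the mRNA sequence vector defaults to a column-wise
**max** over valid positions (`mrna_summary = "max"`) rather than a mean,
because presence of a localized binding-site-like feature anywhere in a
~800-token transcript is a max-type statistic -- a mean buries it by a
factor of the sequence length. The masked mean remains available
(`mrna_summary = "mean"`), and `pool_features()` -- the pooling applied to
the attended miRNA output, whose time dimension is short -- is a masked
mean.

## Evaluation protocol

`sample_negatives()` draws unobserved miRNA-mRNA combinations uniformly
without replacement (balanced by default). `kfold_split()` stratifies by
label. Thresholded metrics (ACC, F1, MCC, SEN, PPV, TNR) use score
$\ge 0.5$ as the positive call; zero-denominator metrics are reported as 0
and flagged. AUC is the rank-based (Mann-Whitney) statistic with ties at
half credit; AUPR is the average-precision step area with tied scores
grouped. `cross_validate()` rebuilds the node embedding per fold from
training positives only (a `full_graph` flag embeds the complete positive
graph instead, for studying exactly the leakage discussed above), trains
on the training fold and scores the held-out fold; the report carries one
row per fold plus the mean and the sample (n-1) standard deviation.

## The synthetic fixture

`generate_fixture()` emulates the shape of a curated interaction corpus at
desk scale: 40 miRNAs of 22 nt, 120 mRNAs of 200--800 nt (i.i.d. uniform
residues), 600 positive + 600 negative pairs. For each positive pair the
Watson-Crick reverse complement of the miRNA seed (positions 2--8) is
written into the mRNA at a random position, never overlapping a previously
planted site; labels flip independently with `noise_rate`. By
construction a trivial substring matcher separates noise-free classes
perfectly (AUC 1), bounding what any model can achieve. The generator does
**not** simulate binding thermodynamics, site accessibility, conservation,
expression, or the hub-dominated degree structure of real interaction
networks -- so the graph view is pure noise here, and passing synthetic
tests demonstrates plumbing and the sequence pathway, not biological
validity.

`synthetic_benchmark()` is the packaged end-to-end protocol: pretraining
on the fixture corpus, then 5-fold cross-validation of the full model, a
label-shuffled control, and the `noatt` / `nolstm` ablations, using
`benchmark_model_config()` (800-token mRNA windows to cover the longest
simulated transcripts, pool 4 to shorten the recurrent pass, 20 epochs at
Adam lr $5 \times 10^{-3}$, the anti-shortcut regularizers above). These
problem sizes are the package's choice for minutes-scale single-CPU runs;
`scripts/acceptance.R` reproduces all of its numbers from scratch.

## Known limitations

* The fused model must *discover* the miRNA-conditioned complementarity
  relation (which mRNA motif matters depends on which miRNA is present) by
  gradient descent. At the fixture's scale -- ~1000 training pairs, 40
  distinct seeds, ~24 positives per seed -- this conjunctive credit
  assignment is beyond what the architecture reaches within the
  benchmark's training budget: the leak-free cross-validated AUC that
  `scripts/acceptance.R` computes sits near chance, indistinguishable from
  its label-shuffled control. The test suite's global-motif check shows
  the converse: when the planted site is the *same* for every positive
  pair, the identical pipeline recovers it essentially perfectly on
  held-out pairs. Together these bracket the honest conclusion: the
  pipeline is sound, single-motif detection is easy, and the
  miRNA-conditioned matching needs substantially more data or training
  than a desk-scale run provides. Treat the synthetic benchmark AUC as a
  measure of end-to-end trainability at this scale, not as an upper bound
  on the architecture at realistic data sizes.
* GraRep embeddings are transductive; unseen nodes fall back to zero
  vectors.
* Attention weights are only reported per head via `mutual_attention()`;
  no attempt is made to interpret them as binding-site locations.
* The mRNA capacity truncates long transcripts to their 3' end; genuinely
  5'-located sites in long transcripts fall outside the default window.
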