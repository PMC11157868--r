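---
title: "Dual graph representation learning for circRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual graph representation learning for circRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Experimentally validated circRNA-disease associations form a very sparse
bipartite graph: a typical curated resource covers a few hundred circRNAs
and under a hundred diseases at 1-2% density. `circlink` treats candidate
discovery as link prediction on the heterogeneous network
`X = [[0, A], [A^T, 0]]` built from the binary association matrix `A`, and
scores unknown pairs with a classifier trained on two complementary node
representations:

* a **local** embedding `H_l`: graph-convolutional propagation of
  similarity-derived node features, capturing each node's immediate
  neighbourhood;
* a **global** embedding `H_g`: skip-gram vectors learned from biased
  second-order random walks, capturing community-level network position.

The central modelling assumption is the standard one for this family of
methods: circRNAs associated with semantically similar diseases are
functionally similar, and vice versa, so similarity structure plus network
topology carries signal about unobserved links.

## Similarity construction

**Disease semantic similarity (DS).** Each disease term sits in a rooted
DAG (MeSH-style child-to-parent edge list). An ancestor `a` of target `d`
contributes `SC_d(a) = max over children c of a within d's ancestor set of
gamma * SC_d(c)`, with `SC_d(d) = 1`. For `gamma <= 1` this is
`gamma^(shortest downward distance)`, but we implement the recursive max
rule directly so multi-parent (diamond) terms are handled exactly; the unit
tests check it against an explicit all-paths enumeration. Similarity is the
shared-ancestor contribution mass normalised by the two semantic values.
`gamma` defaults to 0.5 (dimensionless decay per DAG level), the value
conventionally used with this recursion; larger values flatten the
hierarchy, smaller values make similarity nearly diagonal. Diseases absent
from the ontology are retained with `T_d = {d}` and a warning: they get
self-similarity 1 and zero cross-similarity, and the Gaussian-kernel
fallback (below) fills their rows. Dropping them instead would silently
change the node set between folds.

**circRNA functional similarity (FS)** is the symmetric best-match average:
each disease of one circRNA is matched against the other circRNA's disease
set under DS, summed both ways and divided by the total number of diseases.
We deliberately use the cross-set form (set `i` scored against set `j` and
vice versa); scoring a set against itself would make every term 1 and the
measure vacuous. circRNAs with no training-fold association have an empty
disease set and an all-zero FS row (including the diagonal, which we leave
at 0 because a unit self-similarity there would survive integration and
mask the kernel fallback).

**Gaussian interaction profile kernels (CK, DK).** Profile vectors are rows
(circRNAs) or columns (diseases) of `A`;
`K(i, j) = exp(-lambda * ||p_i - p_j||^2)` with
`lambda = p / sum_i ||p_i||^2`, i.e. bandwidth adapted to the mean profile
norm. An all-zero `A` leaves the bandwidth undefined and is an explicit
error.

**Integration.** `Xc` keeps FS where it is nonzero and falls back to CK
elsewhere; `Xd` likewise patches DS with DK. This is idempotent and keeps
the informative, ontology-driven values wherever they exist while ensuring
the matrices fed downstream are dense enough to train on.

## Feature extraction

A sparse auto-encoder compresses each row of `Xc` (and `Xd`) to `k`
dimensions: `y = sigmoid(x W1 + b1)` with `W1: p x k`, then a second layer
`z = sigmoid(y W2 + b2)` with square `W2: k x k`. The default training
objective is the *code-consistency* loss `(1/p) sum ||y - z||^2`: with a
square second layer the architecture cannot reconstruct the p-dimensional
input, so the natural objective for this exact architecture is agreement
between the hidden code and its nonlinear re-mapping, and the per-row
output `z` is the feature used downstream. A conventional auto-encoder
(decoder `W2: k x p`, loss `(1/p) sum ||x - z||^2`, hidden code `y` as the
feature) is available via `ae_objective = "reconstruction"` for users who
prefer the textbook variant. Sparsity is an optional L1 penalty on hidden
activations (`ae_l1`, default 0 — the penalty is off unless requested).

Training is plain full-batch gradient descent: 200 epochs at learning rate
1e-3 by default, weights initialised from a seeded standard normal scaled
by `1/sqrt(fan-in)`. On the similarity matrices this package targets
(entries in [0, 1], a few hundred rows) this is smooth and stable; the
tests assert the loss is finite at every epoch and non-increasing over the
final half of training to 1e-6. A non-finite loss aborts with the epoch
index (the usual cause is a user-supplied learning rate far above 1e-2).

`k` defaults to 64, a width suited to benchmark-scale inputs (hundreds of
circRNAs). The encoder cannot be wider than its input, so `k <= min(n, m)`
is enforced; on the 100 x 30 synthetic benchmark used throughout the tests
we set `k = 16`.

## Local embedding (GCN propagation)

`H^{t+1} = ReLU(Â W_t H^t)` with `Â = D̃^{-1/2}(X + I)D̃^{-1/2}`,
`H^0 = Q`, and depth 2 by default. The layer weights `W_t` are seeded
random `(n+m) x (n+m)` matrices and are *untrained*: no loss is ever
defined for them. This makes `H_l` a random but reproducible projection of
neighbourhood-aggregated features — cheap, deterministic given the seed,
and sufficient for the downstream tree ensemble, which is insensitive to
rotations of its inputs. Weights are scaled by `1/sqrt(n+m)` so repeated
propagation neither explodes nor vanishes. The self-loops in `X + I`
guarantee positive degrees, so isolated nodes reduce to identity rows and
the normalised adjacency has spectral radius at most 1 (asserted in tests).

## Global embedding (biased walks + skip-gram)

Walks follow the second-order scheme with return parameter `p` and in-out
parameter `q`: arriving at `v` from `t`, a neighbour `x` is drawn with
unnormalised weight `alpha * w_vx` where `alpha` is `1/p` if `x = t`, `1`
if `x` is adjacent to `t`, and `1/q` otherwise. Defaults `p = 1.0`,
`q = 0.25` bias the walks outward (depth-first), which suits the sparse
bipartite topology: long excursions are what connect circRNAs to diseases
several hops away. Corpus defaults are the standard regime for this
embedding family: 10 walks per node of length 80, window 5, 5 epochs of
skip-gram with 5 negative samples (unigram^0.75 noise distribution, linear
learning-rate decay from 0.025). The walker and trainer are implemented in
C++ (single-threaded, own RNG) so the corpus and the embedding are
bit-reproducible from the seed. Isolated nodes produce no walks and keep
zero vectors, a stated convention rather than an error, so that fold
matrices with empty rows flow through the pipeline.

## Classification and evaluation

Pair `(c, d)` is represented by concatenating the two fused embedding rows
(width `4k`; an elementwise-product variant of width `2k` is available via
`pair_mode = "hadamard"`). Training pairs are all known associations plus
an equal-sized uniform sample of unknown cells (`neg_ratio = 1`); the
balanced design is what makes the thresholded metrics at 0.5 meaningful.
The default classifier is an extremely-randomized-trees ensemble (ranger
with `splitrule = "extratrees"`, one random split per candidate variable,
no bootstrap, 100 trees); random forest, logistic regression, k-NN, and
Gaussian naive Bayes are available for comparison experiments.

Cross-validation partitions the *positive pairs* (not nodes) into folds.
Per fold, every artifact — DS is ontology-only, but FS, CK, DK, Xc, Xd, the
auto-encoders, the CDHN, and both embeddings — is rebuilt from the training
positives alone. Held-out positives are scored against an equally sized
held-out negative sample drawn from cells unknown in the full matrix;
training negatives are drawn from cells unknown in the training matrix,
excluding all held-out pairs. The acceptance tests audit this directly:
rebuilding any fold's artifacts from an association matrix in which the
held-out positives never existed reproduces the CV-internal artifacts
bit-for-bit.

Metric conventions: AUROC uses the rank (Mann-Whitney) form with ties at
1/2 — the tests verify it equals trapezoidal ROC integration and an
independent ROC package to 1e-12; AUPR is step integration of the
precision-recall curve over distinct thresholds; MCC with any degenerate
confusion-matrix margin is 0 by convention, and precision with no positive
predictions is reported as 0. Report tables print 4 decimals. Ranked score
files break ties lexicographically by circRNA then disease identifier so
output is byte-stable.

## The synthetic benchmark

`generate_synthetic_dataset()` emulates the statistical shape of a curated
association resource: association scores are the product of two
non-negative gamma(2, 1) factor matrices of rank `latent_rank`, with the
top `n_pos` cells marked as known associations — a planted low-rank
structure that similarity-based link prediction should recover. The
disease ontology is a random recursive tree of bounded depth with ~15%
extra child-to-deeper-ancestor edges so some terms have multiple parents
and the max-over-parents recursion is genuinely exercised. The default
configuration (100 circRNAs, 30 diseases, 300 positives, rank 3, depth 4)
gives 10% density.

What passing on this fixture does and does not show: it demonstrates that
the pipeline recovers planted low-rank structure without leakage, that all
stages compose correctly, and that the fused scheme is competitive with
its ablations. It does not emulate the long-tailed degree distributions,
curation biases, or ontology depth of real resources, so fixture metrics
are not forecasts of benchmark performance. Problem sizes in the test
suite (5-fold, single repeat, `k = 16`) were chosen as the smallest
configuration at which the planted structure is reliably recoverable;
`repeats = 10` remains the default for real analyses.

## Determinism and numerical choices

One master seed fans out to every stochastic stage through a deterministic
hash of (seed, stage label), each derived seed a valid 32-bit integer.
Two full runs with the same seed produce bit-identical score files; this
is asserted in the acceptance tests. Identifier ordering is lexicographic
at load time so all matrices have a deterministic row/column order
regardless of input file order. Duplicate association rows collapse to a
single 1; cycles or self-loops in the ontology are hard errors that name
an offending cycle.

## Known limitations

* Diseases (or circRNAs) with no training associations are represented
  only through kernel fallbacks and zero walk vectors; predictions for
  fully isolated nodes are close to uninformative.
* The GCN layer is an untrained random projection by design; users wanting
  a learned propagation should treat `H_l` as a baseline.
* Classifier probabilities are not calibrated; use the ranking, not the
  absolute scores.
* No statistical test is provided for comparing schemes or classifiers;
  the paired fold design in `run_ablation()` supports such tests but the
  package does not perform them.
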