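---
title: "Methods: graph convolution-attention encoding with cross-view contrastive learning for microbe-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph convolution-attention encoding with cross-view contrastive learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Curated microbe–disease association databases record which microbes have
been experimentally linked to which diseases. The result is a sparse binary
matrix $A \in \{0,1\}^{n_m \times n_d}$ in which $A_{ij}=1$ is a confirmed
association and $A_{ij}=0$ means only that no association has been
reported — absence of evidence, not evidence of absence. The prediction
task is to rank the zero cells by how likely they are to be true but
undiscovered associations, so that laboratory effort can be focused on the
most promising candidates.

`gcatmd` implements a graph-neural-network pipeline for this task: Gaussian
interaction-profile (GIP) similarity networks, a stacked
graph-convolution + graph-attention (GCAT) encoder with a dual
feature-fusion module, a cross-view contrastive loss, and an inner-product
decoder, trained end to end with Adam.

## Model

### GIP similarity networks

The interaction profile $IP(m_i)$ of microbe $m_i$ is row $i$ of $A$;
$IP(d_j)$ is column $j$. Similarity is a Gaussian of squared profile
distance,

$$KM(m_i, m_j) = \exp\!\big(-\lambda_m \lVert IP(m_i) - IP(m_j)\rVert^2\big),$$

with the bandwidth normalized by the mean squared profile norm,
$\lambda_m = \lambda'_m \big/ \tfrac{1}{n_m}\sum_i \lVert IP(m_i)\rVert^2$
and $\lambda'_m = 1$ by default (identically for diseases). This is the
standard GIP convention: the exponent is dimensionless and the kernel
adapts to the overall density of the network. The kernel has unit diagonal,
values in $(0,1]$, and equals 1 exactly when two profiles coincide —
including two all-zero profiles, which the formula deliberately treats as
identical.

A binary similarity adjacency keeps pairs whose kernel value reaches a
threshold $t$ (default $0.4$). The adjacency diagonal is forced to zero
even though self-similarity is 1: the encoder's GCN normalization adds
explicit self-loops ($G + I$), and keeping both would double-count self
edges.

### The GCAT encoder

Three graphs are encoded independently, with no weight sharing:

* the **association graph**: the bipartite adjacency
  $G = \begin{bmatrix} 0 & A \\ A^\top & 0 \end{bmatrix}$ over
  $n_m + n_d$ nodes, with initial features
  $H^{(0)} = \mathrm{blockdiag}(KM, KD)$;
* the **microbe similarity graph** (adjacency $MA$, features the rows of
  $KM$);
* the **disease similarity graph** (adjacency $DA$, features the rows of
  $KD$).

Each encoder first projects its input features to dimension $F$ with a
learned matrix $W_{proj}$. One GCAT layer is then GCN propagation followed
by multi-head GAT aggregation:

$$H_{gcn} = \sigma_{gcn}\!\big(\tilde D^{-1/2}(G+I)\tilde D^{-1/2}\, H\, W\big),
\qquad
z_i = \sigma_{att}\!\Big(\tfrac{1}{K}\sum_{k=1}^{K}\sum_{j \in N_i \cup \{i\}}
\alpha_{ij}^{k}\, W_{att}^{k} h_j\Big),$$

where the attention coefficients are a per-node softmax over
$N_i \cup \{i\}$ of LeakyReLU-activated scores
$a \cdot [W_{att} h_i \,\Vert\, W_{att} h_j]$. The GAT output of layer $l$
feeds the GCN of layer $l+1$, yielding per-layer outputs
$Z^{(1)}, \dots, Z^{(L)}$ that a **dual fusion** module combines:

$$Z = \big(Z^{(1)} \Vert \cdots \Vert Z^{(L)}\big) W_a
 + \big(Z^{(1)} \odot \cdots \odot Z^{(L)}\big) W_b.$$

Concatenation preserves per-layer information; the Hadamard product
emphasises features the layers agree on.

Design choices worth stating, because the architecture sketch leaves them
genuinely open:

* **Layer stacking.** Only the first layer of each mechanism is forced by
  the definitions above; we define one GCAT layer as GCN-then-GAT with the
  GAT output feeding the next GCN. This matches the left-to-right data
  flow of the encoder diagram and produces exactly $L$ per-layer outputs
  for the fusion module.
* **Input projection.** A single explicit projection $W_{proj}$ to $F$
  before layer 1, plus per-layer $F \times F$ GCN weights. Reading the
  propagation rule as containing *both* a feature projection and a
  first-layer weight would double-project for no benefit.
* **Attention neighborhoods** include the node itself (standard GAT
  practice), which also guarantees a non-empty softmax on isolated nodes.
  Attention runs on the *binary* adjacency; the thresholding step
  binarizes explicitly, so kernel-weighted attention would re-introduce
  weights the threshold was meant to remove.
* **Activations.** $\sigma_{gcn} = \mathrm{ReLU}$,
  $\sigma_{att} = \mathrm{ELU}$, LeakyReLU slope 0.2 inside attention (the
  only activation the architecture pins down). All are configurable.
* **Initialisation.** Glorot-uniform with a run-level seed, the standard
  choice for GCN/GAT stacks.

### Cross-view contrastive loss

The association-graph encoder output is row-sliced at $n_m$ into microbe
and disease association-view embeddings $ZA_m$, $ZA_d$; the similarity
encoders give $ZS_m$, $ZS_d$. For each disease $i$ the pair
$(ZA_{d_i}, ZS_{d_i})$ is positive and every other node of either view is
a negative:

$$\ell(x_i, y_i) = \log
\frac{e^{\theta(x_i,y_i)/\tau}}
{e^{\theta(x_i,y_i)/\tau} + \sum_{k \ne i}\big(e^{\theta(x_i,x_k)/\tau} +
 e^{\theta(x_i,y_k)/\tau}\big)},$$

with $\theta$ cosine similarity and temperature $\tau$. Both entity losses
are symmetrized over anchors and implemented as *positive penalties*
(negated mean log-ratio); a printed variant of the microbe-side loss with
the opposite sign would reward misalignment and make the objective
degenerate, so both sides use the same sign. With a single node the loss
is exactly zero (no negatives). The loss is invariant to per-row positive
rescaling of the embeddings, a property the tests check.

### Decoder and training objective

Final embeddings concatenate the two views,
$Z_m = [ZA_m \Vert ZS_m]$, $Z_d = [ZA_d \Vert ZS_d]$, and the decoder is
$A' = \mathrm{sigmoid}(Z_m Z_d^\top)$, so every score lies strictly in
$(0,1)$. Training minimises

$$\mathcal{L} = \mathrm{BCE}(A'|_{\text{train edges}}) +
\lambda\, \mathcal{L}_{contrast}$$

by full-batch Adam. The BCE runs over the training positives plus an
equal number of negatives sampled once per split from the zero cells
(fixed across epochs); the contrastive term averages over *all* nodes, as
its definition requires. Full-batch training is deliberate: the graphs
here have a few hundred nodes, and determinism matters more than
throughput at that scale.

Because no automatic differentiation library is involved, the package
computes all gradients analytically — through the decoder, the contrastive
log-ratio, the fusion module, the attention softmax and the GCN stack —
and the test suite verifies them against central finite differences at
$10^{-4}$ relative tolerance on small seeded models. This check is the
single most load-bearing test in the package: everything downstream
(training curves, CV performance) depends on it.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `t` | 0.4 | kernel threshold for similarity edges (dimensionless, in (0,1)); lower adds noisy edges, higher isolates nodes |
| `F_dim` | 128 | embedding dimension |
| `L` | 3 | GCAT layers (receptive-field radius in hops) |
| `heads` | 2 | attention heads, averaged |
| `tau` | 1 | contrastive temperature; smaller sharpens the softmax over negatives |
| `lam` | 0.2 | weight of the contrastive penalty in the total loss |
| `lr`, `wd` | 1e-5, 1e-3 | Adam learning rate and L2 weight decay |
| `epochs` | 100 | fixed-length training (no early stopping) |
| `eps` | 1e-7 | clipping for logs and cosine norms; pure numeric safety |

The defaults are the operating point reported for the curated-database
setting this pipeline targets. The synthetic experiments in the tests and
the acceptance script deliberately raise `lr` to $10^{-3}$ (with 200–500
epochs), because the planted-block benchmark is smaller and farther from
convergence at the database-scale learning rate.

### Ablation variants

Every component can be switched off through `model_config(variant=)`:
similarity-networks-only (`sim_only`), association-network-only
(`asso_only`), no GCN stage (`no_gcn`), no attention stage (`no_gat`), no
contrastive term (`no_cl`), and all seven fusion combinations of
concatenation / sum / Hadamard product (`fusion_C` … `fusion_CSH`; dual
fusion is `fusion_CH`). The test suite trains every variant end to end, so
none is a dead configuration.

## The synthetic generator, and what passing tests mean

`generate_synthetic()` plants a block structure: microbes and diseases are
assigned round-robin to `n_blocks` groups, and each cell is Bernoulli
($p_{in}$ within-block, $p_{out}$ between). Round-robin (rather than
random) assignment makes expected edge counts exactly computable, which
the tests exploit. The generator emulates the clustering hypothesis that
motivates GIP similarity — entities in the same functional group share
interaction partners — and therefore exercises every stage of the
pipeline meaningfully. The benchmark configuration used by the tests and
the acceptance script is 200 microbes x 40 diseases, 4 blocks,
$p_{in} = 0.3$, $p_{out} = 0.02$.

It does **not** imitate real curated data in other respects: no
heavy-tailed degree distribution, no correlated reporting bias, no
multi-typed (increase/decrease) associations, and conditional independence
of cells given blocks. That last property has a consequence worth being
explicit about: given the training fold, the Bayes-optimal score of a test
cell depends only on its block pair, so the achievable held-out AUC of
*any* method is capped by the tie structure. For the benchmark
configuration, positives are within-block with probability
$600/720 = 0.833$ and sampled-negative zero cells with probability
$1400/7280 = 0.192$, giving an optimal AUC of

$$0.833 \times 0.808 + \tfrac12\,(0.833 \times 0.192 + 0.167 \times 0.808)
\approx 0.82.$$

The held-out AUC the tests and the acceptance script measure on this
benchmark should therefore be read against that ceiling, not against 1. A
high score demonstrates correct recovery of planted structure up to the
information limit — it does not by itself predict performance on real
curated databases, which have richer signal (and richer confounds).

## Evaluation protocol

Repeated k-fold cross-validation partitions the *positives* into folds;
negatives are sampled per split, balanced, disjoint between train and
test, and never overlapping a positive. For every fold the similarity
networks and the message-passing graph are rebuilt from the training
matrix only — the tests verify bitwise that flipping held-out cells
changes neither the kernels nor any training-epoch loss. AUC is computed
in the exact rank form (ties one half) and AUPR by step-wise
precision-recall integration (average precision), the common convention
for PR curves; trapezoidal PR integration would be slightly optimistic.
Precision/recall/F1 use a 0.5 cutoff, configurable, since the convention
is otherwise unstated. Summaries are reported as `mean (sd)` over folds.

Candidate ranking for a disease trains on *all* known associations
(nothing held out), scores that disease's zero cells, and returns the
top-k with ties broken by microbe index for stability.

## Numerical choices and degenerate inputs

* Attention softmax subtracts the row maximum over the support before
  exponentiation; isolated nodes attend only to themselves.
* Squared profile distances are clamped at zero to absorb floating-point
  cancellation, and the kernel diagonal is set to exactly 1.
* All-zero profiles receive similarity 1 to each other, as the formula
  dictates; an all-zero association matrix yields bandwidth 0 (with a
  warning) and a flat all-ones kernel.
* Scores are clipped to $[\varepsilon, 1-\varepsilon]$ inside losses only;
  gradients use the unclipped sigmoid, the standard stable form.
* De-duplication of input tables is exact-string after whitespace
  trimming, case-preserving (taxonomic names carry case); row/column order
  is radix-sorted so indices are locale-independent.
* Negative sampling is uniform over zero cells, once per split; per-epoch
  resampling would make the loss a moving target and break the bitwise
  determinism the tests rely on.

## Known limitations

* The contrastive term is computed over all nodes each epoch, which is
  $O((n_m + n_d)^2)$ — fine at a few hundred nodes, the intended scale.
* Binary associations only; evidence direction (increase/decrease) is out
  of scope.
* No early stopping or model selection: training length is part of the
  configuration, and on small dense problems long training can overfit
  the held-out fold (visible in the benchmark's gap to its ceiling).
* GIP similarity is the only similarity; ontology- or sequence-based
  similarities are deliberately not included.
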