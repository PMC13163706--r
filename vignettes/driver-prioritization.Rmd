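---
title: "Driver gene prioritization on bipartite gene-sample graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver gene prioritization on bipartite gene-sample graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most somatic mutations in a tumor are passengers; a small minority are
drivers that confer a selective growth advantage. Frequency-based driver
detection misses low-frequency drivers, and cohort-level scores ignore that
the same gene can play different roles in different patients. `driversage`
scores every *gene-sample pair*: it learns embeddings for genes and samples
on the bipartite graph that connects known driver genes to the samples they
are mutated in, decodes a per-sample driver probability for every mutated
gene, and only then aggregates the per-sample rankings into a cohort-level
driver list. Known drivers (e.g. an NCG-derived list) provide the
supervision; the value of the method lies in how it ranks the *remaining*
mutated genes and in the stability of the aggregated list.

## Preprocessing

Three inputs: a gene expression matrix, a binary somatic mutation matrix
(genes x samples), and a confidence-weighted PPI network. Confidence
filtering follows the source conventions (keep `>= 0.5` for CPDB-style
exports; `> 0.85`, via `strict_greater`, for STRING-style scores).

Expression is standardized per gene across samples, `z = (x - mu) / sigma`,
and an entry with `z >= 2` is *aberrant*. Three conventions needed fixing
where the rule leaves latitude:

* **sigma** is the population standard deviation (divide by n), with the
  sample convention available via `sd_type`. Flags can differ at the
  threshold boundary between the two conventions; with dozens of samples the
  difference is negligible.
* Genes with zero spread get `z = 0` everywhere: they carry no outlier
  signal and must never be flagged.
* Aberrance is one-sided (`z >= 2`) by default, matching the rule as stated;
  `two_sided = TRUE` flags `|z| >= 2` for analyses that treat silencing as
  signal.

A mutated gene is kept only if its mutation plausibly reaches downstream
expression: gene g survives iff in some sample j it is mutated *and* one of
its PPI neighbors is aberrant in that same sample j. This same-sample
coupling is the stricter of the two defensible readings (the cohort-level
variant is available via `coupling = "cohort"`); it is what makes the PPI
network matter, and it is the channel through which the network
negative controls act. Genes never mutated are excluded outright.

The retained genes define three matrices sharing index maps: `Xg` (binary
mutations, G x N; the gene node features), `Xs` (expression, N x G; the
sample node features), and the association matrix `A` with `A[i, j] = 1` iff
gene i is mutated in sample j and is a known driver. Gene order is
lexicographic and sample order follows the input columns, fixed before any
randomness so runs are reproducible.

## The model

**Encoder.** Two GraphSAGE layers on the bipartite graph. Per layer, each
side aggregates the degree-normalized mean of its neighbors on the other
side and adds its own transformed features:

    Hg' = ReLU(Hg W_self + D_g^-1 A Hs W_neigh)
    Hs' = ReLU(Hs W_self + D_s^-1 A' Hg W_neigh)

Zero-degree rows of the normalized adjacency stay zero (isolated nodes
propagate self features only) rather than receiving self-loops. The
aggregation adjacency is the association matrix `A` by default — the graph
the supervision lives on — with the full mutation matrix available through
`adjacency_source = "mutation"`. To keep held-out labels out of the
representation, the columns of `A` belonging to held-out samples are zeroed
during both training and inference; a held-out sample is embedded from its
expression alone.

Fixed-fan-out neighbor sampling (`sampling_size`, the usual grid being
5–30) sparsifies the adjacency *before* normalization, reconciling the
sampled formulation with the dense normalized one; the dense path is the
reference. Sampling is redrawn each epoch with the epoch index folded into
the seed, so runs remain deterministic.

**Bidirectional cross-attention.** A single-head scaled dot-product
attention in each direction re-weights the encoder output: genes query
samples (`softmax(G Wq (S Wk)' / sqrt(dk)) · S Wv`, then an output
projection with bias and ReLU), and symmetrically samples query genes. The
two directions use separate Q/K/V parameter sets by default — reusing one
set across transposed roles would force `d = dk` — with `share_qkv = TRUE`
available. Q/K/V projections carry no bias, and there are no residual
connections. This stage is what lets the relevance of a sample to a gene be
context-dependent instead of fixed by the adjacency.

**Decoder and loss.** Both sides pass through a plain linear projection
(no activation) and are compared by cosine similarity mapped to a
probability, `P = (cos + 1) / 2`; a zero-norm embedding has cosine defined
as 0, hence probability 0.5. Training minimizes a weighted binary
cross-entropy over the training-sample columns: positives (driver,
mutated-sample pairs) are up-weighted by `beta`, which defaults to the
negatives-to-positives ratio inside the mask — the standard imbalance
heuristic, here typically 10–20. The loss uses a scalar class weight rather
than per-pair weights. Probabilities are clipped to `[1e-7, 1 - 1e-7]` to
keep the logs finite.

**Optimization.** Adam (lr `1e-3`, 200 epochs by default), full-batch — the
cohorts fit in memory at desk scale. Weights use seeded Glorot-uniform
initialization; biases start at zero. Gradients are computed by a
hand-derived reverse pass through the whole architecture (attention softmax
and cosine included) and are verified against central finite differences in
the test suite to a relative error of 1e-4. Training with the same seed is
bit-reproducible; a non-finite loss aborts with the epoch number.

## Ranking

Per sample, only the genes mutated in that sample are candidates; they are
ordered by predicted score (ties broken by gene symbol so lists are stable)
and the top `ceiling(0.5 * m)` of the m mutated genes are kept. The ceiling
convention means a sample with a single mutated gene still votes.

**Exponential Pairwise Voting (EPV).** A gene at rank r in a sample votes
with strength `w = exp(-alpha * (r - 1))`. For every ordered pair (gi, gj)
and sample: if gi is listed and either outranks gj or gj is absent, gi's
strength is added to gi's *win* total and to gj's *loss* total. The final
score is `P = win / (win + loss)` (0 for a gene never compared), ranked
descending with ties broken by win then symbol. The implementation uses the
closed form — at rank r a gene beats `U - r` opponents, where U is the
universe size — and the test suite checks exact agreement with a brute-force
enumeration of all ordered pairs.

The voting **universe** defaults to the genes appearing in at least one
candidate list: a gene outside every list scores 0 regardless, but the
universe size does change the absent-opponent wins of listed genes, so the
"all retained genes" variant is exposed via the `universe` argument.

`alpha` defaults to 0.5; cohort-specific tuned values (0.9 breast, 0.3 lung
adenocarcinoma, 0.6 prostate) are available through `default_alpha()`. At
`alpha = 0` voting is unweighted, which is exactly the **Condorcet
baseline**: `condorcet_rank()` implements pairwise majorities with unit
votes, ranked by Copeland-style win proportion — "standard Condorcet" is
underdetermined for incomplete ballots, and Copeland scoring is our stated
interpretation — and is kept as an independent implementation so the two
routes cross-check each other.

During cross-validation, each sample's candidate list comes from the fold
in which it was *held out*, so the final aggregated ranking never uses a
list produced by a model that saw that sample's labels. Per-fold rankings
(EPV over only that fold's test samples) feed the reported top-K
precision/recall/F1, averaged across folds.

## Evaluation and negative controls

`kfold_split()` partitions samples by seeded shuffle and contiguous
chunking (sizes differ by at most one). Top-K metrics are the usual
`precision = hits / K`, `recall = hits / |truth|`, F1 their harmonic mean.

Two network negative controls mirror the robustness analysis:
`edge_shuffle()` performs degree-preserving double-edge swaps (self-loops
and duplicates rejected; the degree of every node is exactly preserved), and
`node_shuffle()` permutes gene labels over the intact topology, destroying
the correspondence between a gene's features and its network position. Three
shuffled replicates per control type is the default protocol in the
acceptance analyses. Because the PPI network enters the method only through
the expression-impact filter, these controls act by changing which genes
survive preprocessing — which is precisely the claim they test.

## The synthetic cohort generator

`simulate_cohort()` plants drivers in a random network: drivers mutate at
`driver_mut_rate`, passengers at `passenger_mut_rate`, and when a driver is
mutated in a sample each of its network neighbors has that sample's
expression shifted by `neighbor_shift` (in units of the per-gene noise sd,
so the shift is directly comparable to the z >= 2 aberrance threshold).
Defaults — 200 genes, 50 samples, 20 drivers, rates 0.3 / 0.05, shift 3,
Erdős–Rényi with edge probability 0.04 (mean degree about 8, a realistic
local density for a confidence-filtered PPI neighborhood at this scale) —
define a strong-signal cohort in which the filter should retain essentially
all drivers and roughly a third of mutated passengers. A Barabási–Albert
option provides degree heterogeneity for shuffle-control studies.

What the generator does *not* emulate: real mutation spectra
(hypermutators, mutual exclusivity), expression distributions
(heteroscedastic counts, batch effects), or network modularity. Passing
results on these fixtures demonstrate correctness of the machinery and
recoverability of a planted signal, not performance on real tumors. Note
also that at these mutation rates the expression-impact filter is close to
saturated for drivers (a driver mutated in ~15 of 50 samples almost always
has some aberrant neighbor somewhere), so label-permuted networks degrade
recovery only moderately; on real cohorts, where genes are mutated in far
fewer samples, the filter is much more selective and the negative controls
bite harder.

## Problem sizes and numerical choices

The test suite exercises reduced models (widths 5–16, 30–120 epochs) on
small cohorts (40 genes x 12 samples, with a denser network so the filter
retains a workable gene set), and the acceptance analyses run the full
default configuration (widths 64, 200 epochs) on the default 200 x 50
cohorts — 5 cohort seeds for driver recovery against three node-shuffled
replicates each, and the 8-way ablation (the two ranking strategies reuse
the same fitted models, so the 8 configurations need 4 cross-validated
fits). On one CPU a full 5-fold pipeline takes roughly 10-15 seconds.

Numerical conventions collected in one place: population sigma; `z = 0` for
constant genes; zero rows preserved by row normalization; ReLU everywhere
the architecture specifies an activation, nothing on the final projections;
attention softmax uses per-row max subtraction; cosine clipped to
`[-1, 1]` against rounding; loss clipping `1e-7`; tie-breaks are score
descending, then win descending, then gene symbol ascending, everywhere a
list is produced.

## Limitations

On the strong-signal synthetic fixtures the pipeline operates near its
performance ceiling, and there the cross-attention stage adds no measurable
headroom over feeding the encoder straight to the decoder — occasionally it
costs a single top-K gene to estimation variance. The stage targets
heterogeneous cohorts where gene-sample relevance genuinely varies; a
near-ceiling planted-driver fixture cannot demonstrate that benefit, and we
report this rather than adjust the fixture.

Supervision is transductive over genes: a known driver's label reaches the
model through every training fold, so cross-validation here measures
generalization across *samples*, not the discovery rate of unlabeled
drivers. The loss uses one scalar class weight; per-pair weighting is not
implemented. Single-head attention only. No early stopping — the epoch
count is a fixed budget. Expression enters raw (not z-scored) as sample
features, matching the matrix definitions; rescaling experiments are left
to the user.
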