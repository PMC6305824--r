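---
title: "Differential connectivity analysis with shrinkage Gaussian graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential connectivity analysis with shrinkage Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgnet)
```

## The question this package answers

Two tissues — say normal colorectal mucosa and adjacent tumour — can share
most of their differentially expressed genes and still differ radically in
how those genes are *wired*. A gene whose expression barely changes can
move from the periphery of the co-regulation network to its centre, or
vice versa. `dcgnet` formalises one specific operationalisation of this
idea: a **differentially connected gene (DCG)** is a gene that sits in the
top betweenness-centrality fraction of the cancer network but not in the
normal network's top fraction — a cancer-specific hub.

The pipeline has five stages:

1. **Differential expression per dataset.** For each gene, the log2
   fold-change is the difference of condition means (the data are assumed
   already on the log2 scale, e.g. RMA-normalized arrays), the p-value
   comes from a per-gene Welch two-sample t-test, and multiplicity is
   handled with Benjamini–Hochberg. A gene is called when its fold-change
   is strictly above `fc_hi = 2.0` or strictly below `fc_lo = 0.5` *and*
   its adjusted p is strictly below `alpha = 0.01`.
2. **Mutual DEGs.** The intersection of the per-dataset DEG sets defines
   the gene universe for the network stages, emulating a multi-series
   meta-analysis in which only reproducible calls survive.
3. **Per-condition network inference.** For each condition separately, a
   Gaussian graphical model is estimated by analytic shrinkage: the sample
   correlation matrix $R$ is replaced by
   $R^\* = (1-\lambda^\*) R + \lambda^\* I$ with
   $$\lambda^\* = \frac{\sum_{i<j} \widehat{\mathrm{Var}}(r_{ij})}
                       {\sum_{i<j} r_{ij}^2}$$
   clipped to $[0,1]$, where $\widehat{\mathrm{Var}}(r_{ij})$ is the
   unbiased empirical variance of the per-sample cross-products of the
   standardized data. Partial correlations follow from the inverse
   $\Omega = (R^\*)^{-1}$ via
   $\rho_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\,\omega_{jj}}$. All
   $\binom{p}{2}$ edges are ranked by $|\rho_{ij}|$ and the top
   `k = 1500` are retained.
4. **Centrality.** The retained edges form a simple undirected, unweighted
   graph over the full universe (isolated genes kept). Exact betweenness
   $b(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ is computed by
   Brandes' algorithm (via igraph), unnormalized — the next stage depends
   only on ranks, which normalization cannot change.
5. **Selection.** In each condition the top `q = 0.40` fraction —
   $\lfloor q N \rfloor$ genes — is selected by betweenness rank. Genes in
   both top sets (the overlap) are removed; the remaining cancer-top genes
   are the DCGs. With a 154-gene universe the cut keeps 61 genes per
   condition, and a 21-gene overlap leaves 40 DCGs.

## Parameters that matter

| parameter | default | units / domain | why this default |
|---|---|---|---|
| `fc_hi`, `fc_lo` | 2.0, 0.5 | fold-change | two-fold change in either direction, strict inequalities |
| `alpha` | 0.01 | adjusted p | strict BH threshold |
| `k` | 1500 | edges | covers a ~150-gene universe while keeping the graph sparse |
| `q` | 0.40 | fraction | top-40% betweenness cut; selection is reported to be insensitive in the 10–40% range |
| `partial_corr_magnitude` | 0.3 | partial correlation | a moderate, estimable conditional dependence |
| `baseline_mean` | 8.0 | log2 a.u. | typical microarray intensity scale; irrelevant to every downstream statistic |

All threshold comparisons are strict (`>`, `<`), matching the convention
the defaults were taken from. The count at the fractional cut is
$\lfloor qN \rfloor$ (truncation, not rounding): $0.40 \times 154 = 61.6$
keeps 61.

## The synthetic world

Because the real multi-series data cannot be bundled, every stage is
validated against a generator with known ground truth. The generator
draws log2 expression from a multivariate normal whose **precision
matrix** has planted sparse support — the regime in which GGM partial
correlations are exactly the conditional-dependence structure, which
makes structure recovery a well-posed test.

A `PrecisionModel` starts from a unit diagonal; each hub receives
`hub_degree` spokes among non-hub genes and `background_edges` extra
random pairs are added, with off-diagonals set so the implied partial
correlations equal $\pm$`partial_corr_magnitude` (random signs). If the
minimum eigenvalue is at or below the floor 0.05, the diagonal is
inflated once by a constant: this preserves the support exactly and
attenuates every planted partial correlation by the same factor
$1/(1+\delta)$ — planted magnitudes are exact whenever the raw pattern
already clears the floor, and uniformly shrunk (never rewired) otherwise.

Two-condition studies share the shared-hub skeleton, the background edges
and all edge signs between conditions; only condition-specific hub edges
differ. Two details deserve emphasis:

* **Background edges avoid condition-specific hubs.** Background
  structure is common to both conditions, so letting it touch a
  "cancer-only" hub would give that gene genuine normal-network
  connectivity and contradict its own definition.
* **Per-gene noise variance is 1** on the log2 scale (precision diagonal
  1 before inflation); heterogeneous variances can be configured but are
  off by default. Planted differential-expression shifts are at least
  1 log2 unit so they clear the two-fold threshold in expectation.

The generator emulates: several independent datasets sharing one truth
(differing only in sampling noise and sample sizes), condition-specific
and shared hubs, and planted expression shifts. It does **not** emulate
probe-level artefacts, RMA normalization, batch effects, heavy-tailed
noise, or count data. A green recovery test therefore establishes that
the pipeline recovers conditional-dependence hubs from Gaussian data of
realistic size — not that it is robust to array-specific artefacts.

## Numerical choices and edge cases

* **Shrinkage intensity.** Genes are centered and scaled per condition
  before estimation (this makes the cross-product variance formula
  well-defined). A zero denominator $\sum r_{ij}^2 = 0$ yields
  $\lambda^\* = 1$ by convention; fewer than 3 samples is an error.
* **Degenerate tests.** A gene with zero variance in both groups gets
  p = 1 when the group means are equal and p = 0 otherwise, rather than
  crashing on a 0/0 statistic.
* **Tie-breaks.** Edge ranking breaks $|\rho|$ ties lexicographically on
  the (sorted) gene-id pair; node ranking breaks betweenness ties
  lexicographically on the gene id, with dense ranks. Ties at the
  $\lfloor qN \rfloor$ boundary are resolved by this deterministic order,
  never by expanding the selection. All outputs are consequently
  bit-reproducible across platforms.
* **Disconnected graphs.** Unreachable pairs contribute nothing to
  betweenness; isolates score 0 and stay eligible (at the bottom) for the
  fractional cut, which is applied over the *full* universe — only this
  reproduces 61 from 154.
* **Seeds.** One global seed fans out to stage seeds as
  `seed * 100 + offset`, so the truth construction and each condition's
  sampling are independently reproducible; all analysis stages after the
  generator are seed-free and deterministic.

## Design decisions where the design was open

* **Welch t instead of a moderated t.** The package's contribution is the
  connectivity analysis, not the DE test; re-implementing empirical-Bayes
  variance shrinkage would wholesale-import a second published method.
  `call_degs()` accepts externally computed p-values, so a moderated-t
  table can be substituted without touching the rest of the pipeline.
* **"Adjusted p" means Benjamini–Hochberg**, the de facto default of
  standard microarray DE tooling.
* **Edge ranking by $|\rho|$.** The classical shrinkage-GGM tool ranks
  edges by posterior probability from a mixture model fitted to the
  partial-correlation distribution; for a monotone null the two orderings
  agree at the top of the list, and the local-fdr machinery is out of
  scope. This is a deliberate simplification.
* **DCG direction.** DCGs are cancer-top minus overlap — not the
  symmetric difference. The normal-specific complement is computed and
  reported, but not labelled DCG.
* **`gene_filter = "all"`.** The pipeline normally restricts networks to
  the mutual-DEG universe and aborts if that universe is empty. Null
  studies (identical generative models, no shifts) are exactly the case
  where it *should* be empty, so calibration experiments run with
  `gene_filter = "all"`; the option exists for that reason and for users
  who want connectivity analysis decoupled from DE filtering.
* **Recovery experiments fix the planted truth.** Recovery frequency is
  assessed over independent expression draws from one fixed planted
  model (`make_multi_dataset`), the standard design for a recovery
  experiment: the truth layout is part of the stated world, not a
  nuisance to marginalize over. Regenerating the truth every run mixes
  layout lottery into the frequency and is reported in the test suite's
  design notes rather than asserted.
* **Enrichment statistic.** Over-/under-representation uses the exact
  hypergeometric tails (`p_over = P[X >= k]`, `p_under = P[X <= k]`) with
  BH q-values across the collection. Rank-combined web-service scores and
  network-crosstalk statistics are intentionally not reimplemented; term
  lists produced by such services are not reproduction targets.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
res <- make_two_condition_study(two_condition_params(
  n_genes = 30L, n_normal = 200L, n_cancer = 200L,
  n_shared_hubs = 4L, n_cancer_hubs = 1L, n_normal_hubs = 0L,
  hub_degree = 6L, background_edges = 12L,
  de_genes = setNames(rep(2, 30), sprintf("g%04d", 1:30)), seed = 1L))
bundle <- run_pipeline(list(res$study),
                       pipeline_config(k = 60L, q = 0.40))
bundle
res$truth$cancer_specific_hubs %in% bundle$dcg$dcgs
```

## Known limitations

* Networks are unweighted and undirected; no edge-significance model, no
  orientation, no dynamic rewiring.
* The Welch test assumes per-gene independence across genes for BH to
  control FDR in the usual sense; strong co-expression makes BH
  conservative-on-average but not adaptive.
* The q-cut counts are only meaningful relative to a fixed universe;
  comparing DCG sets across universes of different sizes is not
  supported.
* Identifier matching is case-sensitive after whitespace stripping; no
  alias resolution is attempted.
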