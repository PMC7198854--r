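---
title: "Driver gene prioritization with a degree-biased random walk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver gene prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverwalk)
```

## The problem and the model

Most mutations in a tumor are passengers; the genes whose alteration actually
confers a growth advantage — drivers — are a small minority, and several of
them are rarely mutated across a cohort. Frequency-based calling misses those,
which motivates network propagation: expression signal diffuses over an
interaction network so that genes central to perturbed neighborhoods
accumulate score even when their own mutation count is modest.

`driverwalk` implements one such propagation scheme with three distinctive
choices:

1. **A cancer-specific network.** Rather than walking on a generic
   interactome, the reference network is filtered down to *differential
   coexpression* support: a directed reference edge survives only if its gene
   pair is significantly correlated (Pearson, `p < 0.05`) in exactly one of
   the tumor/normal conditions. Pairs significant in both conditions reflect
   housekeeping co-regulation; pairs significant in neither carry no signal;
   both are removed.
2. **A degree-biased transition rule.** A random walker at node `i` prefers
   out-neighbors that are themselves highly connected: the transition
   probability to neighbor `j` is proportional to `j`'s out-degree, mixed
   with a uniform teleportation term `(1 − α)/n` (default `α = 0.85`). This
   encodes the assumption that information flows preferentially through
   hubs.
3. **A centrality-weighted restart on seed genes.** The restart (probability
   `1 − d`, default `d = 0.85`) jumps to known cancer genes, each weighted by
   the mean of its normalized betweenness and Katz centralities, so
   topologically central seeds attract more of the walk.

After convergence, only mutated genes are reported: the walk scores the whole
network, but candidacy requires at least one somatic event in the cohort —
an SNV, or a GISTIC copy-number call of ±2. Low-level calls (±1) are
deliberately excluded; they are too common to be informative.

## Parameters

| Parameter | Default | Role |
|---|---|---|
| `threshold` | 0.05 | Coexpression significance level, applied strictly (`p < 0.05`); raw p-values, no multiplicity correction — the edge rule is a screen, not an inference. |
| `alpha_mix` (`α`) | 0.85 | Weight of the degree-biased term in each transition row; the complement is uniform teleportation. |
| `d` | 0.85 | Walk damping; `1 − d` is the restart probability. The classical PageRank value. |
| `eps` | 1e-8 | Stopping threshold on the squared-difference sum `Σ(r(t+1) − r(t))²` (used exactly in that form, not its square root). |
| `max_iter` | 1000 | Iteration cap; in practice the walk converges in tens of iterations. |
| `katz_fraction` | 0.85 | Katz damping expressed as a fraction of the convergence limit `1/λ₁`. |

All scores are probabilities: the transition matrix is row-stochastic by
construction, and if `r(0)` and the prior each sum to 1 then so does every
iterate, which the tests assert per iteration.

## Readings of the formulas that required a decision

Several points in the walk's definition admit more than one reading; the
package fixes them as follows, and records the relevant settings in each
run's metadata sidecar.

* **Teleportation reaches every column.** The `(1 − α)/n` term is added to
  all entries of a row, neighbors and non-neighbors alike. This is the only
  reading under which rows sum to exactly 1 (`α + n·(1−α)/n = 1`), and it
  mirrors PageRank teleportation.
* **The uniform branch covers two degeneracies.** A row falls back to `1/n`
  when the sum of its out-neighbors' out-degrees is zero — which happens both
  for dangling nodes (no out-neighbors) and for nodes whose out-neighbors are
  all sinks. Both cases zero the same denominator, so both take the same
  branch.
* **Degree means out-degree.** On a directed graph "degree" is ambiguous;
  the walk explicitly consumes out-degrees (row sums of `A`), and that is
  what `out_degree()` computes.
* **Boundary significance.** `p = 0.05` exactly is *not* significant, in
  either condition, making the XOR differential rule self-consistent.
* **Two-sided t test.** The Pearson p-value uses the t transform
  `t = r·sqrt((m−2)/(1−r²))` with `m − 2` degrees of freedom, two-sided —
  the conventional test; strong negative correlation is evidence of
  coexpression structure too.
* **Zero-variance genes.** Their correlations are undefined; they are
  flagged `NA` and treated as never significant, since they carry no
  coexpression evidence.
* **Betweenness on the directed graph.** Shortest paths are directed, with
  the printed normalization `2/(n²−3n+2)` (the undirected convention)
  applied verbatim; constant factors are immaterial because the prior is
  renormalized downstream. An `bc_undirected` escape hatch computes the
  undirected variant instead. Unreachable pairs contribute 0.
* **Katz closed form.** `KC = (I − α_K Aᵀ)⁻¹·1` is the k-from-0 walk-count
  series (its entries are ≥ 1); the package implements the closed form by a
  dense linear solve and the tests check it against truncated power series.
  Since no fixed numeric damping is universally convergent, `α_K` is
  parameterized as a fraction of `1/λ₁` so convergence holds by
  construction. For a 0/1 adjacency `λ₁` is either 0 (acyclic) or ≥ 1, so
  eigensolver noise on nilpotent matrices is clamped to 0.
* **Prior normalization order.** Each centrality is first normalized to sum
  1 over *all* network genes, then averaged per seed, then the seed vector
  is renormalized. The alternative (normalizing over seeds only) differs
  only by a constant per centrality and is not exposed; the chosen order
  keeps the two centralities on a common scale before averaging.
* **r(0) matters only transiently.** For `d < 1` the stationary point is
  unique, so the start vector cannot change the ranking; the normalized mean
  tumor expression start is still honored so iteration counts are faithful.
  Genes in the network but absent from the tumor expression are a hard
  error rather than silently imputed — the start vector would otherwise be
  arbitrary.
* **Deterministic ties.** Every downstream sort breaks score ties by gene
  identifier ascending, making outputs byte-identical across reruns.

## The synthetic study condition

The generator (`fixture_config()`, `simulate_fixture()`) emulates exactly the
structure the method assumes, with defaults that define the standard study
condition used by the tests and the acceptance script:

* 300 genes, 150 tumor + 150 normal samples;
* a directed preferential-attachment reference network (3 out-links per
  node, orientation chosen so accumulated attachment yields heavy-tailed
  *out*-degree), with each planted module additionally a directed clique;
* 3 planted driver modules of 10 genes whose tumor-condition expression
  shares a per-sample factor, `x = sqrt(ρ)·f + sqrt(1−ρ)·ε` with `ρ = 0.7`
  (pairwise correlation exactly `ρ` in expectation); normal condition is
  independent noise; both matrices are shifted affinely to be non-negative,
  which leaves every correlation untouched;
* driver mutation rate 0.3 per sample against a background of 0.02, with
  30% of driver events emitted as ±2 CNV calls rather than SNVs (so the
  GISTIC rule is exercised) and 5% neutral ±1 calls sprinkled in;
* seeds are half of the planted drivers plus 10 non-driver decoys; the
  benchmark is the full planted-driver set.

Unstated knobs (attachment density, decoy count, CNV share) were fixed once
at values typical of cohort data of this size and are not tuned per test.

What the generator does **not** emulate: library-size and GC effects, RSEM
quantification quirks, heavy-tailed marginal expression, correlated mutation
processes (mutual exclusivity, hypermutators), or annotation noise in seed
and benchmark sets. A pass on the fixture therefore demonstrates that the
machinery recovers planted signal under the method's own assumptions — not
that those assumptions hold on any particular cohort.

## Numerical and testing notes

Correctness is established against independent oracles rather than
re-derivations of the same code path: explicit-sum Pearson with the t CDF;
shortest-path counting by matrix powers for betweenness; truncated series for
Katz; a dense linear solve `(1−d)(I − dPᵀ)⁻¹·prior` for the walk's fixed
point. Problem sizes follow the quantity being checked: exhaustive oracles
run at `n ≤ 15` (betweenness) and `n ≤ 50` (Katz), stochastic-matrix and
walk contracts at `n ≤ 200` over dozens of random graphs, and the end-to-end
recovery experiment at the standard 300-gene condition with 100-permutation
null references — sizes at which every property is measurable with
comfortable margins while the whole suite stays quick to run.

Two calibration checks tie the edge screen to its nominal level: under a
pure-null fixture the differential-pair rate concentrates at
`2·0.05·0.95 = 0.095`, and in the planted-block fixture the per-edge
recovery probability is the probability the pair stays null in normal tissue
(0.95 — tumor-side significance is essentially certain at `ρ = 0.7`,
`m = 150`); the corresponding tests assert the Monte-Carlo mean within three
binomial standard errors of those values.

## Limitations

* Dense matrix algebra throughout: appropriate for desk-scale networks (up
  to roughly 10⁴ nodes after differential filtering), not for full
  interactomes without sparsification.
* The mutation filter is cohort-level (mutated anywhere), matching the
  method's population focus; per-patient rankings are out of scope.
* Gene identifiers are opaque case-sensitive strings; no symbol aliasing or
  cross-database ID mapping is attempted, so inputs must share a vocabulary.
* Only Pearson coexpression is offered — no Spearman, partial correlation,
  or soft-thresholding network variants.
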