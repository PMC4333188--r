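---
title: "Adaptive k-core decomposition for PPI prediction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive k-core decomposition for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreppi)
```

## The problem and the model

Experimentally derived protein–protein interaction (PPI) networks are
incomplete, and the missing edges are not uniformly distributed: proteins
that assemble into complexes interact far more often than random pairs, so
within-complex interactions are systematically under-reported. Complex
detection algorithms (MCODE, COACH, NDComplex and relatives) locate the
dense regions of the network, but their output is heterogeneous — a
"complex" may consist of several weakly bridged subnets, or of loosely
connected proteins that should not all be predicted to bind.

`coreppi` therefore interposes a decomposition step between detection and
prediction. For one complex with member set $V$:

1. **Seed.** Find a complete subnet of $k$ nodes (a $k$-clique) among the
   remaining members. In this literature that seed is called a *k-core*,
   which collides with the graph-theoretic k-core (maximal subgraph of
   minimum degree $k$); the package uses clique semantics throughout and
   keeps the field's name only in prose.
2. **Greedy extension.** Repeatedly take the remaining member with the
   largest number of connections into the current subnet and append it if
   the extended density
   $$\mathrm{density} = \frac{2m}{n(n-1)}$$
   ($n$ nodes, $m$ induced edges) remains *strictly* greater than a
   threshold $\lambda$. Extension stops at the first rejection, or when the
   best candidate has no connection into the subnet.
3. **Prune and repeat.** The accepted subnet is removed from the complex
   and the procedure restarts on the residue.
4. **Abandon.** When no $k$-clique remains, the residue is discarded:
   loosely connected members never contribute predictions.

Every retained subnet is then an evidence unit: each unordered member pair
absent from the network becomes a predicted interaction. Because detectors
can emit overlapping or duplicated complexes, a pair may be predicted by
several subnets; its repetition count $h$ (1 + number of additional
predicting subnets) is tracked, and `filter_by_repetition(pred, 2)`
extracts the repeatedly predicted, higher-confidence subset.

The method is adaptive in the sense that nothing is assumed about the
number, size or shape of the complexes — the same $k$ and $\lambda$ handle
tight cliques, bridged multi-module complexes, and sparse aggregates (which
simply dissolve into abandoned residue).

## Parameters

* **k (seed clique size, integer ≥ 2, no default).** The granularity of
  decomposition: subnets smaller than $k$ can never be retained. Small $k$
  (4) suits detectors that emit many small-to-medium complexes; a larger
  $k$ (7) is appropriate when complexes are large and internally dense, as
  larger seeds keep the greedy extension anchored in genuinely dense
  regions. It is deliberately a required per-run argument rather than a
  default, because the right value tracks the scale of the detector's
  output.
* **λ (density threshold, in (0, 1], default 0.7).** A subnet keeps growing
  only while its density strictly exceeds λ. Densities above 0.5 are
  conventionally "dense" for PPI subnets; 0.7 is the usual
  quality/quantity trade-off. Raising λ toward 0.9 yields fewer, more
  reliable predictions; lowering it toward 0.5 the converse.
* **min_h (repetition filter, integer ≥ 1, default 1).** 1 keeps
  everything; 2 implements the "predicted more than once" adjustment. It
  is exposed generically because intermediate repetition levels are
  informative; the run report always includes the full h histogram.
* **mode (seed selection).** `"deterministic"` picks the lexicographically
  smallest k-clique; `"random"` draws uniformly from the enumerated
  k-cliques using R's RNG. Deterministic is the default so that runs are
  reproducible without seed bookkeeping; random mode reflects the original
  formulation ("a k-core is determined randomly") and is appropriate when
  exploring the variability of the decomposition.

## Numerical and procedural choices

* **Strict density comparison.** A candidate is accepted only if the
  extended density is $> \lambda$, never $\geq$. The boundary case matters:
  a K4 plus a node with one connection has density exactly
  $2\cdot7/(5\cdot4) = 0.7$ and is rejected at the default threshold, which
  is what keeps bridged twin modules apart.
* **Ties in greedy extension** (several candidates with the same maximal
  connection count) are broken by the lexicographically smallest
  identifier. The choice is arbitrary but fixed, making runs reproducible.
* **First rejection stops the extension** rather than trying the
  next-best candidate. A rejected node's connection count cannot improve,
  and stopping outright follows the procedure's plain reading; the
  rejected node stays in the residue pool and may join a later subnet.
* **Candidate pools are complex-local.** Seeds are searched and extensions
  drawn only among the complex's remaining members, never the whole
  network; decomposition of one complex is independent of all others.
* **Clique enumeration is exhaustive** over the induced subgraph (via
  igraph). Detected complexes are small — tens of nodes — so enumeration is
  cheap; the candidate set shrinks by at least $k$ per pruning round, so
  the loop runs at most $\lfloor n/k\rfloor$ times.
* **Degenerate inputs.** Complex members absent from the network are
  ignored with a warning (detector and network snapshots often differ);
  density is undefined below two members and raises an error; an empty
  prediction set is a valid result (a complete complex predicts nothing)
  and evaluation functions that divide by the prediction count refuse it
  explicitly. In the likelihood ratio, $P_-=0$ with $P_+>0$ yields `Inf`
  with a warning, and $P_+=P_-=0$ yields `NaN`.
* **Overlap-ratio rounding** is half-up to integer percent, matching how
  such tables are conventionally reported; annotation hit ratios are
  conventionally reported to two decimals. Exact values are always
  returned alongside.

## What the synthetic generator emulates — and what it does not

`simulate_ppi()` plants dense complexes on a sparse background: each
within-complex pair is an edge with probability `p_within` (default 1),
each remaining pair with `p_background` (default 0.02), consecutive
complexes can share members (`overlap_fraction`), and per complex a
fraction `holdout_fraction` (default 0.1) of realized edges is removed and
recorded as ground truth. Defaults — five complexes of sizes 8–12 on 150
background proteins — keep the within/background density contrast of real
complex-bearing interactomes at a size where exhaustive verification is
possible. The gold-standard positive set is the held-out edges plus a
quarter of the kept within-complex edges; the negative set samples
cross-complex non-edges, the natural analogue of a
different-compartment negative set; the reference interactome is the full
realized within-complex edge set.

Passing tests on this generator demonstrates that the machinery is correct:
seeds are genuine cliques, subnets respect the density bound, predictions
are exactly the missing within-subnet pairs, h counts add up, and held-out
edges are recovered far above a size-matched random baseline. It does *not*
demonstrate performance on real interactomes. Real data have heavy-tailed
degree distributions, correlated false negatives, and detector-specific
complex biases, none of which are modeled; with `p_within = 1` every
prediction is a held-out edge by construction, so precision 1 on the
benchmark is a property of the idealization, not a performance claim. The
generator's role is verification and relative comparison (λ sweeps,
h filtering, baselines), not absolute benchmarking.

One consequence of the generator's geometry is worth noting: its
gold-standard negative set consists of cross-complex pairs, while the
pipeline only ever predicts within-complex pairs, so $P_-$ is structurally
zero and the likelihood ratio is infinite on the benchmark. The estimator
is therefore exercised with finite inputs in the test suite, and the
benchmark reports the raw hit counts instead.

## Design decisions that were genuinely open

* **Residues attached through non-members.** A dense module and a sparse
  residue can be connected through a protein that is not a complex member;
  because candidate pools are complex-local, such bridges are invisible to
  the extension and the residue is abandoned. A bridge that *is* a member
  is subject to the density test like any other candidate — at λ = 0.7 a
  single-edge attachment to a 5-clique would be accepted (density 0.733),
  which is the rule's intended behaviour, not a corner case to special-case
  away.
* **h counting per (complex, subnet) source.** Subnets within one complex
  are node-disjoint and cannot repeat a pair, so increments effectively
  come from distinct complexes; recording the full provenance keeps the
  accounting invariant ($\sum h$ = total emitted predictions) checkable.
* **Problem sizes in tests.** Property tests run on hundreds of random
  graphs of up to 15 nodes — the scale where exhaustive subset enumeration
  is a usable oracle — and the recovery studies use 20 generator seeds at
  the default sizes. These sizes were chosen so the whole suite verifies
  the method's claims exhaustively where exhaustiveness is possible.
* **CLI as a thin shell.** The launcher only dispatches to `ppi_cli()`;
  every behaviour is a package function, so the entire surface is testable
  in-process.

## Known limitations

* Standard graph-theoretic k-core peeling, weighted or directed edges, and
  subnet overlap within one complex are out of scope by design.
* Identifier namespaces are opaque strings; no cross-referencing between
  identifier systems is attempted.
* Clique enumeration is exponential in the worst case; the method is meant
  for detector-sized complexes (tens of nodes), not for decomposing whole
  interactomes in one call.
* The annotation screen is a substring match on term names — deliberately
  simple; it does not traverse an ontology graph.

## A minimal session

```{r example}
sim <- simulate_ppi(seed = 1, overlap_fraction = 0.3)
pred <- predict_interactions(sim$network, sim$complexes, k = 4, lambda = 0.7)
pred
recovery_metrics(pred, sim$held_out)
attr(pred, "report")$h_histogram
```
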