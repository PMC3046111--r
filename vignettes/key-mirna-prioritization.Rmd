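---
title: "Methods: network-based prioritization of key disease miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based prioritization of key disease miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkey)
```

`mirkey` turns a narrative analysis strategy — find the miRNAs whose
disease dysregulation a beneficial drug reverses, then weigh their
regulatory capacity, efficiency and emphasis on a protein–protein
interaction (PPI) network — into a deterministic, testable pipeline.  This
vignette explains each model, the choices behind the defaults, and what the
synthetic benchmark does and does not demonstrate.

## The four-group reversal classifier

The expression input is a pooled design: one log2 value per miRNA per group
(control, disease, disease+drug, drug-only), with no replicates.  All
inference is therefore threshold-based, not statistical:

* a miRNA is **dysregulated** when |disease − control| ≥ 0.5 log2 units;
  the boundary counts as dysregulated ("at least" a half-unit change);
* a dysregulated miRNA is **drug-reversed** when the disease+drug value
  lies on the control side of the disease value *and* the linear fold
  change `2^|disease_drug − disease|` strictly exceeds 1.5.

The direction condition matters: a miRNA pushed even further from control
by the drug shows a large fold change but is not "reversed".  Fold changes
are computed on the linear scale from the log2 differences; whether the
original chip analysis used linear or log2 folds is not documented, so the
package fixes the linear reading and exposes the threshold
(`fold_threshold`).

Between-group similarity over the dysregulated set is the Pearson
correlation of deviation-from-control vectors.  The upstream source for
this quantity is not fully specified, so the package deliberately uses this
standard, symmetric, bounded statistic and documents it as its own choice;
it reproduces the qualitative use (a between-group similarity heatmap) but
is not guaranteed to match any previously printed similarity value.  It is
undefined (an error, not a number) for fewer than three dysregulated miRNAs
or a zero-variance deviation vector.

## Static score: regulatory capacity

The PPI network is built from a weighted edge list, keeping edges with
confidence ≥ 0.7 (inclusive; STRING's 0–999 integer dialect is rescaled by
1/1000 automatically).  Degree and neighborhood connectivity are computed
on the *unweighted* topology of the filtered graph — the convention of the
standard network-analysis tooling this mirrors — while confidences are used
for filtering and later as clustering weights.

For a miRNA with target set *T* (only in-network targets; the others are
counted and reported separately):

`static = mean(deg(T))/mean(deg(V)) + mean(nc(T))/mean(nc(V)) − offset`

"Normalization by the network mean" is implemented as a plain ratio — the
only reading under which the published offset (3.3) and enhancement cutoff
(0.6) can coexist with scores of order one: if the targets were the whole
network the score would be exactly `2 − 3.3 = −1.3`.  The offset's
provenance is not documented upstream; it is reproduced verbatim and
config-exposed (`static_offset`, `static_cutoff`).  A miRNA with no target
in the network gets an explicit `NA` record, and a miRNA must clear the
cutoff on *both* networks (when a second edge list is supplied) to count as
showing enhanced regulation; with a single network the flag degrades
gracefully.

Isolated nodes are assigned neighborhood connectivity 0 by convention.

## Dynamic score: regulatory efficiency

The perturbation model is uniform-affinity mass-action dimerization: every
retained edge is a reversible binding reaction with one global association
constant `K` (default 1, in reciprocal concentration units).  With
abundances `total_i` attached as node attributes (linear scale; non-positive
values floored at 1e-6), the equilibrium satisfies, for every node,

`free_i = total_i / (1 + K · Σ_{j ∈ N(i)} free_j)`

and `complex_ij = K · free_i · free_j` on every edge.  The solver is a
damped fixed-point iteration (damping 0.5) on the free-concentration
vector, converging on both the relative update step and the mass-balance
residual (`tol = 1e-10`, `max_iter = 10000`); non-convergence is a typed
error carrying the residual, never a silent result.  The fixed point is
independent of damping and node order (tested), and the two-node case has a
closed-form quadratic solution used as an exact oracle.

A miRNA's perturbation multiplies its in-network targets' totals by a fold
— 0.5 for an up-regulated miRNA (more miRNA, more repression), 2.0 for a
down-regulated one.  The magnitude is not documented upstream; halving and
doubling are the package's defaults (`fold_up`, `fold_down`), reported in
every output.  After re-equilibration each non-source node's response is
`max(free'/free, free/free')` (≥ 1; defined as 1 when both are 0).  The
**perturbed subgroup size** at threshold *t* counts non-source nodes with
response ≥ *t*; sources are excluded so the score measures *propagation*,
not the imposed change itself.  The dynamic score is
`size(2.0) / size(1.2)`, 0 when the denominator is 0, hence always in
[0, 1].

### What propagates in this model

A perturbed node moves a binding partner in proportion to its own free
concentration's share of the partner's binding load.  Two consequences,
both confirmed by the package's property tests:

* abundant nodes with *few* competing partners are the efficient
  propagators; scarce nodes barely move anything when halved;
* hubs propagate poorly regardless of abundance, because a hub's free
  concentration is suppressed by its many partners.

The static and dynamic scores are therefore nearly orthogonal — hub
targeting drives one, abundant low-degree targeting the other — which is
why the pipeline treats them as separate evidence axes.  Note the sign of
the emergent correlation between dynamic score and mean log2 target
abundance on synthetic data is a consequence of this mechanism (abundant
targets propagate); empirical datasets have been reported to show the
opposite sign, which this model, under fold perturbations with a uniform
affinity, does not reproduce.  The correlation is reported per run rather
than asserted.

## Module discovery and enrichment

Regulatory emphasis is located on the subnetwork induced by a miRNA's
in-network targets (the method is never applied to the whole network).
Clusters are grown greedily from seeds in decreasing degree order over
not-yet-covered nodes, maximizing weighted cohesiveness

`f(V) = w_in / (w_in + w_bound + penalty · |V|)`

with single add-or-remove moves and strict improvement; near-duplicate
clusters with overlap score `|A∩B|²/(|A|·|B|) ≥ 0.8` are merged, and
clusters below size 3 or weighted internal density 0.5 are discarded.
These defaults (`penalty = 2`, `min_size = 3`, `min_density = 0.5`,
`overlap_merge = 0.8`) are the conventional defaults of
cohesiveness-based overlapping clustering; all are config-exposed.
Tie-breaks everywhere are lexicographic on node identifier, so results are
bit-stable under input reordering (tested).

Two caveats discovered while validating on planted truth, inherent to the
objective rather than the implementation (which matches brute-force
recomputation to 1e-12):

* a background node with two or three edges into a dense module can be a
  *locally optimal* cluster member; recovery of a planted module is then
  perfect in most instances but occasionally carries one extra node;
* from a singleton seed at equal edge weights, growth can prefer a chain of
  weak leaves over module mates (whose own internal strength inflates the
  boundary term) and drift away.  Weight separation — within-complex edges
  carrying higher confidence than background edges, as in real curated
  networks — removes the drift.

The largest module (ties: higher cohesiveness, then lexicographic) is
scored against each gene set by the upper-tail hypergeometric test,
drawing |module| from a universe of all network nodes, with
Benjamini–Hochberg adjustment across sets.

## Ranking

The final prioritization is codified as filter-then-sort: keep
drug-reversed miRNAs with enhanced static regulation, order by the best
adjusted enrichment p of the largest regulated module (ascending; miRNAs
without a module rank last), then by dynamic score (descending), then by
identifier.  The upstream narrative never states a single combined rule;
this codification is the package's interpretation, chosen to be
deterministic and testable, and is marked as such.

## The synthetic benchmark

`simulate_mi_study()` generates the full input bundle plus planted truth:

* **Network**: preferential-attachment graph (500 nodes, 3 edges per new
  node by default — exactly `(n−m)·m` edges), confidences uniform on
  [0.7, 1], log-normal abundances (meanlog `log 10`, sdlog 1).  The scale
  keeps `K·free` of order one so binding is neither saturated nor inert.
* **Modules**: two 8-node member sets drawn from abundant, low-degree
  nodes, with within-module edges added at probability 0.9 and confidence
  [0.85, 1] (complex-internal interactions carry stronger evidence).
  Low-degree membership keeps the complexes separable inside target
  subnetworks; abundance makes perturbing them propagate.
* **Target maps**: background miRNAs target 25 genes uniformly; each key
  miRNA targets its planted module + the top 12 hubs (static score) +
  abundant low-degree amplifier nodes (dynamic score).  Evidence labels are
  30% validated, and predicted records get p-values such that ≈ 60% of all
  records are validated-or-credible (p < 0.01).
* **Expression**: control ~ N(8, 1); planted disease effects of magnitude
  1.0–1.4 log2 (background ≤ 0.15), drug reversal 1.0–|effect| toward
  control for planted reversed miRNAs (others drift ≤ 0.25), i.i.d. noise
  at sd 0.1 on every value.  Margins are ≥ 2 noise-SD beyond every
  threshold so recovery tests are sharp rather than flaky.
* **Gene sets**: one disease set (the planted module members plus ten extra
  genes) and size-matched uniform decoys.

All generators are pure functions of (configuration, seed).

What the benchmark does **not** emulate: replicate-level microarray noise
and normalization artifacts, true miRNA target-prediction error structure,
the degree–abundance correlations of real tissues, the inverse
abundance–efficiency relationship reported empirically (see above), or
identifier-mapping noise between expression, network and target spaces.
Passing the planted-truth tests shows the pipeline's machinery is correct
and sharp under its own assumptions — not that those assumptions hold for
any particular real dataset.

## Problem sizes and runtime choices

The test suite exercises the study conditions directly: the planted-truth
acceptance checks run classification on 100 generated studies and the full
pipeline (including all per-miRNA equilibria) on 50, with the default
500-node network; oracle-equivalence checks use ≤ 50-node random graphs
where brute-force recomputation is exact; the equilibrium grid covers
K and totals over {0.1, 1, 10}.  A full pipeline run on the default
configuration takes on the order of a second on one core, dominated by the
per-miRNA re-equilibrations.

## Degenerate inputs

Typed conditions (`mirkey_input_error`, `mirkey_parameter_error`,
`mirkey_undefined_error`, `mirkey_convergence_error`,
`mirkey_empty_network_error`, `mirkey_lookup_error`) cover: missing group
columns (named in the message), malformed edge records (with line number),
empty networks after filtering, miRNAs with no in-network targets (explicit
`NA` markers, never silently dropped), undefined similarities and
correlations, non-positive abundances (floored, with the floor documented),
and disjoint identifier spaces between targets and network (fail-fast with
examples).
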