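---
title: "The circuit activity model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circuit activity model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcircuits)
```

This vignette documents the model implemented by `sigcircuits`, the
assumptions behind it, the defaults of every tunable parameter, and the
reasoning behind the numerical and statistical choices.

## 1. Pathways and circuits

A pathway is a directed graph over protein nodes with signed edges
(`activation` / `inhibition`); each node is backed by one or more genes.
Structural roles are purely topological:

* **receptors** — nodes with no incoming edges (signal entry points),
* **effectors** — nodes with no outgoing edges (function triggers),
* isolated nodes carry neither role and are dropped from circuits.

For each effector, `extract_circuits()` builds one **circuit**: the induced
subgraph on the intersection of (i) nodes reachable from any receptor and
(ii) nodes from which the effector is reachable. This walk-based definition
handles feedback loops naturally: a cycle belongs to a circuit whenever it
lies on some receptor→effector walk. Circuits whose effector is unreachable
from every receptor are dropped with a warning rather than an error, because
one malformed effector should not invalidate the rest of a pathway.

Self-loops are removed and duplicate edges collapsed (keeping the first sign
and warning on conflicts) at construction time; edges referring to unknown
nodes are fatal, since silently inventing nodes would change the topology.

## 2. Signal propagation

Each node receives a normalized expression proxy $v_n \in [0,1]$. Signal
enters at receptors with intensity 1 and a node transmits

$$ S_n \;=\; v_n \cdot \Big(1 - \prod_{a \in A_n} (1 - S_a)\Big) \cdot
   \prod_{i \in I_n} (1 - S_i), $$

with $A_n$, $I_n$ the signals arriving over activating and inhibiting edges.
For receptors the activation term is defined as 1, so $S = v$. A non-receptor
node with no activating inputs transmits 0 (signal extinction): inhibition
alone cannot generate signal. The circuit's activity is the effector's $S$.

The rule is a soft AND/OR algebra: activations combine like independent
"at least one input active" probabilities, inhibitions attenuate
multiplicatively, and $v_n$ scales transmission by how available the protein
is. All three factors are in $[0,1]$, so signals are bounded in $[0,1]$ and
the map is monotone in every activating input.

**Numerics.** Acyclic circuits are evaluated in a single topological pass —
this is exact, with no iteration error. Cyclic circuits are solved by Jacobi
fixed-point iteration started from all-zero signals: because the update is
monotone and bounded on $[0,1]^k$, the iterates increase toward the least
fixed point, which makes the result independent of node ordering. Iteration
stops when the largest componentwise change falls below `tol` (default
`1e-6`, matching the tolerance at which results are reported) or after
`max_iter` sweeps (default 1000); hitting the cap raises a
`non_convergence_warning` but still returns the last iterate, so one stubborn
circuit cannot abort a whole run. Samples are propagated as matrix columns in
lockstep.

## 3. Expression preprocessing

`normalize_expression()` applies a fixed chain:

1. **`log1p`** — variance stabilization that tolerates zeros.
2. **Truncation** at the global `q_low = 0.01` / `q_high = 0.99` quantiles
   (type-7, computed over the whole matrix) — outlier clamping so a single
   extreme value cannot stretch the final rescaling.
3. **Quantile normalization** — every column is replaced by the mean order
   statistics across columns (ties receive the average of their candidate
   values), making column distributions identical. The implementation is
   cross-checked against `limma::normalizeQuantiles(ties = TRUE)` in the test
   suite.
4. **Rescaling to $[0,1]$** — global min/max by default, so the *relative*
   scale between genes survives; `per_gene` rescaling is available when each
   gene should use its own dynamic range, and `none` skips the step.

Two contracts are worth spelling out. First, quantile normalization is
*rank-based*: changing one gene's value changes other genes' normalized
values only when it crosses their ranks. Second, truncation creates ties at
the clamp bounds, and tie-averaging there is the one documented departure
from exactly identical column order statistics.

A matrix with no variation at all cannot be quantile-normalized or rescaled
meaningfully; it passes through with a `degenerate_matrix_warning` (rescaling
a constant matrix yields 0.5, the least-informative value) rather than
failing, because degenerate inputs occur legitimately in edge-case fixtures.

**Frozen normalization.** `fit_normalization()` captures the truncation
bounds, the quantile-normalization target and the rescale bounds;
`apply_normalization()` replays them on new data. Perturbation analyses fit
the model once on the *original* matrix and apply it to both original and
perturbed copies, so a perturbation is compared all-else-equal instead of
re-deriving the reference from data it has itself distorted.

Probe-level inputs are aggregated by `aggregate_probes()`: the 90th
percentile of a gene's uniquely-mapping probes; probes mapping to several
genes are discarded unless they are a gene's only coverage, in which case
their median is used — a compromise between losing the gene entirely and
letting ambiguous probes dominate.

**Node values.** `compute_node_values()` summarizes a node's genes with the
90th percentile by default (a robust "is any isoform expressed" proxy;
`mean`, `min`, `max` are available). Genes absent from the matrix leave their
node at `missing_default = 0.5` — agnostic rather than extinguishing — and
the affected nodes are reported in an attribute.

## 4. Perturbation

`perturbation_spec()` supports three modes:

* `lof_scale` — multiply target rows by `factor` (default `0.01`, a
  hundred-fold knock-down; must be in $(0,1]$),
* `set_value` — set target rows to a constant in $[0,1]$ (on the normalized
  scale, e.g. a hard knock-out at 0),
* `overexpress` — multiply by a factor $> 1$.

Only resolved target rows change; unresolved targets warn (or error if none
resolves). `perturbation_effect()` reports per-circuit mean activity before
and after plus `log2((mean_perturbed + eps) / (mean_original + eps))` with
`eps = 1e-10` guarding exact zeros. The fold change compares *means of
activities* (not activities of means): activity is the sample-level quantity
of interest and the mean is its natural summary across samples.

`variant_interpreter()` runs the knock-down per tissue: cases are perturbed
copies of the controls, contrasted with the Wilcoxon test below; failures in
one tissue are isolated and reported, not propagated. `lof_scan()` knocks
down every pathway gene in turn and summarizes each gene's *breadth*: the
number of circuits moved by more than `breadth_threshold = 0.5` in absolute
log2 fold change.

Because quantile normalization is rank-based, a knock-down of a gene that
crosses other genes' ranks shifts those genes' normalized values slightly.
This is a real property of the preprocessing, not an artifact; it is why
perturbations of genes far from any pathway can still produce tiny (and,
with duplicated samples, systematic) activity shifts.

## 5. Differential signaling statistics

`wilcoxon_contrast()` compares circuit activities between two groups with the
two-sided Wilcoxon rank-sum test: activities are bounded, often skewed and
occasionally degenerate, so a rank test is safer than a t-test. The exact
distribution is used when the smaller group has fewer than 8 samples
(`exact_threshold = 8`); beyond that the normal approximation with continuity
correction is both accurate and tie-tolerant. Circuits whose activities are
completely tied across both groups get `p = 1` and direction `"none"` —
no evidence, not missing evidence. P-values are adjusted across circuits with
Benjamini–Hochberg (`bh_adjust()`), and direction is the sign of the median
difference (case minus control).

## 6. Synthetic fixtures and their limits

`make_pathway()` draws random DAGs (edges only from lower to higher node
index, with probability `edge_density`; each edge inhibiting with probability
`inhibition_fraction`), optionally injecting one feedback edge
(`cycle = TRUE`), and retries seeds until the pathway yields at least one
extractable circuit. `make_expression()` draws log-normal expression
(per-gene `meanlog ~ N(2, 1)`, `sdlog = 0.5`), can append background genes,
and can inject a case/control effect either as an independent second draw
(default — the realistic two-cohort situation) or as a duplicated copy of
the controls with only the target genes scaled (`duplicate_groups = TRUE` —
the all-else-equal construction used for exact recovery checks).
`make_tissue_panel()` produces per-tissue matrices with baseline offsets.
Everything is seeded through an RNG-state-preserving helper, so fixture
generation is byte-reproducible and leaves the caller's RNG untouched.

These generators are built for *property checks*, not biological realism:
genes are independent (no co-expression structure), expression is
homoscedastic log-normal, and topologies are uniform random DAGs rather than
scale-free signaling maps. Conclusions about calibration and recovery
transfer to real data only insofar as the rank-based pipeline is insensitive
to those distributional details.

Two generator regimes deserve a warning. With single-gene nodes and very few
genes, the lowest-ranked gene of each column rescales to ~0, so some node is
extinguished in every sample and many activities are exactly 0 — the
fixture CLI therefore defaults to 3 genes per node. Conversely, with
multi-gene nodes the 90th-percentile aggregator can make a single-gene
knock-down nearly a no-op; exact knock-down recovery checks use single-gene
nodes plus background genes.

## 7. Resolved design questions

* **Receptor semantics.** Receptors are modeled with an explicit `source`
  flag in `node_signal()` rather than an empty-activation special case, so
  "no activating inputs" can mean extinction for interior nodes and
  full input for receptors without ambiguity.
* **Rescaling scope.** Global (matrix-wide) truncation and rescaling are the
  defaults: per-gene scaling erases between-gene level differences, which the
  node proxy is supposed to carry. `per_gene` remains available.
* **Iteration scheme.** Jacobi (synchronous) updates rather than Gauss–Seidel:
  marginally slower, but the fixed point reached from zero is then manifestly
  independent of node ordering, which is asserted in the tests.
* **Two-group fixtures.** Independent draws are the default for case/control
  fixtures; duplicated groups are opt-in because they are a diagnostic
  construction, not a realistic one.
* **Degenerate inputs.** Constant matrices and all-tied contrasts degrade
  gracefully (warnings, `p = 1`) instead of erroring, so batch runs over many
  pathways survive individual degenerate cases.
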