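---
title: "Relative chirality indices and chirality-sensitive QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative chirality indices and chirality-sensitive QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirind)
```

## The problem

Topological indices are computed from the hydrogen-suppressed molecular
graph, and a graph does not change under reflection: enantiomers receive
identical values for every conventional descriptor, so a QSAR built from
them cannot explain why a receptor prefers one mirror image over the
other.  The relative chirality index (RCI) restores that information at
the descriptor level.  At a tetrahedral stereocenter the four substituents
A > B > C > D (Cahn–Ingold–Prelog priority) are each assigned a
nonnegative weight $\delta_a, \delta_b, \delta_c, \delta_d$ — a
topological index of the substituent fragment — and combined
asymmetrically:

$$^R\mathrm{RCI} = 3\delta_a + 2\delta_a\delta_b
  + \delta_a\delta_b\delta_c + \delta_a\delta_b\delta_c\delta_d$$
$$^S\mathrm{RCI} = 3\delta_a + 2\delta_a\delta_c
  + \delta_a\delta_b\delta_c + \delta_a\delta_b\delta_c\delta_d$$

The two formulas are the telescoping sums of partial products taken
around the stereocenter in the two rotational senses; they differ exactly
by $2\delta_a(\delta_b - \delta_c)$, so enantiomers separate whenever the
b- and c-ranked substituents differ in weight, and coincide (correctly)
when they do not.  Molecules with $N$ centers are aggregated by the root
mean square $\sqrt{\tfrac1N \sum_i \mathrm{RCI}_i^2}$, which also
separates diastereomers.  Because any fragment-level index can serve as
the weighting, one molecule yields a whole family of chirality
descriptors with widely varying mutual correlation — a descriptor *space*
rather than a single number.

```{r worked}
# the worked example: compound 1, an S-configured arylglycinamide
g <- parse_smiles(compound1_smiles())
cc <- extract_fragments(g, find_stereocenters(g)[1])
cc
w <- vapply(cc$fragments, fragment_weight, 0, scheme = "XV1")
c(R = rci_R(w), S = rci_S(w))
```

## Fragment protocol

Each substituent fragment *includes the chiral carbon* as its root, so
the attachment vertex keeps its connectivity; the center's three lost
bonds are refilled with hydrogens.  The hydrogen substituent (rank d for
every compound in the reference set) has weight 0 by convention, applied
uniformly rather than by evaluating each index on the bare one-carbon
fragment.  A weighting scheme is *pruned for the whole dataset* if any
molecule has a zero weight on a rank a, b or c substituent, since the
products above would then collapse.

CIP ranking is computed from the atomic-number hierarchical digraph
(duplicate atoms for multiple bonds, implicit hydrogens as terminal
vertices, ring closures ending in a duplicate of the revisited atom, and
a mean-atomic-number duplicate per aromatic atom).  This is the first CIP
rule only: isotopes and stereo-dependent ranking are out of scope, which
is sufficient for the compound classes handled here; exact priority ties
raise a "not a chiral center" error, and a user-supplied priority
ordering can override the ranking per center.

## The weighting schemes

The registry (`weight_schemes()`, `r nrow(weight_schemes())` schemes)
covers:

* **Connectivity** $^m\chi$ families for paths, clusters and
  path-clusters up to order 6, under simple-degree, bond-order-weighted
  and Kier–Hall valence-delta weightings
  ($\delta^v = Z^v - h$ for second-row atoms,
  $(Z^v-h)/(Z-Z^v-1)$ below).
* **Balaban J** $= \frac{q}{\mu+1}\sum_{\text{edges}} (s_i s_j)^{-1/2}$
  on the simple graph — aromatic bonds count as single edges, the
  convention that reproduces the reference value for the saturated
  fragment exactly.
* **Kier shape indices** $^1\kappa,\ ^2\kappa$: the scheme registry
  carries a global calibration factor of 0.5 on the standard Kier
  formula, fixed once against the worked-example value
  ($^2\kappa = 2.083$ for the rank-a fragment, exactly half the textbook
  4.167); `kappa_index()` itself exposes the uncalibrated formula.
* **Zagreb** M1/M2, **path counts** P1–P6 and the overall path
  multiplicity family.  The names OPM, V_MPC and B_OPM are defined here
  as: total simple-path count (lengths 1–6); the valence-weighted path
  connectivity sum; and bond-order-weighted overall path multiplicity.
  These are package conventions — the descriptor names are traditional
  but their exact definitions are not published.
* **Information content**: Shannon entropy of the order-r
  neighbourhood-equivalence partition (iterative refinement, so order
  r+1 provably refines order r), with SIC/CIC/TIC/BIC variants, in bits.
  Unprefixed names use the hydrogen-filled graph; the `H` prefix uses
  the hydrogen-suppressed graph.  Partitions that stop refining are
  flagged degenerate, and constant descriptor columns are pruned before
  modelling.
* **Triplet indices**: solve $M x = r$ where $M$ is the adjacency or
  distance matrix with its diagonal replaced by a per-vertex vector, and
  aggregate $x$.  The letter codes map Z → atomic numbers, N → graph
  order, N2 → order squared, V → degrees, S → distance sums; operation
  1 is the plain sum.  This mapping is pinned by the single published
  calibration value (AZV1 = 1.422 for the rank-a fragment): a
  graph-order diagonal gives 1.324 and is therefore ruled out.  The five
  aggregation operations (sum, sum of squares, sum of root magnitudes,
  $n \times$ geometric mean, geometric mean) and the 2 × 10 × 5 = 100
  code grammar are recorded registry conventions; registry weights are
  magnitudes, since distance-matrix systems can produce negative local
  invariants.

One reference value resists every plain reconstruction: the printed
first-order information content of the rank-a fragment (1.7799 bits)
matches neither the H-filled (2.33) nor H-suppressed (1.84) Shannon
construction, and the printed Balaban J of the two aromatic fragments
(3.298, 3.033) matches neither the simple-graph nor the
bond-order-weighted conventions.  These values are therefore carried as
*printed inputs* in the worked-example tables and tests, not asserted as
outputs of the index modules; the remaining eight of the twelve
structure-derived reference numbers reproduce exactly.

## The modelling pipeline

`qcsar()` fits the whole chain and returns a classed model object:

1. **Standardize** by $\ln(x+1)$ — fragment indices differ by orders of
   magnitude.
2. **Prune** all-zero and constant columns.
3. **PCA on the correlation matrix**, retaining components with
   eigenvalue > 1 (Kaiser rule; the eigenvalues of a correlation matrix
   sum to the variable count, which is what makes the rule meaningful).
4. **Stepwise regression** of activity on the retained component scores
   (forward on partial-F p ≤ 0.05, backward at p ≥ 0.10 — the defaults
   of the statistical package tradition this pipeline mirrors; both are
   arguments).  Orthogonal scores mean no collinearity among entered
   predictors by construction.
5. **Re-express in descriptors**: for each component in the final score
   model, select the descriptor with maximal |r| to its scores — ties go
   to the descriptor with more distinct values ("least degenerate"),
   then to the lexicographically first name — and refit.  A score model
   cannot predict new compounds without redoing the PCA; the descriptor
   refit can.
6. **Five-fold cross-validation** of the refit with a seeded shuffle;
   fold memberships are reported, and with 20 compounds each fold holds
   exactly 4.

```{r pipeline}
d <- gen_qsar_dataset(20, 60, 2, noise_sd = 0.3, seed = 7, beta = c(1, 0.7))
fit <- qcsar(d$x, d$y, cv_seed = 7)
fit
```

## What the synthetic generators emulate

`gen_chiral_molecules()` builds acyclic molecules over C/N/O/S/F/Cl with
1–3 annotated tetrahedral centers, each emitted with its mirror image,
and guarantees by construction (validated through the ranking routine)
that every center's four substituents are CIP-distinguishable.
`gen_qsar_dataset()` mimics the statistical shape of a real descriptor
pool: lognormal nonnegative values, a strongly hierarchical correlation
structure (a few large correlated blocks with geometrically decreasing
sizes, like the steep eigenvalue profile of real topological-index
matrices), and an activity that is linear *on the transformed scale* in a
few planted descriptors, each the latent anchor of its block
(within-block correlation 0.95, activity noise SD 0.3 against
unit-order coefficients).  Block factors are drawn orthogonal in-sample;
without this the leading eigenvalues of same-sized blocks are degenerate
and the components are arbitrary rotations, which no selection rule can
undo.  What passing recovery tests therefore shows is that the pipeline
finds planted, identified, block-anchored signal at the study's
dimensions (20 compounds × 198 descriptors × 3 signals); it does not
show that three interpretable descriptors must emerge from real
assay data, where signal need not be block-aligned and factor overlap is
uncontrolled.

## Numerical choices and limitations

* Graphs are exact integer structures; shortest paths come from a BFS
  library routine and are cross-checked against a Floyd–Warshall oracle
  in the tests; triplet systems use a direct dense solve and refuse
  (near-)singular systems by error rather than regularising.
* Problem sizes in the test suite: oracle equivalence on graphs ≤ 8
  vertices (exhaustive subgraph enumeration), recovery on 20 seeded
  replicates of the 20 × 198 × 3 design, algebraic identities on 10⁴
  random weight vectors.
* The SMILES parser covers the neutral organic subset with brackets,
  rings and tetrahedral marks; charged or isotopic atoms parse but are
  rejected by the index modules, matching the neutral reference
  compound set.  Axial and planar chirality, stereocenters at
  non-carbon atoms, and 3D geometry are out of scope.
* Descriptor values are deterministic; all stochastic steps (generators,
  cross-validation folds) take explicit seeds and are reproducible
  byte-for-byte.
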