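# chirind — relative chirality indices for chirality-sensitive QSAR

Conventional topological indices are computed from the molecular graph,
and enantiomers have identical graphs: every classical descriptor assigns
the *R*- and *S*-isomer the same number, so a QSAR built from them is
blind to stereochemistry — a serious gap for drug-discovery datasets
where receptors are themselves chiral.  `chirind` implements the relative
chirality index (RCI) family of descriptors and the modelling pipeline
that uses them.

At each tetrahedral stereocenter the four substituents, ranked
A > B > C > D by Cahn–Ingold–Prelog priority, receive nonnegative weights
δ<sub>a</sub>, δ<sub>b</sub>, δ<sub>c</sub>, δ<sub>d</sub> — each a
topological index of the substituent fragment (the fragment includes the
chiral carbon as its root).  The two isomers get:

    R-RCI = 3 δa + 2 δa δb + δa δb δc + δa δb δc δd
    S-RCI = 3 δa + 2 δa δc + δa δb δc + δa δb δc δd

so `R-RCI − S-RCI = 2 δa (δb − δc)`: mirror images separate exactly when
the b- and c-ranked substituents differ in weight.  Multi-center
molecules aggregate per-center values by root mean square, which also
separates diastereomers.  Because *any* fragment index can serve as the
weighting — Balaban J, Kier–Hall χ and κ, Zagreb, overall connectivity,
Basak information content, triplet indices — one molecule yields a
multidimensional space of chirality descriptors (216 registered schemes).

The package provides:

* a SMILES parser for the neutral organic subset with tetrahedral
  stereo perception (`parse_smiles`, `configuration`),
* CIP-style substituent ranking and fragment extraction
  (`cip_rank`, `extract_fragments`),
* the index modules (`balaban_j`, `chi`, `kappa_index`, `zagreb`,
  `path_counts`, `overall_connectivity`, `neighborhood_partition`, `ic`,
  `ic_variants`, `solve_triplet`, `triplet_index`),
* the descriptor matrix builder with the zero-weight pruning rule
  (`compute_rci_matrix`, `weight_schemes`),
* the QSAR pipeline as a classed model: ln(x+1) standardization,
  correlation-matrix PCA with Kaiser retention, stepwise regression on
  component scores, per-component descriptor selection and refit,
  seeded k-fold cross-validation (`qcsar`, with `print`, `summary`,
  `coef`, `predict`, `residuals`, `plot` methods),
* seeded synthetic generators for chiral molecules and planted-signal
  QSAR datasets (`gen_chiral_molecules`, `gen_qsar_dataset`), and
* a thin command-line front end (`inst/cli/chirind`) with subcommands
  `descriptors`, `weights`, `rci`, `qsar`, `synth`, `fixtures`.

## Worked example

Compound 1 of the reference set is an S-configured arylglycinamide.
Extracting its stereocenter fragments and weighting them:

```r
library(chirind)
g  <- parse_smiles(compound1_smiles())
cc <- extract_fragments(g, find_stereocenters(g)[1])
cc
#> <chiral_center> atom 1 (S)
#>   a: CNCCN(C)C
#>   b: CC(=O)NCc1cc(C(F)(F)F)cc(C(F)(F)F)c1
#>   c: Cc1ccccc1
#>   d: H

run_weights(data.frame(id = "cpd1", smiles = compound1_smiles()),
            schemes = c("K2", "XV1", "AZV1"))
#>     id center configuration rank                             fragment    K2   XV1  AZV1
#> 1 cpd1      1             S    a                            CNCCN(C)C 2.083 2.564 1.422
#> 2 cpd1      1             S    b CC(=O)NCc1cc(C(F)(F)F)cc(C(F)(F)F)c1 3.093 5.027 4.180
#> 3 cpd1      1             S    c                            Cc1ccccc1 1.172 2.411 1.711
#> 4 cpd1      1             S    d                                    H 0.000 0.000 0.000
```

The rows are the four CIP-ranked fragments; the hydrogen substituent has
weight 0 by convention.  Feeding the weights through the S-isomer formula
gives the compound's descriptors:

```r
compute_rci_matrix(data.frame(id = "cpd1", smiles = compound1_smiles()),
                   schemes = c("K2", "XV1", "AZV1"))
#>          K2    XV1   AZV1
#> cpd1 18.683 51.131 19.307
```

These match the published worked values for the S isomer (18.683, 51.131,
19.307).  A full modelling run on a synthetic dataset with three planted
signal descriptors:

```r
d   <- gen_qsar_dataset(20, 198, 3, noise_sd = 0.3, seed = 11)
fit <- qcsar(d$x, d$y, cv_seed = 11)
fit
#> Chirality-sensitive QSAR model
#>   compounds: 20  descriptors: 198 ( 0 dropped as degenerate )
#>   retained components (eigenvalue > 1): ...
#>   score model: PC1 + PC2 + PC3  R2 = ...
#>   descriptor model: D... + D... + D...
```

`summary(fit)` adds eigenvalues, fold-wise cross-validation R², and the
activity-correlation ranking; `predict(fit, newdata)` scores new
compounds through the descriptor refit (the score model would require
repeating the PCA, which is exactly why the pipeline re-expresses the
model in real descriptors).

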