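frag <- table2_fragment_graphs()

test_that("Balaban J matches hand values and the worked fragment", {
  expect_equal(balaban_j(frag$a), 2.678, tolerance = 5e-4)
  expect_equal(balaban_j(parse_smiles("CC")), 1.0)
  expect_equal(balaban_j(parse_smiles("C")), 0)
})

test_that("Balaban J is invariant under vertex relabeling", {
  set.seed(77)
  for (rep in 1:10) {
    g <- random_tree_graph(sample(4:9, 1))
    perm <- sample(n_atoms(g))
    expect_equal(balaban_j(permute_graph(g, perm)), balaban_j(g))
  }
})

test_that("chi indices reproduce worked values and trivial cases", {
  expect_equal(chi(frag$a, 1, weighting = "valence"), 2.564, tolerance = 5e-4)
  expect_equal(chi(frag$c, 1, weighting = "valence"), 2.411, tolerance = 5e-4)
  expect_equal(chi(parse_smiles("CC"), 1), 1.0)
  expect_error(chi(frag$a, 7), "order")
})

test_that("first-order simple chi equals the Randic edge sum", {
  graphs <- c(frag[c("a", "b", "c")],
              list(parse_smiles("CC(C)C"), cycle_graph(6)))
  for (g in graphs) {
    d <- degrees(g)
    randic <- sum(1 / sqrt(d[g$bonds$i] * d[g$bonds$j]))
    expect_equal(chi(g, 1), randic)
  }
})

test_that("chi over all subgraph kinds agrees with the exhaustive oracle", {
  graphs <- list(parse_smiles("CC(C)(C)CC"), parse_smiles("CC(C)C(C)(C)C"),
                 cycle_graph(6), parse_smiles("CC1CCC1"))
  for (g in graphs) {
    for (ord in 1:4) for (kind in c("path", "cluster", "path-cluster", "chain")) {
      expect_equal(chi(g, ord, kind), chi_oracle(g, ord, kind),
                   info = paste(g$smiles, ord, kind))
    }
  }
})

test_that("subgraph enumeration matches the edge-subset oracle", {
  graphs <- list(frag$a, parse_smiles("CC(C)(C)CC"), cycle_graph(5),
                 parse_smiles("C1CC1CC"))
  for (g in graphs) for (ord in 1:4) {
    mine <- chirind:::connected_edge_subgraphs(g, ord)
    oracle <- subgraphs_by_subset(g, ord)
    canon <- function(l) sort(vapply(l, function(e) paste(sort(e), collapse = ","), ""))
    expect_equal(canon(mine), canon(oracle), info = paste(g$smiles, ord))
  }
})

test_that("kappa shape indices follow the Kier formulas", {
  expect_equal(kappa_index(parse_smiles("CCCCC"), 2), 4)
  expect_equal(kappa_index(parse_smiles("CCCC"), 1), 4)
  expect_equal(kappa_index(frag$a, 2), 25 * 6 / 36)  # standard value, twice Table 2
  expect_error(kappa_index(parse_smiles("CC"), 2), "too small")
})

test_that("the registry kappa scheme carries the recorded 0.5 calibration", {
  expect_equal(fragment_weight(frag$a, "K2"), 2.083, tolerance = 5e-4)
  expect_equal(fragment_weight(frag$b, "K2"), 3.093, tolerance = 5e-4)
  expect_equal(fragment_weight(frag$c, "K2"), 1.172, tolerance = 5e-4)
})

test_that("Zagreb indices and trivial graphs", {
  p3 <- parse_smiles("CCC")
  expect_equal(zagreb(p3, 1), 6)
  expect_equal(zagreb(p3, 2), 4)
  expect_equal(zagreb(parse_smiles("C"), 1), 0)
  expect_equal(zagreb(parse_smiles("C"), 2), 0)
})

test_that("path counts match hand counts, tree identity and the oracle", {
  expect_equal(unname(path_counts(parse_smiles("CCC"), 2)), c(3, 2, 1))
  expect_equal(unname(path_counts(parse_smiles("C"), 0)), 1)
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    g <- random_tree_graph(n)
    pc <- path_counts(g, n - 1)
    expect_equal(sum(pc[-1]), n * (n - 1) / 2)  # unique path per vertex pair
  }
  g <- parse_smiles("CC1CCC1C")
  for (len in 1:4)
    expect_equal(unname(path_counts(g, 4)[len + 1]), path_count_oracle(g, len))
})

test_that("overall connectivity sums parent degrees over subgraphs", {
  expect_equal(overall_connectivity(parse_smiles("CC"), 1), 2)
  expect_equal(overall_connectivity(parse_smiles("CCC"), 0), 4)
  expect_equal(overall_connectivity(parse_smiles("C"), 1), 0)
  # explicit hand check on the 3-path at order 1: two edge-subgraphs,
  # each contributing (1+2) parent degree
  expect_equal(overall_connectivity(parse_smiles("CCC"), 1), 6)
})

test_that("indices coincide on enantiomer fragment sets taken unordered", {
  mols <- gen_chiral_molecules(3, seed = 21, n_centers = 1)
  for (m in seq_len(nrow(mols))) {
    g1 <- parse_smiles(mols$smiles[m])
    g2 <- parse_smiles(mols$enantiomer_smiles[m])
    cc1 <- extract_fragments(g1, find_stereocenters(g1)[1])
    cc2 <- extract_fragments(g2, find_stereocenters(g2)[1])
    for (sch in c("J", "XV1", "M1", "OC2", "AZV1")) {
      w1 <- sort(vapply(cc1$fragments, fragment_weight, 0, scheme = sch))
      w2 <- sort(vapply(cc2$fragments, fragment_weight, 0, scheme = sch))
      expect_equal(w1, w2, info = sch)
    }
  }
})
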