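test_that("SMILES parsing recovers atom counts, bonds and degrees", {
  g <- parse_smiles("CNCCN(C)C")
  expect_equal(n_atoms(g), 7L)
  expect_equal(n_bonds(g), 6L)
  expect_equal(degrees(g), c(1L, 2L, 2L, 2L, 3L, 1L, 1L))
  expect_equal(g$atoms$element, c("C", "N", "C", "C", "N", "C", "C"))

  g1 <- parse_smiles("C")
  expect_equal(n_atoms(g1), 1L)
  expect_equal(n_bonds(g1), 0L)

  tol <- parse_smiles("Cc1ccccc1")
  expect_equal(n_atoms(tol), 7L)
  expect_equal(n_bonds(tol), 7L)
  expect_equal(cyclomatic(tol), 1L)
  # aromatic ring hydrogens: 5 CH + CH3
  expect_equal(sum(tol$atoms$attached_h), 8L)
})

test_that("implicit hydrogen filling follows standard valences", {
  expect_equal(parse_smiles("C")$atoms$attached_h, 4L)
  expect_equal(parse_smiles("O")$atoms$attached_h, 2L)
  expect_equal(parse_smiles("C=O")$atoms$attached_h, c(2L, 0L))
  expect_equal(parse_smiles("C#N")$atoms$attached_h, c(1L, 0L))
  expect_equal(parse_smiles("FC(F)(F)F")$atoms$attached_h, c(0L, 0L, 0L, 0L, 0L))
  expect_equal(parse_smiles("c1ccncc1")$atoms$attached_h, c(1L, 1L, 1L, 0L, 1L, 1L))
})

test_that("malformed and disconnected input is rejected with a clear error", {
  expect_error(parse_smiles("C(("), "unclosed")
  expect_error(parse_smiles("C)C"), "unmatched")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CQC"), "unexpected token")
  expect_error(parse_smiles("[Xx]"), "bracket atom")
  expect_error(parse_smiles("C.C"), "unexpected token")
})

test_that("charged/isotopic atoms parse but index modules reject them", {
  g <- parse_smiles("C[N+](C)(C)C")
  expect_equal(g$atoms$charge[2], 1L)
  expect_error(valence_deltas(g), "charged or isotopically")
  g2 <- parse_smiles("[13C]")
  expect_equal(g2$atoms$isotope[1], 13L)
})

test_that("distance matrix matches hand counts and the worked fragment", {
  p3 <- parse_smiles("CCC")
  expect_equal(rowSums(distance_matrix(p3)), c(3, 2, 3))
  g <- parse_smiles("CNCCN(C)C")
  expect_equal(rowSums(distance_matrix(g)), c(20, 15, 12, 11, 12, 17, 17))
  expect_equal(distance_matrix(parse_smiles("C")), matrix(0L, 1, 1))
})

test_that("distance matrix agrees with a Floyd-Warshall oracle on random trees and cycles", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_tree_graph(sample(2:10, 1))
    expect_equal(unname(distance_matrix(g)), unname(floyd_warshall(g)))
  }
  for (n in 3:10) {
    g <- cycle_graph(n)
    D <- distance_matrix(g)
    expect_equal(unname(D), unname(floyd_warshall(g)))
    # symmetry, zero diagonal, triangle inequality
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (k in seq_len(n)) expect_true(all(D <= outer(D[, k], D[k, ], "+")))
  }
})

test_that("degree sum equals twice the edge count on parsed molecules", {
  mols <- gen_chiral_molecules(10, seed = 5)
  for (smi in c(mols$smiles, mols$enantiomer_smiles)) {
    g <- parse_smiles(smi)
    expect_equal(sum(degrees(g)), 2L * n_bonds(g))
  }
})

test_that("H-filled view has heavy count plus hydrogen total vertices", {
  mols <- gen_chiral_molecules(50, seed = 12)
  for (smi in c(mols$smiles, mols$enantiomer_smiles)) {
    g <- parse_smiles(smi)
    hf <- h_filled(g)
    expect_equal(n_atoms(hf), n_atoms(g) + sum(g$atoms$attached_h))
    expect_equal(sum(hf$atoms$attached_h), 0L)
  }
})

test_that("valence deltas follow the Kier-Hall conventions", {
  expect_equal(valence_delta("N", 1), 4)
  expect_equal(valence_delta("C", 3), 1)
  expect_equal(valence_delta("S", 0), 6 / 9)
  expect_equal(valence_delta("Cl", 0), 7 / 9)
  expect_error(valence_delta("Xx", 0), "unsupported element")
})

test_that("SMILES line files are read with comments and ids", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("# header comment", "m1\tCCO", "", "m2\tc1ccccc1"), f)
  tab <- read_smiles_file(f)
  expect_equal(tab$id, c("m1", "m2"))
  expect_equal(tab$smiles, c("CCO", "c1ccccc1"))
  writeLines(c("justone"), f)
  expect_error(read_smiles_file(f), "malformed")
})

test_that("the SMILES writer round-trips fragment graphs", {
  for (smi in table2_weights()$smiles) {
    g <- parse_smiles(smi)
    g2 <- parse_smiles(mol_to_smiles(g))
    expect_equal(n_atoms(g2), n_atoms(g))
    expect_equal(n_bonds(g2), n_bonds(g))
    expect_equal(sort(table(g2$atoms$element)), sort(table(g$atoms$element)))
    expect_equal(sum(g2$atoms$attached_h), sum(g$atoms$attached_h))
  }
})
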