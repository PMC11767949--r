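test_that("the ten reference RCI values follow from the printed weights", {
  w <- table2_weights()
  ref <- rci_reference()
  for (k in seq_len(nrow(ref))) {
    sch <- ref$scheme[k]
    delta <- w[[sch]]
    expect_equal(rci_R(delta), ref$R[k], tolerance = 5e-3, info = sch)
    expect_equal(rci_S(delta), ref$S[k], tolerance = 5e-3, info = sch)
  }
})

test_that("unit weights give 7 and bad weights error", {
  expect_equal(rci_R(c(1, 1, 1, 1)), 7)
  expect_equal(rci_S(c(1, 1, 1, 1)), 7)
  expect_error(rci_R(c(-1, 1, 1, 1)), "nonnegative")
  expect_error(rci_S(c(1, 1, 1)), "four numbers")
})

test_that("rci_R - rci_S equals 2 da (db - dc) on random weights", {
  set.seed(101)
  W <- matrix(runif(4000, 0, 10), ncol = 4)
  for (r in seq_len(nrow(W))) {
    w <- W[r, ]
    expect_equal(rci_R(w) - rci_S(w), 2 * w[1] * (w[2] - w[3]), tolerance = 1e-9)
  }
  # exact equality when db = dc
  w <- c(2.5, 3.3, 3.3, 0.7)
  expect_identical(rci_R(w), rci_S(w))
})

test_that("rci_R and rci_S are strictly increasing in each positive weight", {
  w <- c(1.5, 2.5, 0.8, 0.3)
  for (k in 1:4) {
    up <- w; up[k] <- up[k] + 0.1
    expect_gt(rci_R(up), rci_R(w))
    expect_gt(rci_S(up), rci_S(w))
  }
})

test_that("swapping the b and c weights exchanges the R and S values", {
  set.seed(7)
  for (rep in 1:50) {
    w <- runif(4, 0, 5)
    ws <- w[c(1, 3, 2, 4)]
    expect_equal(rci_R(ws), rci_S(w))
    expect_equal(rci_S(ws), rci_R(w))
  }
})

test_that("RMS aggregation is the identity for one center and symmetric", {
  expect_equal(rci_rms(52.482), 52.482)
  expect_equal(rci_rms(c(3, 4)), sqrt(25 / 2))
  expect_equal(rci_rms(c(4, 3)), rci_rms(c(3, 4)))
  expect_error(rci_rms(numeric(0)), "empty")
  expect_error(rci_rms(c(1, -2)), "nonnegative")
})

test_that("fragment extraction reproduces the worked-example fragments", {
  g <- parse_smiles(compound1_smiles())
  centers <- find_stereocenters(g)
  expect_length(centers, 1L)
  cc <- extract_fragments(g, centers[1])
  expect_s3_class(cc, "chiral_center")
  expect_equal(cc$configuration, "S")
  expect_equal(names(cc$fragments), c("a", "b", "c", "d"))
  expect_true(cc$fragments$d$is_hydrogen)

  ref <- table2_fragment_graphs()
  for (rk in c("a", "b", "c")) {
    got <- cc$fragments[[rk]]$graph
    expect_equal(n_atoms(got), n_atoms(ref[[rk]]), info = rk)
    expect_equal(n_bonds(got), n_bonds(ref[[rk]]), info = rk)
    # graph identity up to labeling: same J and valence chi
    expect_equal(balaban_j(got), balaban_j(ref[[rk]]), info = rk)
    expect_equal(chi(got, 1, weighting = "valence"),
                 chi(ref[[rk]], 1, weighting = "valence"), info = rk)
  }
})

test_that("molecules without stereocenters and CIP ties are handled", {
  expect_length(find_stereocenters(parse_smiles("CCO")), 0L)
  # two identical substituents: not a chiral center
  g <- parse_smiles("[C@](C)(C)(N)O")
  expect_error(extract_fragments(g, 1), "not a chiral center")
})

test_that("a two-stereocenter molecule yields two centers and RMS aggregation", {
  mols <- gen_chiral_molecules(1, seed = 33, n_centers = 2)
  g <- parse_smiles(mols$smiles[1])
  centers <- find_stereocenters(g)
  expect_length(centers, 2L)
  per_center <- vapply(centers, function(ct) {
    cc <- extract_fragments(g, ct)
    w <- vapply(cc$fragments, fragment_weight, 0, scheme = "XV1")
    if (cc$configuration == "R") rci_R(w) else rci_S(w)
  }, 0)
  M <- compute_rci_matrix(mols[, c("id", "smiles")], schemes = c("XV1"))
  expect_equal(unname(M[1, "XV1"]), rci_rms(per_center))
})

test_that("diastereomers receive different RMS descriptors", {
  mols <- gen_chiral_molecules(1, seed = 14, n_centers = 2)
  smi_rr <- mols$smiles[1]
  # flip only the first stereo mark: a diastereomer, not the enantiomer
  flip_first <- function(s) {
    if (grepl("@@", substr(s, 1, 4))) sub("@@", "@", s)
    else sub("@", "@@", s)
  }
  smi_rs <- flip_first(smi_rr)
  M <- compute_rci_matrix(data.frame(id = c("rr", "rs"),
                                     smiles = c(smi_rr, smi_rs)),
                          schemes = c("XV1", "J"))
  cfg <- attr(M, "centers")
  expect_false(identical(cfg$rr$configuration, cfg$rs$configuration))
  expect_false(any(M["rr", ] == M["rs", ]))
})

test_that("the zero-weight pruning rule drops and retains correctly", {
  schemes <- c("s_ok", "s_zero_b", "s_zero_d")
  mk <- function(da, db, dc, dd) {
    m <- matrix(c(da, db, dc, dd), nrow = 3, ncol = 4, byrow = TRUE,
                dimnames = list(schemes, c("da", "db", "dc", "dd")))
    m["s_zero_b", "db"] <- 0
    m["s_zero_d", "dd"] <- 0
    m
  }
  weights <- list(mol1 = list(mk(1, 2, 3, 0)))
  kept <- prune_zero_weight_schemes(weights, schemes)
  expect_true("s_ok" %in% kept)
  expect_true("s_zero_d" %in% kept)   # rank-d zeros are the norm
  expect_false("s_zero_b" %in% kept)
  # all nonzero: unchanged
  w2 <- list(mol1 = list(matrix(1, 1, 4, dimnames = list("s", c("da","db","dc","dd")))))
  expect_equal(prune_zero_weight_schemes(w2, "s"), "s")
})

test_that("user-supplied priorities override the CIP ranking", {
  g <- parse_smiles(compound1_smiles())
  cc_auto <- extract_fragments(g, 1)
  # reverse the a/c assignment by hand: priorities as atom indices (0 = H)
  ranked <- cip_rank(g, 1)$neighbors
  idx <- vapply(ranked, function(s) if (identical(s, "H")) 0L else as.integer(s), 0L)
  cc_swap <- extract_fragments(g, 1, priorities = idx[c(3, 2, 1, 4)])
  expect_equal(cc_swap$fragments$a$smiles, cc_auto$fragments$c$smiles)
  expect_equal(cc_swap$fragments$c$smiles, cc_auto$fragments$a$smiles)
})

test_that("compound 1 reproduces the structure-derived reference schemes", {
  M <- compute_rci_matrix(data.frame(id = "1", smiles = compound1_smiles()),
                          schemes = c("XV1", "K2", "AZV1"))
  ref <- rci_reference()
  # compound 1 is the S isomer
  expect_equal(unname(M[1, "XV1"]), ref$S[ref$scheme == "XV1"], tolerance = 5e-3)
  expect_equal(unname(M[1, "K2"]), ref$S[ref$scheme == "K2"], tolerance = 5e-3)
  expect_equal(unname(M[1, "AZV1"]), ref$S[ref$scheme == "AZV1"], tolerance = 5e-3)
})

test_that("molecules without stereocenters are rejected by the matrix builder", {
  expect_error(compute_rci_matrix(data.frame(id = "x", smiles = "CCO")),
               "no annotated stereocenter")
})
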