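# Independent oracles used by the property tests.  Each deliberately uses a
# different algorithm from the implementation it checks.

# Floyd-Warshall all-pairs shortest paths on the simple graph.
floyd_warshall <- function(g) {
  n <- n_atoms(g)
  D <- matrix(Inf, n, n); diag(D) <- 0
  if (n_bonds(g)) for (k in seq_len(n_bonds(g))) {
    D[g$bonds$i[k], g$bonds$j[k]] <- 1
    D[g$bonds$j[k], g$bonds$i[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Exhaustive connected-subgraph oracle: every subset of m edges, kept when
# the induced subgraph is connected (checked through igraph, not through
# the package's recursive grower).
subgraphs_by_subset <- function(g, m) {
  q <- n_bonds(g)
  if (m < 1 || m > q) return(list())
  combos <- utils::combn(q, m, simplify = FALSE)
  Filter(function(edges) {
    verts <- unique(c(g$bonds$i[edges], g$bonds$j[edges]))
    ig <- igraph::graph_from_data_frame(
      data.frame(a = match(g$bonds$i[edges], verts),
                 b = match(g$bonds$j[edges], verts)),
      directed = FALSE, vertices = data.frame(name = seq_along(verts)))
    igraph::is_connected(ig)
  }, combos)
}

# Brute-force chi by direct summation over the oracle's subgraph list.
chi_oracle <- function(g, order, kind, weighting = "simple") {
  w <- switch(weighting, simple = degrees(g), valence = valence_deltas(g))
  if (order == 0) return(sum(1 / sqrt(w[w > 0])))
  total <- 0
  for (edges in subgraphs_by_subset(g, order)) {
    if (chirind:::classify_subgraph(g, edges) != kind) next
    verts <- unique(c(g$bonds$i[edges], g$bonds$j[edges]))
    if (any(w[verts] <= 0)) next
    total <- total + 1 / sqrt(prod(w[verts]))
  }
  total
}

# Simple-path count oracle: DFS over vertex sequences, counting each
# unordered path once via endpoint ordering.
path_count_oracle <- function(g, len) {
  if (len == 0) return(n_atoms(g))
  n <- n_atoms(g)
  A <- adjacency_matrix(g)
  count <- 0
  extend <- function(path) {
    if (length(path) == len + 1) {
      if (path[1] < path[length(path)]) count <<- count + 1
      return(invisible())
    }
    for (nxt in which(A[path[length(path)], ] == 1))
      if (!nxt %in% path) extend(c(path, nxt))
  }
  for (v in seq_len(n)) extend(v)
  count
}

# Canonical form of the radius-r rooted neighbourhood of an atom; two atoms
# are order-r equivalent iff their canonical forms match.  Recursive
# canonicalisation, independent of the iterative-refinement implementation.
rooted_ball_canon <- function(g, atom, r) {
  A <- adjacency_matrix(g)
  rec <- function(v, from, depth) {
    if (depth < 0) return("")
    kids <- setdiff(which(A[v, ] == 1), from)
    inner <- if (depth == 0) character(0)
      else sort(vapply(kids, function(k) {
        o <- g$bonds$order[(g$bonds$i == v & g$bonds$j == k) |
                           (g$bonds$j == v & g$bonds$i == k)][1]
        paste0(o, rec(k, v, depth - 1))
      }, ""))
    paste0(g$atoms$element[v], "{", paste(inner, collapse = ","), "}")
  }
  # breadth-limited but path-aware: adequate for the trees used in tests
  rec(atom, integer(0), r)
}

# Random labelled tree on n vertices as a molgraph-like object with all-C
# atoms (via igraph's sampler, independent of the SMILES machinery).
random_tree_graph <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(parse_smiles("C"))
  ig <- igraph::sample_tree(n)
  el <- igraph::as_edgelist(ig)
  smiles_free_molgraph(data.frame(i = el[, 1], j = el[, 2], order = 1), n)
}

# Cycle graph C_n.
cycle_graph <- function(n) {
  stopifnot(n >= 3)
  smiles_free_molgraph(
    data.frame(i = seq_len(n), j = c(2:n, 1L), order = 1), n)
}

# Assemble a molgraph directly from a bond list (all carbons, no H).
smiles_free_molgraph <- function(bonds, n) {
  structure(list(
    atoms = data.frame(element = rep("C", n), aromatic = FALSE,
                       attached_h = 0L, charge = 0L, isotope = NA_integer_,
                       stereo = "", Z = 6, Zv = 4, stringsAsFactors = FALSE),
    bonds = bonds, nbr_order = NULL, smiles = "<synthetic>",
    cache = new.env(parent = emptyenv())), class = "molgraph")
}

# Relabel the vertices of a molgraph by a permutation (oracle helper for
# invariance tests).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  atoms <- g$atoms[inv, , drop = FALSE]; rownames(atoms) <- NULL
  bonds <- data.frame(i = perm[g$bonds$i], j = perm[g$bonds$j],
                      order = g$bonds$order)
  structure(list(atoms = atoms, bonds = bonds, nbr_order = NULL,
                 smiles = "<permuted>",
                 cache = new.env(parent = emptyenv())), class = "molgraph")
}

# The worked-example fragment graphs (parsed once per test file load).
table2_fragment_graphs <- function() {
  lapply(setNames(table2_weights()$smiles, table2_weights()$rank), parse_smiles)
}
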