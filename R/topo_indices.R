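# Connected-subgraph enumeration and the topo-structural / topo-chemical
# scalar indices used as substituent weights.

# All connected subgraphs with exactly m edges, as a list of edge-index
# vectors.  Exhaustive recursive growth with string-key deduplication; the
# fragment graphs this package handles are small (tens of atoms, m <= 6).
connected_edge_subgraphs <- function(g, m) {
  .gmemo(g, paste0("subgraphs_", m), function() .edge_subgraphs_build(g, m))
}

.edge_subgraphs_build <- function(g, m) {
  q <- n_bonds(g)
  if (m < 1L || q == 0L || m > q) return(list())
  ei <- g$bonds$i; ej <- g$bonds$j
  # edges incident to each vertex
  inc <- vector("list", n_atoms(g))
  for (e in seq_len(q)) {
    inc[[ei[e]]] <- c(inc[[ei[e]]], e)
    inc[[ej[e]]] <- c(inc[[ej[e]]], e)
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", 0L)
  grow <- function(edges, verts) {
    key <- paste(sort(edges), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    if (length(edges) == m) { out[[length(out) + 1L]] <<- sort(edges); return(invisible()) }
    cand <- setdiff(unique(unlist(inc[verts])), edges)
    for (e in cand) grow(c(edges, e), unique(c(verts, ei[e], ej[e])))
  }
  for (e in seq_len(q)) grow(e, c(ei[e], ej[e]))
  out
}

# Kier-Hall subgraph taxonomy: path (tree, max degree <= 2), cluster (tree,
# no internal degree-2 vertex, max degree >= 3), path-cluster (tree with
# both), chain (contains a cycle).
classify_subgraph <- function(g, edges) {
  vi <- g$bonds$i[edges]; vj <- g$bonds$j[edges]
  verts <- unique(c(vi, vj))
  if (length(edges) >= length(verts)) return("chain")
  deg <- table(factor(c(vi, vj), levels = verts))
  if (max(deg) <= 2) return("path")
  if (any(deg == 2)) return("path-cluster")
  "cluster"
}

.vertex_weights <- function(g, weighting) {
  switch(weighting,
         simple  = as.numeric(degrees(g)),
         valence = valence_deltas(g),
         bond    = bond_degrees(g),
         stop("unknown weighting '", weighting, "'", call. = FALSE))
}

#' Molecular connectivity (chi) indices
#'
#' Kier-Hall generalisation of the Randic index: the sum over connected
#' subgraphs of a given kind and order of the reciprocal square root of the
#' product of vertex weights, the weights being simple degrees, bond-order
#' weighted degrees, or Kier-Hall valence deltas measured in the parent
#' graph.  Order 0 sums over single vertices.  Vertices with zero weight
#' contribute nothing (their subgraph term is dropped).
#'
#' @param g a `molgraph`.
#' @param order number of edges in each subgraph, 0..6.
#' @param kind one of `"path"`, `"cluster"`, `"path-cluster"`, `"chain"`.
#' @param weighting one of `"simple"`, `"valence"`, `"bond"`.
#' @examples
#' chi(parse_smiles("CNCCN(C)C"), 1, weighting = "valence")  # 2.564
#' @export
chi <- function(g, order, kind = "path", weighting = "simple") {
  if (order < 0 || order > 6) stop("chi: order must be in 0..6", call. = FALSE)
  kind <- match.arg(kind, c("path", "cluster", "path-cluster", "chain"))
  w <- .vertex_weights(g, weighting)
  if (order == 0L) {
    ok <- w > 0
    return(sum(1 / sqrt(w[ok])))
  }
  subs <- connected_edge_subgraphs(g, order)
  total <- 0
  for (edges in subs) {
    if (classify_subgraph(g, edges) != kind) next
    verts <- unique(c(g$bonds$i[edges], g$bonds$j[edges]))
    wv <- w[verts]
    if (any(wv <= 0)) next
    total <- total + 1 / sqrt(prod(wv))
  }
  total
}

#' Balaban distance-sum connectivity index J
#'
#' `J = (q / (mu + 1)) * sum over edges of (s_i * s_j)^(-1/2)` where `s_i`
#' is the distance sum of vertex `i` on the simple graph, `q` the edge count
#' and `mu` the cyclomatic number.  Defined as 0 for the one-vertex graph.
#'
#' @param g a connected `molgraph`.
#' @examples
#' balaban_j(parse_smiles("CNCCN(C)C"))  # 2.678
#' @export
balaban_j <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(0)
  if (!is_connected(g)) stop("balaban_j: graph is disconnected", call. = FALSE)
  s <- rowSums(distance_matrix(g))
  q <- n_bonds(g); mu <- cyclomatic(g)
  terms <- 1 / sqrt(s[g$bonds$i] * s[g$bonds$j])
  q / (mu + 1) * sum(terms)
}

#' Kier shape (kappa) indices
#'
#' Standard Kier formulas `1k = n (n-1)^2 / (1P)^2` and
#' `2k = (n-1) (n-2)^2 / (2P)^2`, with `mP` the number of paths of length
#' `m`.  The formula is exposed unmodified; the weight-scheme registry
#' applies its own recorded calibration factor (see [weight_schemes()]).
#'
#' @param g a `molgraph`.
#' @param order 1 or 2.
#' @examples
#' kappa_index(parse_smiles("CCCCC"), 2)  # 4
#' @export
kappa_index <- function(g, order) {
  if (!order %in% c(1L, 2L)) stop("kappa_index: order must be 1 or 2", call. = FALSE)
  n <- n_atoms(g)
  if (n < order + 1L)
    stop("kappa_index: graph too small (n = ", n, ") for order ", order, call. = FALSE)
  pm <- unname(path_counts(g, order)[order + 1L])
  if (pm == 0) return(0)
  if (order == 1L) n * (n - 1)^2 / pm^2 else (n - 1) * (n - 2)^2 / pm^2
}

#' Zagreb indices
#'
#' `M1 = sum of squared degrees`; `M2 = sum over edges of the degree
#' product`.
#'
#' @param g a `molgraph`.
#' @param which 1 or 2.
#' @export
zagreb <- function(g, which) {
  if (!which %in% c(1L, 2L)) stop("zagreb: which must be 1 or 2", call. = FALSE)
  d <- degrees(g)
  if (which == 1L) sum(d^2)
  else if (n_bonds(g) == 0L) 0
  else sum(d[g$bonds$i] * d[g$bonds$j])
}

#' Simple-path counts by length
#'
#' Counts undirected simple paths of each length `0..max_order` (each path
#' counted once; length 0 paths are the vertices).
#'
#' @param g a `molgraph`.
#' @param max_order maximum path length, at most 10.
#' @return numeric vector of length `max_order + 1` named `P0`, `P1`, ...
#' @export
path_counts <- function(g, max_order = 6L) {
  if (max_order > 10L) stop("path_counts: max_order must be <= 10", call. = FALSE)
  .gmemo(g, paste0("path_counts_", max_order), function() .path_counts_build(g, max_order))
}

.path_counts_build <- function(g, max_order) {
  n <- n_atoms(g)
  counts <- numeric(max_order + 1L)
  counts[1L] <- n
  if (max_order >= 1L && n_bonds(g) > 0L) {
    adj <- vector("list", n)
    for (r in seq_len(n_bonds(g))) {
      adj[[g$bonds$i[r]]] <- c(adj[[g$bonds$i[r]]], g$bonds$j[r])
      adj[[g$bonds$j[r]]] <- c(adj[[g$bonds$j[r]]], g$bonds$i[r])
    }
    walk <- function(v, visited, len) {
      if (len > 0L) counts[len + 1L] <<- counts[len + 1L] + 1
      if (len == max_order) return(invisible())
      for (w in adj[[v]]) if (!visited[w]) {
        visited[w] <- TRUE
        walk(w, visited, len + 1L)
        visited[w] <- FALSE
      }
    }
    for (v in seq_len(n)) {
      visited <- logical(n); visited[v] <- TRUE
      walk(v, visited, 0L)
    }
    counts[-1L] <- counts[-1L] / 2  # each path seen from both ends
  }
  setNames(counts, paste0("P", 0:max_order))
}

#' Overall connectivity indices
#'
#' The sum, over all connected subgraphs with `order` edges, of the total
#' vertex weight of the subgraph measured in the parent graph (simple,
#' bond-order-weighted, or valence weights).  Order 0 sums the weights of
#' the single-vertex subgraphs, i.e. the total weight of the graph.
#'
#' @param g a `molgraph`.
#' @param order subgraph edge count, 0..6.
#' @param weighting one of `"simple"`, `"bond"`, `"valence"`.
#' @export
overall_connectivity <- function(g, order, weighting = "simple") {
  if (order < 0 || order > 6) stop("overall_connectivity: order must be in 0..6", call. = FALSE)
  w <- .vertex_weights(g, weighting)
  if (order == 0L) return(sum(w))
  subs <- connected_edge_subgraphs(g, order)
  total <- 0
  for (edges in subs) {
    verts <- unique(c(g$bonds$i[edges], g$bonds$j[edges]))
    total <- total + sum(w[verts])
  }
  total
}

# Overall path multiplicity conventions used by the scheme registry.
# OPM   = total number of simple paths of length 1..6.
# V_MPC = valence-weighted total path connectivity: sum over simple paths
#         (length 1..6) of prod(valence delta)^(-1/2).
# B_OPM = overall connectivity with bond-order weights summed over path
#         subgraphs of order 1..6.
overall_path_multiplicity <- function(g, weighting = c("count", "valence", "bond")) {
  weighting <- match.arg(weighting)
  if (n_bonds(g) == 0L) return(0)
  if (weighting == "count")
    return(sum(path_counts(g, min(6L, n_atoms(g) - 1L))[-1L]))
  if (weighting == "valence") {
    total <- 0
    for (ord in seq_len(min(6L, n_bonds(g))))
      total <- total + chi(g, ord, kind = "path", weighting = "valence")
    return(total)
  }
  total <- 0
  w <- bond_degrees(g)
  for (ord in seq_len(min(6L, n_bonds(g)))) {
    for (edges in connected_edge_subgraphs(g, ord)) {
      if (classify_subgraph(g, edges) != "path") next
      verts <- unique(c(g$bonds$i[edges], g$bonds$j[edges]))
      total <- total + sum(w[verts])
    }
  }
  total
}
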