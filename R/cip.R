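# CIP-style substituent ranking and tetrahedral stereo perception.
#
# Ranking implements the atomic-number hierarchical digraph (CIP rule 1a):
# each branch is explored away from the stereocenter; multiple bonds add
# phantom duplicate atoms, implicit hydrogens are Z = 1 leaves, and ring
# closures back onto the current path terminate in a phantom of the revisited
# atom.  Aromatic bonds contribute one phantom per atom carrying the mean
# atomic number of its aromatic neighbours (mancude-ring convention).
# Isotope- and stereo-dependent CIP rules are out of scope.

.branch_key <- function(g, atom, from, path) {
  z <- g$atoms$Z[atom]
  kids <- character(0)
  nb <- n_bonds(g)
  if (nb) {
    arz <- numeric(0)
    for (k in seq_len(nb)) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      if (i != atom && j != atom) next
      other <- if (i == atom) j else i
      o <- g$bonds$order[k]
      if (o == 2) kids <- c(kids, sprintf("%03d", g$atoms$Z[other]))
      if (o == 3) kids <- c(kids, rep(sprintf("%03d", g$atoms$Z[other]), 2))
      if (o == 1.5) arz <- c(arz, g$atoms$Z[other])
      if (other == from) next
      if (other %in% path) {
        kids <- c(kids, sprintf("%03d", g$atoms$Z[other]))  # ring-closure phantom
      } else {
        kids <- c(kids, .branch_key(g, other, atom, c(path, other)))
      }
    }
    if (length(arz)) kids <- c(kids, sprintf("%03d", round(mean(arz))))
  }
  kids <- c(kids, rep("001", g$atoms$attached_h[atom]))
  paste0(sprintf("%03d", z), "(",
         paste(sort(kids, decreasing = TRUE), collapse = ";"), ")")
}

# Priority key of the branch entered through `first` from `center`;
# "H" denotes the implicit-hydrogen substituent.
.substituent_key <- function(g, center, first) {
  if (identical(first, "H")) return("001()")
  .branch_key(g, first, center, c(center, first))
}

#' Rank the substituents at a stereocenter by CIP-style priority
#'
#' @param g a `molgraph`.
#' @param center atom index of the stereocenter.
#' @return list with `neighbors` (atom indices, `"H"` for the implicit
#'   hydrogen) ordered a > b > c > d, and `keys` (their priority keys).
#'   Errors if two substituents tie (the atom is then not a chiral center).
#' @export
cip_rank <- function(g, center) {
  nbrs <- .real_neighbors(g, center)
  subs <- as.list(nbrs)
  if (g$atoms$attached_h[center] == 1L) subs <- c(subs, "H")
  if (length(subs) != 4L)
    stop("atom ", center, " is not a tetrahedral stereocenter ",
         "(has ", length(subs), " substituents)", call. = FALSE)
  keys <- vapply(subs, function(s) .substituent_key(g, center, s), "")
  if (anyDuplicated(keys))
    stop("atom ", center, " is not a chiral center: two substituents have ",
         "identical CIP priority", call. = FALSE)
  ord <- order(keys, decreasing = TRUE)
  list(neighbors = subs[ord], keys = keys[ord])
}

.real_neighbors <- function(g, atom) {
  nb <- integer(0)
  if (n_bonds(g)) for (k in seq_len(n_bonds(g))) {
    if (g$bonds$i[k] == atom) nb <- c(nb, g$bonds$j[k])
    if (g$bonds$j[k] == atom) nb <- c(nb, g$bonds$i[k])
  }
  nb
}

#' Find annotated tetrahedral stereocenters
#'
#' Returns the indices of atoms carrying a tetrahedral stereo mark (`@` or
#' `@@`) with four substituents (counting one implicit hydrogen).
#'
#' @param g a `molgraph`.
#' @export
find_stereocenters <- function(g) {
  marked <- which(g$atoms$stereo %in% c("@", "@@"))
  marked[vapply(marked, function(a)
    length(.real_neighbors(g, a)) + g$atoms$attached_h[a] == 4L, TRUE)]
}

# Parity of the permutation taking the SMILES-written neighbour order to
# CIP priority order; with neighbours written (a,b,c,d), "@@" denotes R.
.perm_parity <- function(p) {
  inv <- 0L
  for (i in seq_along(p)) for (j in seq_along(p)) if (i < j && p[i] > p[j]) inv <- inv + 1L
  inv %% 2L
}

#' Determine the R/S configuration of an annotated stereocenter
#'
#' Combines the tetrahedral mark (`@` anticlockwise / `@@` clockwise as seen
#' from the first written neighbour) with the written neighbour order and
#' the CIP priority ranking.
#'
#' @param g a `molgraph`.
#' @param center atom index carrying a stereo mark.
#' @return `"R"` or `"S"`.
#' @export
configuration <- function(g, center) {
  stereo <- g$atoms$stereo[center]
  if (!stereo %in% c("@", "@@"))
    stop("atom ", center, " carries no tetrahedral stereo mark", call. = FALSE)
  written <- g$nbr_order[[center]]       # 0 marks the bracket hydrogen
  if (length(written) != 4L)
    stop("atom ", center, " does not have four written neighbours", call. = FALSE)
  ranked <- cip_rank(g, center)$neighbors
  ranked_ids <- vapply(ranked, function(s) if (identical(s, "H")) 0L else as.integer(s), 0L)
  pos <- match(ranked_ids, written)
  if (anyNA(pos)) stop("internal error: stereo neighbour mismatch at atom ", center,
                       call. = FALSE)
  parity <- .perm_parity(pos)
  if (stereo == "@@") { if (parity == 0L) "R" else "S" }
  else { if (parity == 0L) "S" else "R" }
}
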