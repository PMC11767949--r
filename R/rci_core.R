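# The relative chirality index (RCI): CIP-ranked substituent fragments at a
# stereocenter, each weighted by a topological index of the fragment graph,
# combined so that R and S isomers receive different values.

#' R-isomer relative chirality index
#'
#' `rci_R = 3 da + 2 da db + da db dc + da db dc dd`, the telescoping sum of
#' the partial products of the CIP-ordered substituent weights
#' `(da, db, dc, dd)`, `da` belonging to the highest-priority substituent.
#'
#' @param w numeric vector of four nonnegative weights `(da, db, dc, dd)`.
#' @examples
#' rci_R(c(2.678, 3.298, 3.033, 0))  # 52.48
#' @export
rci_R <- function(w) {
  .check_weights(w)
  unname(3 * w[1] + 2 * w[1] * w[2] + w[1] * w[2] * w[3] + w[1] * w[2] * w[3] * w[4])
}

#' S-isomer relative chirality index
#'
#' `rci_S = 3 da + 2 da dc + da db dc + da db dc dd`; the mirror image of
#' [rci_R()] with the roles of the b- and c-ranked substituents exchanged in
#' the pairwise term.
#'
#' @param w numeric vector of four nonnegative weights `(da, db, dc, dd)`.
#' @examples
#' rci_S(c(2.678, 3.298, 3.033, 0))  # 51.07
#' @export
rci_S <- function(w) {
  .check_weights(w)
  unname(3 * w[1] + 2 * w[1] * w[3] + w[1] * w[2] * w[3] + w[1] * w[2] * w[3] * w[4])
}

.check_weights <- function(w) {
  if (length(w) != 4L || !is.numeric(w) || anyNA(w))
    stop("weights must be four numbers (da, db, dc, dd)", call. = FALSE)
  if (any(w < 0)) stop("substituent weights must be nonnegative", call. = FALSE)
  invisible(w)
}

#' Root-mean-square aggregation over stereocenters
#'
#' A molecule with `N` stereocenters gets the single descriptor
#' `sqrt(mean(RCI_i^2))`; for `N = 1` this is the per-center value itself.
#'
#' @param values per-center RCI values, all nonnegative.
#' @export
rci_rms <- function(values) {
  if (!length(values)) stop("rci_rms: empty value list", call. = FALSE)
  if (any(values < 0)) stop("rci_rms: values must be nonnegative", call. = FALSE)
  sqrt(mean(values^2))
}

# ---- fragment extraction -------------------------------------------------

# Induced fragment: the chiral carbon plus the branch entered through
# `first`, with only the center-first bond kept at the center.
.build_fragment <- function(g, center, first) {
  if (identical(first, "H")) {
    frag <- parse_smiles("C")
    return(list(graph = frag, smiles = "C", is_hydrogen = TRUE, atoms = integer(0)))
  }
  # branch atoms: reachable from `first` without passing through center
  n <- n_atoms(g)
  keep <- logical(n); keep[first] <- TRUE
  queue <- first
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in .real_neighbors(g, v)) {
      if (w == center || keep[w]) next
      keep[w] <- TRUE; queue <- c(queue, w)
    }
  }
  members <- c(center, which(keep))
  idx <- match(seq_len(n), members)  # old -> new
  sel <- with(g$bonds, (keep[i] & keep[j]) | (i == center & j == first) |
                       (j == center & i == first))
  bonds <- g$bonds[sel, , drop = FALSE]
  bonds <- data.frame(i = idx[bonds$i], j = idx[bonds$j], order = bonds$order)
  atoms <- g$atoms[members, , drop = FALSE]
  rownames(atoms) <- NULL
  # the center loses its other three bonds: refill with hydrogens; drop stereo
  atoms$stereo[1] <- ""
  atoms$attached_h[1] <- 3L
  frag <- structure(list(atoms = atoms, bonds = bonds, nbr_order = NULL,
                         smiles = NA_character_,
                         cache = new.env(parent = emptyenv())), class = "molgraph")
  frag$smiles <- mol_to_smiles(frag, root = 1L)
  list(graph = frag, smiles = frag$smiles, is_hydrogen = FALSE,
       atoms = which(keep))
}

#' Extract the four CIP-ranked substituent fragments at a stereocenter
#'
#' Cuts the four bonds at the stereocenter and returns each substituent as a
#' fragment graph that includes the chiral carbon as its root (so the
#' connectivity of the attachment vertex is preserved, the chiral carbon
#' being refilled with hydrogens).  Priorities come from the CIP-style
#' ranking, or from a user-supplied ordering.
#'
#' @param g a `molgraph` with stereo annotations.
#' @param center stereocenter atom index.
#' @param priorities optional integer vector of four atom indices (0 for the
#'   implicit hydrogen) in priority order a, b, c, d, overriding CIP.
#' @return an object of class `chiral_center`: list with `center`,
#'   `configuration` (`"R"`/`"S"`), and `fragments`, a list of four entries
#'   (ranks `a` to `d`) each holding `rank`, `smiles`, `graph`,
#'   `is_hydrogen`.
#' @export
extract_fragments <- function(g, center, priorities = NULL) {
  if (!center %in% find_stereocenters(g))
    stop("atom ", center, " is not an annotated tetrahedral stereocenter",
         call. = FALSE)
  if (is.null(priorities)) {
    ranked <- cip_rank(g, center)$neighbors
  } else {
    if (length(priorities) != 4L)
      stop("priorities must list four substituents", call. = FALSE)
    ranked <- lapply(priorities, function(p) if (p == 0L) "H" else as.integer(p))
  }
  # substituent branches must not rejoin: atom sets must be disjoint
  frags <- lapply(ranked, function(s) .build_fragment(g, center, s))
  branch_atoms <- unlist(lapply(frags, `[[`, "atoms"))
  if (anyDuplicated(branch_atoms))
    stop("substituents at atom ", center, " form a ring through the center",
         call. = FALSE)
  names(frags) <- c("a", "b", "c", "d")
  for (r in seq_along(frags)) frags[[r]]$rank <- names(frags)[r]
  structure(list(center = center,
                 configuration = configuration(g, center),
                 fragments = frags),
            class = "chiral_center")
}

#' @export
print.chiral_center <- function(x, ...) {
  cat("<chiral_center> atom ", x$center, " (", x$configuration, ")\n", sep = "")
  for (f in x$fragments)
    cat("  ", f$rank, ": ", if (f$is_hydrogen) "H" else f$smiles, "\n", sep = "")
  invisible(x)
}

# ---- SMILES writer (fragments; no stereo) --------------------------------

#' Write a molecular graph back to SMILES
#'
#' Depth-first writer used to emit substituent fragments rooted at the
#' chiral carbon.  Stereo marks are not written; aromatic atoms are written
#' lowercase; charges and isotopes use bracket atoms.
#'
#' @param g a `molgraph`.
#' @param root atom index to start from.
#' @export
mol_to_smiles <- function(g, root = 1L) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  if (n_bonds(g)) for (k in seq_len(n_bonds(g))) {
    adj[[g$bonds$i[k]]] <- rbind(adj[[g$bonds$i[k]]], c(g$bonds$j[k], g$bonds$order[k], k))
    adj[[g$bonds$j[k]]] <- rbind(adj[[g$bonds$j[k]]], c(g$bonds$i[k], g$bonds$order[k], k))
  }
  visited <- logical(n)
  used_edge <- logical(max(1L, n_bonds(g)))
  ring_id <- 0L
  ring_at <- vector("list", n)  # pending ring-closure digits per atom

  # pre-walk to assign ring closures (back edges of the DFS tree)
  parent_edge <- integer(n)
  order_visit <- integer(0)
  stack <- root; visited[root] <- TRUE
  dfs <- function(v) {
    order_visit <<- c(order_visit, v)
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      w <- adj[[v]][r, 1]; e <- adj[[v]][r, 3]
      if (used_edge[e]) next
      if (visited[w]) {  # back edge -> ring closure
        used_edge[e] <<- TRUE
        ring_id <<- ring_id + 1L
        tok <- if (ring_id > 9L) paste0("%", ring_id) else as.character(ring_id)
        bsym <- .bond_symbol(g, v, w, adj[[v]][r, 2])
        ring_at[[v]] <<- c(ring_at[[v]], paste0(bsym, tok))
        ring_at[[w]] <<- c(ring_at[[w]], paste0(bsym, tok))
      } else {
        used_edge[e] <<- TRUE; visited[w] <<- TRUE; parent_edge[w] <<- e
        dfs(w)
      }
    }
  }
  dfs(root)

  visited2 <- logical(n)
  emit <- function(v, bond_in) {
    visited2[v] <<- TRUE
    out <- paste0(bond_in, .atom_token(g, v), paste(ring_at[[v]], collapse = ""))
    kids <- list()
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      w <- adj[[v]][r, 1]
      if (visited2[w] || parent_edge[w] != adj[[v]][r, 3]) next
      kids[[length(kids) + 1L]] <- emit(w, .bond_symbol(g, v, w, adj[[v]][r, 2]))
    }
    if (length(kids) > 1L)
      out <- paste0(out, paste0("(", unlist(kids[-length(kids)]), ")", collapse = ""),
                    kids[[length(kids)]])
    else if (length(kids) == 1L) out <- paste0(out, kids[[1L]])
    out
  }
  emit(root, "")
}

.bond_symbol <- function(g, v, w, order) {
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) {
    if (g$atoms$aromatic[v] && g$atoms$aromatic[w]) return("") else return(":")
  }
  ""
}

.atom_token <- function(g, v) {
  el <- g$atoms$element[v]
  tok <- if (g$atoms$aromatic[v]) tolower(el) else el
  if (g$atoms$charge[v] != 0L || !is.na(g$atoms$isotope[v])) {
    ch <- g$atoms$charge[v]
    chs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
           else paste0(if (ch > 0) "+" else "-", abs(ch))
    iso <- if (is.na(g$atoms$isotope[v])) "" else g$atoms$isotope[v]
    h <- g$atoms$attached_h[v]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    return(paste0("[", iso, tok, hs, chs, "]"))
  }
  tok
}
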