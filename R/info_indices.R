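# Basak information-content descriptors from neighbourhood-equivalence
# partitions of the atoms.

#' Neighbourhood-equivalence partition of the atoms
#'
#' Order-0 classes group atoms by element; order-r classes group atoms whose
#' rooted neighbourhoods of radius r are label-isomorphic, obtained by r
#' rounds of iterative refinement (each round relabels an atom by its own
#' class together with the sorted multiset of (bond order, neighbour class)
#' pairs).  Refinement guarantees the order-(r+1) partition refines the
#' order-r partition.
#'
#' @param g a `molgraph`, usually either the parsed graph (H-suppressed
#'   view) or [h_filled()] of it (H-filled view, the default for the
#'   unprefixed IC descriptors).
#' @param r neighbourhood radius, 0..6.
#' @return an object of class `nbr_partition`: list with `classes` (integer
#'   class id per atom), `r`, `n`, and `degenerate` (TRUE when the partition
#'   stopped refining before radius `r`).
#' @export
neighborhood_partition <- function(g, r) {
  if (r < 0 || r > 6) stop("neighborhood_partition: r must be in 0..6", call. = FALSE)
  .gmemo(g, paste0("partition_", r), function() .partition_build(g, r))
}

.partition_build <- function(g, r) {
  n <- n_atoms(g)
  labels <- match(g$atoms$element, sort(unique(g$atoms$element)))
  nbrs <- vector("list", n)
  if (n_bonds(g)) for (k in seq_len(n_bonds(g))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]; o <- g$bonds$order[k]
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
  }
  degenerate <- FALSE
  if (r > 0) for (round in seq_len(r)) {
    keys <- vapply(seq_len(n), function(a) {
      nb <- nbrs[[a]]
      nbkey <- if (is.null(nb)) "" else
        paste(sort(paste0(nb[, 2], ":", labels[nb[, 1]])), collapse = ",")
      paste0(labels[a], "|", nbkey)
    }, "")
    new_labels <- match(keys, sort(unique(keys)))
    if (length(unique(new_labels)) == length(unique(labels)))
      degenerate <- TRUE  # stopped refining at or before radius r
    labels <- new_labels
  }
  structure(list(classes = labels, r = r, n = n, degenerate = degenerate),
            class = "nbr_partition")
}

#' Mean information content of a partition (bits)
#'
#' Shannon entropy of the class-size distribution:
#' `IC = -sum_k (n_k/n) log2(n_k/n)`.
#'
#' @param p a `nbr_partition` (or a bare integer class vector).
#' @export
ic <- function(p) {
  classes <- if (inherits(p, "nbr_partition")) p$classes else p
  if (!length(classes)) stop("ic: empty partition", call. = FALSE)
  f <- as.numeric(table(classes)) / length(classes)
  -sum(f * log2(f))
}

#' Structural, complementary, total and bond information content
#'
#' `SIC = IC / log2(n)`; `CIC = log2(n) - IC`; `TIC = n * IC`; `BIC` is the
#' Shannon entropy of the bond classes (a bond's class is its order together
#' with the unordered pair of its endpoint classes) normalised by `log2(q)`.
#' `SIC`/`CIC` require `n >= 2`; `BIC` is 0 when `q < 2`.
#'
#' @param p a `nbr_partition`.
#' @param g the `molgraph` the partition was computed on (needed for `BIC`).
#' @return named list with elements `SIC`, `CIC`, `TIC`, `BIC`.
#' @export
ic_variants <- function(p, g) {
  n <- p$n
  icv <- ic(p)
  if (n < 2) stop("ic_variants: SIC/CIC require n >= 2", call. = FALSE)
  q <- n_bonds(g)
  bic <- 0
  if (q >= 2) {
    cls <- p$classes
    ends <- cbind(cls[g$bonds$i], cls[g$bonds$j])
    keys <- paste0(g$bonds$order, "|", pmin(ends[, 1], ends[, 2]), ":",
                   pmax(ends[, 1], ends[, 2]))
    f <- as.numeric(table(keys)) / q
    bic <- -sum(f * log2(f)) / log2(q)
  }
  list(SIC = icv / log2(n), CIC = log2(n) - icv, TIC = n * icv, BIC = bic)
}
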