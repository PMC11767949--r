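#' @importFrom stats cor lm pf predict coef residuals var sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Element tables for the supported organic subset.  Zv = valence electrons.
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  Z      = c(1, 5, 6, 7, 8, 9, 15, 16, 17, 35, 53),
  Zv     = c(1, 3, 4, 5, 6, 7, 5, 6, 7, 7, 7),
  stringsAsFactors = FALSE
)

# Standard valences used for implicit hydrogen filling (lowest first).
.VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
                  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

.element_info <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (is.na(i)) {
    stop("unsupported element '", symbol, "'; supported: ",
         paste(.ELEMENTS$symbol, collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[i, ]
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lowercase atoms, branches, ring-closure digits (including `%nn`), bond
#' symbols `- = # :`, and bracket atoms with isotope, tetrahedral stereo
#' marks (`@`, `@@`), explicit hydrogen counts and formal charges.  Implicit
#' hydrogens are filled against the lowest standard valence that accommodates
#' the bond-order sum (aromatic bonds count 1.5).  Atom numbering follows
#' SMILES token order.
#'
#' @param smiles a single SMILES string.
#' @return An object of class `molgraph`: a list with `atoms` (data frame
#'   with columns `element`, `aromatic`, `attached_h`, `charge`, `isotope`,
#'   `stereo`, `Z`, `Zv`), `bonds` (data frame `i`, `j`, `order`; aromatic
#'   bonds have order 1.5), `nbr_order` (per-atom neighbour lists in written
#'   order, with `0` marking an implicit hydrogen inside a bracket — used for
#'   stereo perception), and `smiles` (the input).
#' @examples
#' g <- parse_smiles("CNCCN(C)C")
#' n_atoms(g)
#' degrees(g)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("'smiles' must be a single string", call. = FALSE)
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES string", call. = FALSE)

  chars <- strsplit(s, "")[[1]]
  np <- length(chars)

  atoms <- list()      # each: list(element, aromatic, h_explicit, charge, isotope, stereo)
  bonds <- list()      # each: c(i, j, order)
  nbr <- list()        # neighbour order per atom; 0 = bracket hydrogen slot
  stack <- integer(0)  # branch stack
  prev <- 0L
  pending <- NA_real_  # bond order carried by a bond symbol
  rings <- list()      # open ring bonds: key -> list(atom, order, slot)

  add_atom <- function(element, aromatic, h_explicit = NA_integer_,
                       charge = 0L, isotope = NA_integer_, stereo = "") {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         h_explicit = h_explicit, charge = charge,
                                         isotope = isotope, stereo = stereo)
    nbr[[length(atoms)]] <<- integer(0)
    length(atoms)
  }
  add_bond <- function(i, j, order) {
    bonds[[length(bonds) + 1L]] <<- c(i, j, order)
    nbr[[i]] <<- c(nbr[[i]], j)
    nbr[[j]] <<- c(nbr[[j]], i)
  }
  bond_order_between <- function(i, j, pend) {
    if (!is.na(pend)) return(pend)
    if (atoms[[i]]$aromatic && atoms[[j]]$aromatic) 1.5 else 1
  }

  k <- 1L
  while (k <= np) {
    ch <- chars[k]
    if (ch == " ") { k <- k + 1L; next }
    if (ch == "(") {
      if (prev == 0L) stop("SMILES parse error: '(' before any atom in '", s, "'", call. = FALSE)
      stack <- c(stack, prev); k <- k + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) stop("SMILES parse error: unmatched ')' in '", s, "'", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; k <- k + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)
      k <- k + 1L; next
    }
    if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (k + 2L > np) stop("SMILES parse error: truncated '%' ring closure", call. = FALSE)
        key <- paste0(chars[k + 1L], chars[k + 2L]); k <- k + 3L
      } else { key <- ch; k <- k + 1L }
      if (prev == 0L) stop("SMILES parse error: ring digit before any atom", call. = FALSE)
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        ord <- if (!is.na(pending)) pending
               else if (!is.na(op$order)) op$order
               else if (atoms[[prev]]$aromatic && atoms[[op$atom]]$aromatic) 1.5 else 1
        bonds[[length(bonds) + 1L]] <- c(op$atom, prev, ord)
        # fill the reserved slot on the opening atom; append on the closing atom
        nbr[[op$atom]][op$slot] <- prev
        nbr[[prev]] <- c(nbr[[prev]], op$atom)
        rings[[key]] <- NULL
      } else {
        nbr[[prev]] <- c(nbr[[prev]], NA_integer_)  # reserve slot in written order
        rings[[key]] <- list(atom = prev, order = pending, slot = length(nbr[[prev]]))
      }
      pending <- NA_real_
      next
    }
    if (ch == "[") {
      close <- k
      while (close <= np && chars[close] != "]") close <- close + 1L
      if (close > np) stop("SMILES parse error: unterminated '[' in '", s, "'", call. = FALSE)
      body <- paste(chars[(k + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)(Cl|Br|[BCNOPSFI]|[bcnops])(@{1,2})?(H([0-9]*))?([+-]+[0-9]*|[+-][0-9]*)?$",
        body))[[1]]
      if (length(m) == 0L)
        stop("SMILES parse error: cannot read bracket atom '[", body, "]'", call. = FALSE)
      isotope <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
      sym <- m[3]; aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(sym) else sym
      stereo <- m[4]
      hexp <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      charge <- 0L
      if (nzchar(m[7])) {
        cstr <- m[7]
        if (grepl("^[+-]+$", cstr)) {
          charge <- (if (substr(cstr, 1, 1) == "+") 1L else -1L) * nchar(cstr)
        } else {
          sign <- if (substr(cstr, 1, 1) == "+") 1L else -1L
          num <- sub("^[+-]", "", cstr)
          charge <- sign * (if (nzchar(num)) as.integer(num) else 1L)
        }
      }
      idx <- add_atom(element, aromatic, hexp, charge, isotope, stereo)
      if (prev != 0L) add_bond(prev, idx, bond_order_between(prev, idx, pending))
      if (hexp > 0L) nbr[[idx]] <- c(nbr[[idx]], rep(0L, hexp))  # H slots in written order
      prev <- idx; pending <- NA_real_; k <- close + 1L; next
    }
    # organic-subset atom (two-letter first)
    two <- if (k < np) paste0(ch, chars[k + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE)
      if (prev != 0L) add_bond(prev, idx, bond_order_between(prev, idx, pending))
      prev <- idx; pending <- NA_real_; k <- k + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I", "b", "c", "n", "o", "p", "s")) {
      aromatic <- ch %in% c("b", "c", "n", "o", "p", "s")
      idx <- add_atom(toupper(ch), aromatic)
      if (prev != 0L) add_bond(prev, idx, bond_order_between(prev, idx, pending))
      prev <- idx; pending <- NA_real_; k <- k + 1L; next
    }
    stop("SMILES parse error in '", s, "': unexpected token '", ch,
         "' at position ", k, call. = FALSE)
  }
  if (length(stack) > 0L) stop("SMILES parse error: unclosed '(' in '", s, "'", call. = FALSE)
  if (length(rings) > 0L)
    stop("SMILES parse error: unclosed ring bond(s) ",
         paste(names(rings), collapse = ", "), " in '", s, "'", call. = FALSE)
  if (length(atoms) == 0L) stop("SMILES parse error: no atoms in '", s, "'", call. = FALSE)

  n <- length(atoms)
  if (length(bonds)) {
    bmat <- do.call(rbind, bonds)
    bonds_df <- data.frame(i = as.integer(bmat[, 1]), j = as.integer(bmat[, 2]),
                           order = as.numeric(bmat[, 3]))
  } else {
    bonds_df <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }

  # bond-order sums per atom (aromatic = 1.5)
  bo_sum <- numeric(n)
  if (nrow(bonds_df)) for (r in seq_len(nrow(bonds_df))) {
    bo_sum[bonds_df$i[r]] <- bo_sum[bonds_df$i[r]] + bonds_df$order[r]
    bo_sum[bonds_df$j[r]] <- bo_sum[bonds_df$j[r]] + bonds_df$order[r]
  }

  element <- vapply(atoms, `[[`, "", "element")
  aromatic <- vapply(atoms, `[[`, FALSE, "aromatic")
  h_explicit <- vapply(atoms, `[[`, NA_integer_, "h_explicit")
  charge <- vapply(atoms, `[[`, 0L, "charge")
  isotope <- vapply(atoms, `[[`, NA_integer_, "isotope")
  stereo <- vapply(atoms, `[[`, "", "stereo")

  attached_h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(h_explicit[a])) { attached_h[a] <- h_explicit[a]; next }
    vals <- .VALENCES[[element[a]]]
    if (is.null(vals)) { attached_h[a] <- 0L; next }
    need <- ceiling(bo_sum[a])
    v <- vals[vals >= need]
    attached_h[a] <- if (length(v)) as.integer(v[1] - need) else 0L
  }

  info <- .ELEMENTS[match(element, .ELEMENTS$symbol), ]
  if (anyNA(info$Z))
    stop("unsupported element in '", s, "'", call. = FALSE)

  g <- structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       attached_h = attached_h, charge = charge,
                       isotope = isotope, stereo = stereo,
                       Z = info$Z, Zv = info$Zv, stringsAsFactors = FALSE),
    bonds = bonds_df,
    nbr_order = nbr,
    smiles = s,
    cache = new.env(parent = emptyenv())), class = "molgraph")
  if (n > 1L && !is_connected(g))
    stop("disconnected SMILES input '", s, "': a single connected component is required",
         call. = FALSE)
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, "\n", sep = "")
  cat("  ", n_atoms(x), " heavy atoms, ", n_bonds(x), " bonds, ",
      sum(x$atoms$attached_h), " implicit H, mu = ", cyclomatic(x), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms
#' @param g a `molgraph`.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Number of bonds (edges of the simple graph)
#' @param g a `molgraph`.
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' Cyclomatic number mu = q - n + 1
#' @param g a `molgraph`.
#' @export
cyclomatic <- function(g) n_bonds(g) - n_atoms(g) + 1L

#' Adjacency matrix of the simple (bond-order-ignoring) graph
#' @param g a `molgraph`.
#' @export
adjacency_matrix <- function(g) {
  n <- n_atoms(g)
  A <- matrix(0L, n, n)
  if (n_bonds(g)) for (r in seq_len(n_bonds(g))) {
    A[g$bonds$i[r], g$bonds$j[r]] <- 1L
    A[g$bonds$j[r], g$bonds$i[r]] <- 1L
  }
  A
}

.as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (n_bonds(g)) g$bonds[, c("i", "j")] else data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

is_connected <- function(g) {
  if (n_atoms(g) <= 1L) return(TRUE)
  igraph::is_connected(.as_igraph(g))
}

#' Topological distance matrix
#'
#' Unweighted shortest-path lengths on the simple graph (bond orders are
#' ignored, aromatic bonds count as single edges).
#'
#' @param g a `molgraph`.
#' @return integer matrix `D` with `D[i, j]` = shortest-path length.
#' @export
distance_matrix <- function(g) {
  if (n_atoms(g) == 1L) return(matrix(0L, 1, 1))
  if (!is_connected(g)) stop("distance_matrix: graph is disconnected", call. = FALSE)
  .gmemo(g, "distance_matrix", function() {
    D <- igraph::distances(.as_igraph(g))
    dimnames(D) <- NULL
    storage.mode(D) <- "integer"
    D
  })
}

#' Vertex degrees on the simple graph
#' @param g a `molgraph`.
#' @export
degrees <- function(g) {
  n <- n_atoms(g)
  d <- integer(n)
  if (n_bonds(g)) for (r in seq_len(n_bonds(g))) {
    d[g$bonds$i[r]] <- d[g$bonds$i[r]] + 1L
    d[g$bonds$j[r]] <- d[g$bonds$j[r]] + 1L
  }
  d
}

# bond-order-weighted degrees (aromatic = 1.5); used by "B"-prefixed indices
bond_degrees <- function(g) {
  n <- n_atoms(g)
  d <- numeric(n)
  if (n_bonds(g)) for (r in seq_len(n_bonds(g))) {
    d[g$bonds$i[r]] <- d[g$bonds$i[r]] + g$bonds$order[r]
    d[g$bonds$j[r]] <- d[g$bonds$j[r]] + g$bonds$order[r]
  }
  d
}

.check_neutral <- function(g, what) {
  if (any(g$atoms$charge != 0L) || any(!is.na(g$atoms$isotope)))
    stop(what, ": charged or isotopically labelled atoms are not supported ",
         "by the index modules", call. = FALSE)
  invisible(g)
}

#' Kier-Hall valence delta for one atom
#'
#' For second-row atoms `delta_v = Zv - h`; for higher rows
#' `delta_v = (Zv - h) / (Z - Zv - 1)`, where `Zv` is the valence electron
#' count, `Z` the atomic number and `h` the attached hydrogen count.
#'
#' @param element chemical symbol.
#' @param attached_h hydrogen count.
#' @return the valence delta (nonnegative real).
#' @examples
#' valence_delta("N", 1)  # 4
#' valence_delta("S", 0)  # 6/9
#' @export
valence_delta <- function(element, attached_h) {
  info <- .element_info(element)
  if (attached_h < 0) stop("attached_h must be >= 0", call. = FALSE)
  if (info$Z <= 10) info$Zv - attached_h
  else (info$Zv - attached_h) / (info$Z - info$Zv - 1)
}

#' Valence deltas for every atom of a graph
#' @param g a `molgraph`.
#' @export
valence_deltas <- function(g) {
  .check_neutral(g, "valence_deltas")
  vapply(seq_len(n_atoms(g)), function(a)
    valence_delta(g$atoms$element[a], g$atoms$attached_h[a]), numeric(1))
}

# per-graph memoization (graphs are immutable once built; the cache
# environment survives list copying by reference)
.gmemo <- function(g, key, fun) {
  if (is.null(g$cache)) return(fun())
  if (!is.null(g$cache[[key]])) return(g$cache[[key]])
  g$cache[[key]] <- fun()
  g$cache[[key]]
}

#' Hydrogen-filled view of a molecular graph
#'
#' Expands every implicit hydrogen into an explicit vertex, as required by
#' the information-content descriptors computed on the H-filled graph.
#'
#' @param g a `molgraph`.
#' @return a `molgraph` whose vertex count is the heavy-atom count plus the
#'   total hydrogen count; hydrogens are appended after the heavy atoms.
#' @export
h_filled <- function(g) {
  .gmemo(g, "h_filled", function() .h_filled_build(g))
}

.h_filled_build <- function(g) {
  nh <- n_atoms(g)
  hs <- g$atoms$attached_h
  total <- nh + sum(hs)
  element <- c(g$atoms$element, rep("H", sum(hs)))
  aromatic <- c(g$atoms$aromatic, rep(FALSE, sum(hs)))
  bonds <- g$bonds
  nxt <- nh
  for (a in seq_len(nh)) {
    if (hs[a] > 0L) for (k in seq_len(hs[a])) {
      nxt <- nxt + 1L
      bonds <- rbind(bonds, data.frame(i = a, j = nxt, order = 1))
    }
  }
  info <- .ELEMENTS[match(element, .ELEMENTS$symbol), ]
  structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       attached_h = 0L, charge = 0L, isotope = NA_integer_,
                       stereo = "", Z = info$Z, Zv = info$Zv,
                       stringsAsFactors = FALSE),
    bonds = bonds,
    nbr_order = NULL,
    smiles = paste0(g$smiles, " [H-filled]"),
    cache = new.env(parent = emptyenv())), class = "molgraph")
}

#' Read a SMILES line file
#'
#' Lines are `ID<TAB>SMILES`; `#` starts a comment; blank lines are skipped.
#'
#' @param path file path.
#' @return data frame with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(data.frame(id = character(0), smiles = character(0)))
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, 0L) < 2L
  if (any(bad))
    stop("malformed SMILES line(s): ", paste(lines[bad], collapse = "; "), call. = FALSE)
  data.frame(id = vapply(parts, `[[`, "", 1L),
             smiles = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
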