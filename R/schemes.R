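# Registry of delta-weighting schemes: each scheme maps a substituent
# fragment graph to a nonnegative weight.  The rank-d hydrogen substituent
# always has weight 0 by convention, applied uniformly before any scheme is
# evaluated.
#
# Classes mirror the descriptor families: topo-structural (TS), topochemical
# (TC), shape, overall connectivity (OC), path counts, information content
# on the H-filled graph (IC...) and on the H-suppressed graph (H-prefixed),
# and the triplet grammar.  The kappa schemes carry a recorded calibration
# factor of 0.5 on the standard Kier formula.

.KAPPA_CALIBRATION <- 0.5

.scheme_cache <- new.env(parent = emptyenv())

.scheme_table <- function() {
  if (!is.null(.scheme_cache$entries)) return(.scheme_cache$entries)
  entries <- list()
  add <- function(name, class, fun) entries[[length(entries) + 1L]] <<-
    list(name = name, class = class, fun = fun)

  add("J", "topo-structural", function(g) balaban_j(g))
  add("M1", "topo-structural", function(g) zagreb(g, 1L))
  add("M2", "topo-structural", function(g) zagreb(g, 2L))
  for (o in 0:6) local({
    oo <- o
    add(paste0("X", oo), "topo-structural",
        function(g) chi(g, oo, "path", "simple"))
    add(paste0("XV", oo), "topochemical",
        function(g) chi(g, oo, "path", "valence"))
  })
  for (o in 1:6) local({
    oo <- o
    add(paste0("XB", oo), "topochemical",
        function(g) chi(g, oo, "path", "bond"))
  })
  for (o in 3:5) local({
    oo <- o
    add(paste0("SC", oo), "topo-structural",
        function(g) chi(g, oo, "cluster", "simple"))
    add(paste0("BC", oo), "topochemical",
        function(g) chi(g, oo, "cluster", "bond"))
  })
  for (o in 4:6) local({
    oo <- o
    add(paste0("SPC", oo), "topo-structural",
        function(g) chi(g, oo, "path-cluster", "simple"))
    add(paste0("BPC", oo), "topochemical",
        function(g) chi(g, oo, "path-cluster", "bond"))
  })
  for (o in 1:6) local({
    oo <- o
    add(paste0("P", oo), "path-count",
        function(g) as.numeric(path_counts(g, oo)[oo + 1L]))
  })
  add("OPM", "path-count", function(g) overall_path_multiplicity(g, "count"))
  add("V_MPC", "path-count", function(g) overall_path_multiplicity(g, "valence"))
  add("B_OPM", "path-count", function(g) overall_path_multiplicity(g, "bond"))
  for (o in 0:4) local({
    oo <- o
    add(paste0("OC", oo), "overall-connectivity",
        function(g) overall_connectivity(g, oo, "simple"))
    add(paste0("BOC", oo), "overall-connectivity",
        function(g) overall_connectivity(g, oo, "bond"))
  })
  add("K1", "shape", function(g)
    if (n_atoms(g) < 2L) 0 else .KAPPA_CALIBRATION * kappa_index(g, 1L))
  add("K2", "shape", function(g)
    if (n_atoms(g) < 3L) 0 else .KAPPA_CALIBRATION * kappa_index(g, 2L))

  ic_funs <- function(prefix, view_fun, cls) {
    for (o in 0:5) local({
      oo <- o
      add(paste0(prefix, "IC", oo), cls, function(g) {
        gv <- view_fun(g); ic(neighborhood_partition(gv, oo))
      })
      add(paste0(prefix, "SIC", oo), cls, function(g) {
        gv <- view_fun(g)
        if (n_atoms(gv) < 2L) return(0)
        p <- neighborhood_partition(gv, oo); ic_variants(p, gv)$SIC
      })
      add(paste0(prefix, "CIC", oo), cls, function(g) {
        gv <- view_fun(g)
        if (n_atoms(gv) < 2L) return(0)
        p <- neighborhood_partition(gv, oo); ic_variants(p, gv)$CIC
      })
      add(paste0(prefix, "TIC", oo), cls, function(g) {
        gv <- view_fun(g); n_atoms(gv) * ic(neighborhood_partition(gv, oo))
      })
      add(paste0(prefix, "BIC", oo), cls, function(g) {
        gv <- view_fun(g)
        if (n_atoms(gv) < 2L) return(0)
        p <- neighborhood_partition(gv, oo); ic_variants(p, gv)$BIC
      })
    })
  }
  ic_funs("", h_filled, "information-content")          # default: H-filled view
  ic_funs("H", identity, "information-content-Hsup")    # H-suppressed view

  tc <- triplet_codes()
  for (r in seq_len(nrow(tc))) local({
    row <- tc[r, ]
    add(row$name, "triplet", function(g) {
      if (n_atoms(g) < 2L) return(0)
      x <- solve_triplet(g, row$matrix, row$diagonal, row$free)
      abs(triplet_index(x, row$operation))  # registry weights are magnitudes
    })
  })
  .scheme_cache$entries <- entries
  entries
}

#' List the registered weighting schemes
#'
#' @return data frame with columns `name` and `class`; one row per
#'   registered delta-weighting scheme.
#' @examples
#' nrow(weight_schemes())
#' table(weight_schemes()$class)
#' @export
weight_schemes <- function() {
  tab <- .scheme_table()
  data.frame(name = vapply(tab, `[[`, "", "name"),
             class = vapply(tab, `[[`, "", "class"),
             stringsAsFactors = FALSE)
}

.scheme_fun <- function(name) {
  for (e in .scheme_table()) if (e$name == name) return(e$fun)
  stop("unknown weighting scheme '", name, "'; see weight_schemes()", call. = FALSE)
}

#' Compute the delta-weight of one fragment under one scheme
#'
#' The hydrogen substituent has weight 0 by convention; otherwise the named
#' scheme's index is evaluated on the fragment graph (which includes the
#' chiral carbon).
#'
#' @param fragment one entry of a `chiral_center`'s `fragments` list, or a
#'   bare `molgraph`.
#' @param scheme scheme name from [weight_schemes()].
#' @export
fragment_weight <- function(fragment, scheme) {
  if (inherits(fragment, "molgraph")) {
    g <- fragment; is_h <- FALSE
  } else {
    g <- fragment$graph; is_h <- isTRUE(fragment$is_hydrogen)
  }
  if (is_h) return(0)
  .scheme_fun(scheme)(g)
}

#' Delta-weight table for a chiral center
#'
#' @param center a `chiral_center` from [extract_fragments()].
#' @param schemes character vector of scheme names (default: full registry).
#' @return matrix with one row per scheme and columns `da`, `db`, `dc`, `dd`.
#' @export
center_weights <- function(center, schemes = weight_schemes()$name) {
  out <- matrix(NA_real_, length(schemes), 4L,
                dimnames = list(schemes, c("da", "db", "dc", "dd")))
  for (s in seq_along(schemes)) {
    out[s, ] <- vapply(center$fragments, function(f)
      tryCatch(fragment_weight(f, schemes[s]), error = function(e) NA_real_),
      numeric(1))
  }
  out
}

#' Prune schemes whose weights vanish on a non-hydrogen substituent
#'
#' A scheme is removed when, for any molecule, the delta of a rank a, b or c
#' substituent is zero (or could not be computed); a zero rank-d weight is
#' the norm (hydrogen) and is tolerated.
#'
#' @param weights a list (one element per molecule) of lists (one per
#'   center) of weight matrices from [center_weights()].
#' @param schemes the candidate scheme names.
#' @return the retained scheme names.
#' @export
prune_zero_weight_schemes <- function(weights, schemes) {
  bad <- logical(length(schemes))
  for (mol in weights) for (cw in mol) {
    abc <- cw[schemes, c("da", "db", "dc"), drop = FALSE]
    bad <- bad | apply(!is.finite(abc) | abc == 0, 1L, any) |
      !is.finite(cw[schemes, "dd"])  # d may be zero (hydrogen) but not NA
  }
  schemes[!bad]
}

#' Compute the compounds-by-RCI descriptor matrix
#'
#' For every molecule: find its annotated stereocenters, extract the four
#' CIP-ranked fragments per center, weight them under every scheme, apply
#' the configuration-appropriate formula ([rci_R()] for R centers,
#' [rci_S()] for S centers) and aggregate multiple centers by [rci_rms()].
#' Schemes failing the zero-weight rule on any molecule are dropped.
#'
#' @param molecules data frame with columns `id` and `smiles`, or a named
#'   list of `molgraph` objects.
#' @param schemes scheme names (default: full registry).
#' @param priorities optional named list: `priorities[[id]][[as.character(center)]]`
#'   gives the four substituent atom indices in CIP order (0 = implicit H),
#'   overriding the built-in ranking.
#' @return numeric matrix (molecules x retained schemes) with attributes
#'   `centers` (per-molecule center/configuration bookkeeping) and
#'   `dropped` (pruned scheme names).
#' @export
compute_rci_matrix <- function(molecules, schemes = weight_schemes()$name,
                               priorities = NULL) {
  if (is.data.frame(molecules)) {
    ids <- molecules$id
    graphs <- lapply(molecules$smiles, parse_smiles)
  } else {
    ids <- names(molecules)
    graphs <- molecules
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("molecules must carry unique ids", call. = FALSE)

  all_weights <- vector("list", length(graphs))
  all_configs <- vector("list", length(graphs))
  for (m in seq_along(graphs)) {
    g <- graphs[[m]]
    centers <- find_stereocenters(g)
    if (!length(centers))
      stop("molecule '", ids[m], "' has no annotated stereocenter", call. = FALSE)
    ws <- vector("list", length(centers)); cfg <- character(length(centers))
    for (k in seq_along(centers)) {
      pr <- if (!is.null(priorities)) priorities[[ids[m]]][[as.character(centers[k])]]
      cc <- extract_fragments(g, centers[k], priorities = pr)
      ws[[k]] <- center_weights(cc, schemes)
      cfg[k] <- cc$configuration
    }
    all_weights[[m]] <- ws
    all_configs[[m]] <- data.frame(center = centers, configuration = cfg)
  }
  kept <- prune_zero_weight_schemes(all_weights, schemes)
  out <- matrix(NA_real_, length(graphs), length(kept),
                dimnames = list(ids, kept))
  for (m in seq_along(graphs)) {
    cfg <- all_configs[[m]]$configuration
    for (s in seq_along(kept)) {
      vals <- vapply(seq_along(cfg), function(k) {
        w <- all_weights[[m]][[k]][kept[s], ]
        if (cfg[k] == "R") rci_R(w) else rci_S(w)
      }, numeric(1))
      out[m, s] <- rci_rms(vals)
    }
  }
  attr(out, "centers") <- setNames(all_configs, ids)
  attr(out, "dropped") <- setdiff(schemes, kept)
  out
}
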