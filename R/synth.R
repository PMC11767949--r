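# Seeded synthetic generators: chiral molecules with known stereocenters
# for property tests, and descriptor/activity datasets with planted signal
# for pipeline-recovery tests.

# Substituent pool: simple acyclic groups with pairwise-distinct CIP keys in
# most combinations; drawn without replacement per center.
.SUBSTITUENT_POOL <- c(
  "F", "Cl", "O", "N", "S", "C", "CC", "CCC", "C(C)C", "CO", "OC", "CN",
  "CCO", "CCN", "C=O", "C(=O)O", "C(=O)N", "CS", "SC", "CCl", "CF",
  "CCCC", "C(C)(C)C", "OCC", "NC", "CC=O", "CCF", "CCCl", "CCS", "OCO")

# One stereocenter expression.  `subs` are the written branches (the last is
# appended bare, the others parenthesised); a center with a preceding atom
# in the string writes one branch fewer.
.center_smiles <- function(subs, mark, with_h) {
  tok <- paste0("[C", mark, if (with_h) "H", "]")
  k <- length(subs)
  paste0(tok,
         if (k > 1L) paste0("(", subs[-k], ")", collapse = ""),
         if (k >= 1L) subs[k])
}

.flip_marks <- function(smiles) {
  # swap @ and @@ (placeholder swap to avoid double substitution)
  s <- gsub("@@", "\001", smiles, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\001", "@", s, fixed = TRUE)
}

#' Generate seeded synthetic chiral molecules
#'
#' Builds acyclic molecules with 1 to 3 annotated tetrahedral stereocenters
#' over the elements C, N, O, S, F, Cl.  Each center's four substituents are
#' drawn so that their CIP-style priorities are distinct (validated through
#' the ranking routine; combinations that tie are re-drawn).  Every molecule
#' is emitted together with its mirror image (all stereo marks flipped).
#'
#' @param n number of molecules (each with an enantiomer partner).
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @param max_atoms heavy-atom cap (>= 5); draws exceeding it are rejected.
#' @param n_centers number of stereocenters per molecule (1..3), recycled.
#' @return data frame with columns `id`, `smiles`, `enantiomer_smiles`,
#'   `n_centers`.
#' @export
gen_chiral_molecules <- function(n, seed = 1L, max_atoms = 30L, n_centers = NULL) {
  if (max_atoms < 5L) stop("max_atoms must be >= 5", call. = FALSE)
  set.seed(seed)
  if (is.null(n_centers)) n_centers <- rep_len(1:3, n)
  n_centers <- rep_len(n_centers, n)

  draw_molecule <- function(nc) {
    # build the chain back-to-front: one branch of center k carries an
    # ethylene bridge to center k+1; centers after the first have a
    # preceding atom in the string and so write one branch fewer
    smi <- ""
    for (k in rev(seq_len(nc))) {
      with_h <- sample.int(2L, 1L) == 1L
      has_prev <- k > 1L
      nbranch <- 4L - as.integer(with_h) - as.integer(has_prev)
      subs <- .SUBSTITUENT_POOL[sample.int(length(.SUBSTITUENT_POOL), nbranch)]
      if (k < nc) subs[nbranch] <- paste0("CC", smi)
      mark <- if (sample.int(2L, 1L) == 1L) "@" else "@@"
      smi <- .center_smiles(subs, mark, with_h)
    }
    smi
  }
  valid <- function(smi, nc) {
    tryCatch({
      g <- parse_smiles(smi)
      sc <- find_stereocenters(g)
      length(sc) == nc &&
        all(vapply(sc, function(a) {
          ok <- !inherits(tryCatch(extract_fragments(g, a), error = identity),
                          "error")
          ok
        }, TRUE)) &&
        n_atoms(g) <= max_atoms
    }, error = function(e) FALSE)
  }

  out <- vector("list", n)
  for (m in seq_len(n)) {
    nc <- n_centers[m]
    repeat {
      smi <- draw_molecule(nc)
      if (valid(smi, nc)) break
    }
    out[[m]] <- data.frame(id = sprintf("SYN%03d", m), smiles = smi,
                           enantiomer_smiles = .flip_marks(smi),
                           n_centers = nc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic QSAR dataset with planted signal
#'
#' Emulates the study design: a small compound set described by a large
#' descriptor matrix with a strongly hierarchical correlation structure
#' (like the eigenvalue profile of real topological-index pools, where the
#' leading component carries most of the variance).  `k_signal` signal
#' blocks of geometrically decreasing size each share a latent factor; the
#' first member of each block is that factor itself (the planted
#' descriptor) and the rest are noisy copies with within-block correlation
#' about `rho`.  The remaining descriptors form small weakly-correlated
#' nuisance blocks.  Unequal block sizes separate the leading eigenvalues
#' so the retained components are identified, not arbitrary rotations.
#' Descriptors are lognormal (nonnegative, scale-varying, like topological
#' indices); the activity is a linear combination of the
#' ln(x+1)-transformed planted descriptors plus Gaussian noise, i.e. the
#' signal lives on the scale the modelling pipeline works on.
#'
#' @param n_compounds number of rows (study condition: 20).
#' @param n_descriptors number of columns (study condition: 198).
#' @param k_signal number of planted descriptors (study condition: 3).
#' @param noise_sd standard deviation of the activity noise (default 0.3,
#'   moderate against unit-scale signal coefficients).
#' @param seed integer seed.
#' @param rho within-block correlation of the signal blocks (default 0.95).
#' @param beta signal coefficients (default `c(1, 0.8, 0.6)` recycled).
#' @param signal_frac fraction of descriptors belonging to signal blocks
#'   (default 0.8); block sizes decrease geometrically (ratio 0.6).
#' @return list with `x` (descriptor matrix, nonnegative), `y` (activity),
#'   and `truth` (list: planted descriptor names, `beta`, `intercept`,
#'   `blocks` assignment).
#' @export
gen_qsar_dataset <- function(n_compounds, n_descriptors, k_signal,
                             noise_sd = 0.3, seed = 1L, rho = 0.95,
                             beta = c(1, 0.8, 0.6), signal_frac = 0.8) {
  if (k_signal > n_descriptors)
    stop("k_signal must be <= n_descriptors", call. = FALSE)
  if (k_signal < 0 || n_compounds < 4L)
    stop("invalid sizes", call. = FALSE)
  set.seed(seed)
  beta <- rep_len(beta, max(k_signal, 1L))

  # geometrically decreasing signal-block sizes, then nuisance blocks of 6
  if (k_signal > 0L) {
    shares <- 0.6^(seq_len(k_signal) - 1L)
    sizes <- pmax(2L, floor(signal_frac * n_descriptors * shares / sum(shares)))
    while (sum(sizes) > n_descriptors) sizes[which.max(sizes)] <- max(sizes) - 1L
  } else sizes <- integer(0)
  n_noise <- n_descriptors - sum(sizes)
  noise_sizes <- if (n_noise > 0L) rep(6L, n_noise %/% 6L) else integer(0)
  if (n_noise %% 6L) noise_sizes <- c(noise_sizes, n_noise %% 6L)
  blocks <- rep(seq_along(c(sizes, noise_sizes)), times = c(sizes, noise_sizes))

  # block factors drawn orthogonal in-sample (sequential residualisation):
  # the planted structure is then identified -- principal components align
  # with blocks instead of arbitrary rotations of correlated factors
  n_blocks <- length(unique(blocks))
  if (n_blocks >= n_compounds)
    stop("too many blocks for the number of compounds", call. = FALSE)
  fmat <- matrix(rnorm(n_compounds * n_blocks), n_compounds)
  for (b in seq_len(n_blocks)) {
    f <- fmat[, b]
    if (b > 1L) f <- residuals(lm(f ~ fmat[, seq_len(b - 1L), drop = FALSE]))
    fmat[, b] <- as.numeric(scale(f))
  }

  raw <- matrix(0, n_compounds, n_descriptors)
  planted_idx <- integer(k_signal)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    f <- fmat[, b]
    r_b <- if (b <= k_signal) rho else 0.3
    raw[, idx] <- sqrt(r_b) * f +
      sqrt(1 - r_b) * matrix(rnorm(n_compounds * length(idx)), n_compounds)
    if (b <= k_signal) {
      raw[, idx[1L]] <- f  # the planted descriptor is the latent anchor
      planted_idx[b] <- idx[1L]
    }
  }
  x <- exp(raw)  # lognormal, nonnegative, scale-varying
  colnames(x) <- sprintf("D%03d", seq_len(n_descriptors))
  rownames(x) <- sprintf("CPD%03d", seq_len(n_compounds))
  planted <- colnames(x)[planted_idx]
  intercept <- 7
  y <- intercept + rnorm(n_compounds, sd = noise_sd)
  if (k_signal > 0L)
    y <- y + as.numeric(log1p(x[, planted, drop = FALSE]) %*% beta[seq_len(k_signal)])
  list(x = x, y = setNames(y, rownames(x)),
       truth = list(planted = planted,
                    beta = if (k_signal > 0L) setNames(beta[seq_len(k_signal)], planted)
                           else numeric(0),
                    intercept = intercept, blocks = blocks))
}
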