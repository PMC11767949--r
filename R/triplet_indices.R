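# Triplet topological indices: local vertex invariants obtained by solving
# M x = r, where M is the adjacency or distance matrix with its diagonal
# replaced by a per-vertex vector, r is another per-vertex vector, and the
# solution is aggregated by one of five operations.
#
# Letter codes (data-driven registry; see triplet_codes()):
#   matrix:  A = adjacency, D = topological distance
#   vectors: Z = atomic numbers, N = graph order (n, repeated), N2 = n^2,
#            V = vertex degrees, S = distance sums
# The AZV1 worked value (Table-2-style fragment CNCCN(C)C -> 1.422) fixes
# this interpretation: Z must be the atomic-number vector and operation 1
# the plain sum.

.TRIPLET_VECTORS <- c("Z", "N", "N2", "V", "S")

triplet_vector <- function(g, code) {
  n <- n_atoms(g)
  switch(code,
         Z  = as.numeric(g$atoms$Z),
         N  = rep(as.numeric(n), n),
         N2 = rep(as.numeric(n)^2, n),
         V  = as.numeric(degrees(g)),
         S  = as.numeric(rowSums(distance_matrix(g))),
         stop("unknown triplet vector code '", code, "'", call. = FALSE))
}

#' Solve a triplet linear system for local vertex invariants
#'
#' Builds `M` from the adjacency (`"A"`) or distance (`"D"`) matrix with the
#' diagonal replaced by the vector named by `diagonal_code`, and solves
#' `M x = r` with `r` the vector named by `free_code` (direct dense solve).
#'
#' @param g a connected `molgraph`.
#' @param matrix_code `"A"` or `"D"`.
#' @param diagonal_code,free_code one of `"Z"`, `"N"`, `"N2"`, `"V"`, `"S"`.
#' @return numeric vector of local invariants.
#' @export
solve_triplet <- function(g, matrix_code, diagonal_code, free_code) {
  matrix_code <- match.arg(matrix_code, c("A", "D"))
  M <- if (matrix_code == "A") adjacency_matrix(g) else distance_matrix(g)
  storage.mode(M) <- "double"
  diag(M) <- triplet_vector(g, diagonal_code)
  r <- triplet_vector(g, free_code)
  x <- tryCatch(solve(M, r), error = function(e)
    stop("solve_triplet: singular system for spec ", matrix_code,
         diagonal_code, free_code, ": ", conditionMessage(e), call. = FALSE))
  as.numeric(x)
}

#' Aggregate local invariants into a triplet index
#'
#' The five operations: 1 = sum; 2 = sum of squares; 3 = sum of square roots
#' of magnitudes; 4 = n times the geometric mean of magnitudes; 5 =
#' geometric mean of magnitudes.  Operation 1 is fixed by the AZV1
#' calibration; the remaining four are package conventions recorded here.
#'
#' @param x local invariant vector.
#' @param y operation, 1..5.
#' @export
triplet_index <- function(x, y) {
  if (!y %in% 1:5) stop("triplet_index: unknown operation y = ", y, call. = FALSE)
  n <- length(x)
  ax <- abs(x)
  switch(y,
         sum(x),
         sum(x^2),
         sum(sqrt(ax)),
         if (any(ax == 0)) 0 else n * exp(mean(log(ax))),
         if (any(ax == 0)) 0 else exp(mean(log(ax))))
}

#' The triplet descriptor registry
#'
#' The generative grammar `{A, D} x 10 (diagonal, free) code pairs x
#' operations 1..5` yields the 100 triplet descriptors exposed by
#' [weight_schemes()].
#'
#' @return data frame with columns `name`, `matrix`, `diagonal`, `free`,
#'   `operation`.
#' @export
triplet_codes <- function() {
  pairs <- c("ZV", "ZN", "NZ", "NN", "N2S", "VS", "SV", "SZ", "ZS", "VN")
  grid <- expand.grid(op = 1:5, pair = pairs, m = c("A", "D"),
                      stringsAsFactors = FALSE)
  diagc <- ifelse(grid$pair == "N2S", "N2", substr(grid$pair, 1, 1))
  freec <- ifelse(grid$pair == "N2S", "S", substr(grid$pair, 2, 3))
  data.frame(name = paste0(grid$m, grid$pair, grid$op),
             matrix = grid$m, diagonal = diagc, free = freec,
             operation = grid$op, stringsAsFactors = FALSE)
}

# Convenience: named triplet descriptor on a graph.
triplet_descriptor <- function(g, name) {
  reg <- triplet_codes()
  row <- reg[reg$name == name, ]
  if (nrow(row) != 1L) stop("unknown triplet descriptor '", name, "'", call. = FALSE)
  x <- solve_triplet(g, row$matrix, row$diagonal, row$free)
  triplet_index(x, row$operation)
}
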