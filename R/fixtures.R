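# Embedded reference tables: the 20-compound CCR2 antagonist activities,
# the worked-example fragment weights, and the ten reference RCI values for
# compound 1 under the five illustrated weighting schemes.

#' CCR2 antagonist activities (pIC50) for the 20 chiral compounds
#'
#' @return data frame with columns `id` (1..20) and `pIC50`.
#' @export
ccr2_activity <- function() {
  data.frame(
    id = 1:20,
    pIC50 = c(6.00, 6.11, 6.06, 6.37, 6.40, 6.08, 6.12, 6.08, 7.41, 6.66,
              6.76, 7.88, 7.84, 6.64, 7.88, 7.38, 8.74, 8.46, 7.52, 9.37))
}

#' Worked-example substituent weights for compound 1
#'
#' The four substituent fragments at the single stereocenter of compound 1
#' (an S-configured arylglycinamide) and their delta-weights under five
#' schemes: Balaban J, calibrated second-order kappa, first-order valence
#' connectivity, first-order information content, and the AZV1 triplet
#' index.
#'
#' @return data frame with columns `rank`, `smiles`, `J`, `K2`, `XV1`,
#'   `IC1`, `AZV1`.
#' @export
table2_weights <- function() {
  data.frame(
    rank = c("a", "b", "c", "d"),
    smiles = c("CNCCN(C)C",
               "FC(F)(F)c1cc(CNC(C)=O)cc(c1)C(F)(F)F",
               "Cc1ccccc1",
               "C"),
    J    = c(2.678, 3.298, 3.033, 0),
    K2   = c(2.083, 3.093, 1.172, 0),
    XV1  = c(2.564, 5.027, 2.411, 0),
    IC1  = c(1.7799, 2.9852, 1.5329, 0),
    AZV1 = c(1.422, 4.180, 1.711, 0),
    stringsAsFactors = FALSE)
}

#' Reference RCI values for compound 1
#'
#' The ten R- and S-isomer relative chirality indices obtained by feeding
#' the [table2_weights()] columns into the two RCI formulas.
#'
#' @return data frame with columns `scheme`, `R`, `S`.
#' @export
rci_reference <- function() {
  data.frame(
    scheme = c("J", "K2", "XV1", "IC1", "AZV1"),
    R = c(52.482, 26.687, 64.550, 24.112, 26.330),
    S = c(51.064, 18.683, 51.131, 18.942, 19.307))
}

#' SMILES of compound 1 reconstructed from its fragments
#'
#' The S-configured arylglycinamide whose four substituent fragments are the
#' rows of [table2_weights()]; used as the structural worked example.
#'
#' @return a single SMILES string.
#' @export
compound1_smiles <- function() {
  "[C@@H](NCCN(C)C)(C(=O)NCc1cc(C(F)(F)F)cc(C(F)(F)F)c1)c1ccccc1"
}
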