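# Workflow glue: file-in/file-out wrappers tying the descriptor and
# modelling modules together, used by the command-line script.

#' Per-fragment delta-weight table for a SMILES file
#'
#' Parses every record, extracts all annotated stereocenters, and tabulates
#' the delta-weights of the four CIP-ranked fragments per center under the
#' requested schemes.  Records that fail to parse or have no stereocenter
#' are reported and skipped rather than aborting the run.
#'
#' @param smiles either a path to an `ID<TAB>SMILES` file or a data frame
#'   with columns `id`, `smiles`.
#' @param schemes scheme names (default: the five worked-example schemes).
#' @param out optional CSV path to write the table to.
#' @return data frame with columns `id`, `center`, `configuration`, `rank`,
#'   `fragment`, one column per scheme, and attribute `failures` (data frame
#'   id/message for skipped records).
#' @export
run_weights <- function(smiles, schemes = c("J", "K2", "XV1", "IC1", "AZV1"),
                        out = NULL) {
  tab <- if (is.character(smiles)) read_smiles_file(smiles) else smiles
  rows <- list(); failures <- list()
  for (r in seq_len(nrow(tab))) {
    res <- tryCatch({
      g <- parse_smiles(tab$smiles[r])
      centers <- find_stereocenters(g)
      if (!length(centers)) stop("no annotated stereocenter")
      do.call(rbind, lapply(centers, function(ct) {
        cc <- extract_fragments(g, ct)
        w <- t(center_weights(cc, schemes))  # ranks x schemes
        data.frame(id = tab$id[r], center = ct,
                   configuration = cc$configuration,
                   rank = c("a", "b", "c", "d"),
                   fragment = vapply(cc$fragments, function(f)
                     if (f$is_hydrogen) "H" else f$smiles, ""),
                   w, check.names = FALSE, row.names = NULL)
      }))
    }, error = function(e)
      structure(list(id = tab$id[r], message = conditionMessage(e)),
                class = "record_failure"))
    if (inherits(res, "record_failure")) failures[[length(failures) + 1L]] <- res
    else rows[[length(rows) + 1L]] <- res
  }
  empty <- data.frame(id = character(0), center = integer(0),
                      configuration = character(0), rank = character(0),
                      fragment = character(0))
  out_df <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out_df, "failures") <- if (length(failures))
    data.frame(id = vapply(failures, `[[`, "", "id"),
               message = vapply(failures, `[[`, "", "message"))
    else data.frame(id = character(0), message = character(0))
  if (!is.null(out)) write.csv(out_df, out, row.names = FALSE)
  out_df
}

#' Run the full descriptor-to-model workflow
#'
#' Computes the RCI descriptor matrix for a SMILES file, joins it with an
#' activity table, fits the [qcsar()] pipeline, and (optionally) writes a
#' report directory: the descriptor matrix, eigenvalue table, correlation
#' ranking, model summaries, residuals, cross-validation table and a run
#' log with the configuration.
#'
#' @param smiles path to `ID<TAB>SMILES` file or a data frame (`id`,
#'   `smiles`).
#' @param activity path to a CSV with columns `id`, `pIC50` (or any second
#'   column as activity), or a data frame.
#' @param report optional directory to write the report files into.
#' @param schemes scheme names (default: full registry).
#' @param cv_seed,cv_k,p_enter,p_remove passed to [qcsar()].
#' @return the `qcsar` fit, with the descriptor matrix in attribute
#'   `rci_matrix`.
#' @export
run_full <- function(smiles, activity, report = NULL,
                     schemes = weight_schemes()$name,
                     cv_seed = 1L, cv_k = 5L, p_enter = 0.05, p_remove = 0.10) {
  mols <- if (is.character(smiles)) read_smiles_file(smiles) else smiles
  act <- if (is.character(activity)) read.csv(activity) else activity
  ids <- as.character(mols$id)
  aid <- as.character(act[[1L]])
  if (!setequal(ids, aid))
    stop("id mismatch between SMILES and activity files: ",
         paste(union(setdiff(ids, aid), setdiff(aid, ids)), collapse = ", "),
         call. = FALSE)
  y <- setNames(as.numeric(act[[2L]]), aid)[ids]
  M <- compute_rci_matrix(mols, schemes = schemes)
  fit <- qcsar(M, y, cv_seed = cv_seed, cv_k = cv_k,
               p_enter = p_enter, p_remove = p_remove)
  attr(fit, "rci_matrix") <- M
  if (!is.null(report)) {
    dir.create(report, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(id = rownames(M), M, check.names = FALSE),
              file.path(report, "rci_matrix.csv"), row.names = FALSE)
    ev <- data.frame(component = seq_along(fit$pca$eigenvalues),
                     eigenvalue = fit$pca$eigenvalues,
                     pct_variance = fit$pca$pct_variance,
                     cum_pct_variance = fit$pca$cum_pct_variance)
    write.csv(ev[fit$pca$retained, ], file.path(report, "eigenvalues.csv"),
              row.names = FALSE)
    write.csv(fit$screen, file.path(report, "correlation_ranking.csv"),
              row.names = FALSE)
    resid_tab <- data.frame(id = ids, observed = y,
                            predicted = stats::fitted(fit$descriptor_model),
                            residual = residuals(fit$descriptor_model))
    write.csv(resid_tab, file.path(report, "residuals.csv"), row.names = FALSE)
    if (!is.null(fit$cv))
      write.csv(fit$cv$folds, file.path(report, "cross_validation.csv"),
                row.names = FALSE)
    log <- c(
      paste0("chirind ", tryCatch(as.character(utils::packageVersion("chirind")),
                                  error = function(e) "dev")),
      paste0("schemes: ", length(schemes), " requested, ",
             ncol(M), " retained after zero-weight pruning"),
      paste0("dropped schemes: ", paste(attr(M, "dropped"), collapse = ", ")),
      paste0("stepwise thresholds: enter ", p_enter, ", remove ", p_remove),
      paste0("cv: k = ", cv_k, ", seed = ", cv_seed),
      paste0("score model: ", paste(fit$used_pcs, collapse = " + "),
             "  R2 = ", signif(fit$score_model$r_squared, 4)),
      paste0("descriptor model: ", paste(fit$selected, collapse = " + ")))
    writeLines(log, file.path(report, "run_log.txt"))
  }
  fit
}
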