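# The chirality-sensitive QSAR pipeline: ln(x+1) standardization, degenerate
# descriptor pruning, correlation screening, correlation-matrix PCA with
# Kaiser retention, stepwise regression on component scores, per-component
# descriptor selection and refit, and k-fold cross-validation.

#' ln(x + 1) standardization of a descriptor matrix
#'
#' Descriptors differ by orders of magnitude across schemes, so the pipeline
#' models `log_e(descriptor + 1)`.
#'
#' @param m nonnegative numeric matrix (compounds x descriptors).
#' @return the transformed matrix, with attribute `transformed = TRUE`.
#' @export
log_transform <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("log_transform: missing cells", call. = FALSE)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("log_transform: negative value at [", rownames(m)[neg[1, 1]], ", ",
         colnames(m)[neg[1, 2]], "]", call. = FALSE)
  out <- log1p(m)
  attr(out, "transformed") <- TRUE
  out
}

#' Drop degenerate descriptor columns
#'
#' Removes all-zero columns and columns with a single distinct value (both
#' carry no information and break correlation-matrix PCA).
#'
#' @param m numeric matrix.
#' @return the pruned matrix; dropped names in attribute `dropped`.
#' @export
prune_degenerate <- function(m) {
  m <- as.matrix(m)
  n_distinct <- apply(m, 2L, function(col) length(unique(col)))
  keep <- n_distinct >= 2L & apply(m, 2L, function(col) any(col != 0))
  out <- m[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(m)[!keep]
  out
}

#' Rank descriptors by correlation with the activity
#'
#' @param m numeric matrix (compounds x descriptors).
#' @param y activity vector in the same compound order.
#' @param classes optional named class per descriptor (e.g. from
#'   [weight_schemes()]) carried through for Table-style grouped reporting.
#' @return data frame (`descriptor`, `r`, optionally `class`) sorted by
#'   decreasing `|r|`; zero-variance columns are excluded with a warning.
#' @export
correlation_screen <- function(m, y, classes = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != length(y)) stop("row/activity length mismatch", call. = FALSE)
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance descriptor(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- as.numeric(cor(m, y))
  out <- data.frame(descriptor = colnames(m), r = r, stringsAsFactors = FALSE)
  if (!is.null(classes)) out$class <- unname(classes[out$descriptor])
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Correlation-matrix PCA with Kaiser retention
#'
#' Eigendecomposition of the correlation matrix of the (transformed)
#' descriptors; components with eigenvalue > 1 are retained and their
#' standardized scores returned.
#'
#' @param m numeric matrix, at least 3 rows and 2 non-constant columns.
#' @return object of class `pca_result`: list with `eigenvalues`,
#'   `pct_variance`, `cum_pct_variance`, `loadings`, `scores` (retained
#'   components only), `retained`.
#' @export
pca_extract <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("pca_extract: need >= 3 rows and >= 2 columns", call. = FALSE)
  if (any(apply(m, 2L, sd) == 0))
    stop("pca_extract: constant column present; prune first", call. = FALSE)
  R <- cor(m)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  retained <- which(ev > 1)
  Zs <- scale(m)
  scores <- Zs %*% eg$vectors[, retained, drop = FALSE]
  if (length(retained)) colnames(scores) <- paste0("PC", retained)
  structure(list(
    eigenvalues = ev,
    pct_variance = 100 * ev / ncol(m),
    cum_pct_variance = cumsum(100 * ev / ncol(m)),
    loadings = eg$vectors,
    scores = scores,
    retained = retained), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$retained)
  cat("<pca_result> ", length(x$eigenvalues), " variables, ", k,
      " component(s) with eigenvalue > 1\n", sep = "")
  tab <- data.frame(component = seq_len(min(k, length(x$eigenvalues))),
                    eigenvalue = round(x$eigenvalues[seq_len(k)], 2),
                    cum_pct = round(x$cum_pct_variance[seq_len(k)], 1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stepwise multiple linear regression (forward with backward elimination)
#'
#' Forward selection on partial-F p-values with backward elimination:
#' at each step the candidate with the smallest p-value enters if
#' p <= `p_enter`, then any included predictor with p >= `p_remove` leaves.
#' Falls back to the intercept-only model with a warning when nothing meets
#' the entry criterion.
#'
#' @param x predictor matrix or data frame.
#' @param y response vector.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return object of class `stepwise_fit`: list with the final `lm` fit
#'   (`model`), `selected` predictor names, `r_squared`, `adj_r_squared`.
#' @export
stepwise_mlr <- function(x, y, p_enter = 0.05, p_remove = 0.10) {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("row/response mismatch", call. = FALSE)
  dat <- cbind(x, .y = y)
  if (var(y) < 1e-12) {
    warning("response has zero variance; intercept-only model")
    fit <- lm(.reformulate(character(0)), data = dat)
    return(structure(list(model = fit, selected = character(0),
                          r_squared = 0, adj_r_squared = 0,
                          p_enter = p_enter, p_remove = p_remove),
                     class = "stepwise_fit"))
  }
  selected <- character(0)
  candidates <- colnames(x)
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      base_f <- lm(.reformulate(selected), data = dat)
      pv <- vapply(pool, function(v) {
        fit <- lm(.reformulate(c(selected, v)), data = dat)
        .last_term_p(fit, base_f)
      }, numeric(1))
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) <= p_enter) {
        selected <- c(selected, pool[which.min(pv)])
        changed <- TRUE
      }
    }
    # backward step
    if (length(selected) > 1L) {
      repeat {
        full <- lm(.reformulate(selected), data = dat)
        pv <- vapply(selected, function(v) {
          red <- lm(.reformulate(setdiff(selected, v)), data = dat)
          .last_term_p(full, red)
        }, numeric(1))
        if (max(pv, na.rm = TRUE) >= p_remove) {
          selected <- setdiff(selected, selected[which.max(pv)])
        } else break
      }
    }
    if (!changed) break
  }
  if (!length(selected))
    warning("no predictor met the entry criterion; intercept-only model")
  fit <- lm(.reformulate(selected), data = dat)
  sm <- summary(fit)
  structure(list(model = fit, selected = selected,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_fit")
}

.reformulate <- function(terms) {
  if (!length(terms)) stats::as.formula(".y ~ 1")
  else stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + ")))
}

# partial F-test p-value between nested fits (full vs reduced)
.last_term_p <- function(full, reduced) {
  a <- stats::anova(reduced, full)
  p <- a[["Pr(>F)"]][2L]
  if (is.na(p)) Inf else p
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> predictors:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n  R2 =", round(x$r_squared, 3),
      " adj R2 =", round(x$adj_r_squared, 3), "\n")
  invisible(x)
}

#' Select the most correlated descriptor for each retained component
#'
#' For each principal component used in the score model, picks the
#' descriptor whose column has maximal `|r|` with that component's scores;
#' ties (to 8 decimals) are broken by the larger number of distinct values
#' (the "least degenerate" descriptor), then by name.
#'
#' @param m transformed descriptor matrix.
#' @param scores score matrix with named `PC` columns.
#' @param pcs character names of the components to cover (default: all
#'   columns of `scores`).
#' @return named character vector: descriptor per component.
#' @export
select_rci_per_pc <- function(m, scores, pcs = colnames(scores)) {
  m <- as.matrix(m)
  out <- character(0)
  for (pc in pcs) {
    r <- abs(as.numeric(cor(m, scores[, pc])))
    r[!is.finite(r)] <- -Inf
    best <- which(abs(r - max(r)) < 1e-8)
    if (length(best) > 1L) {
      distinct <- vapply(best, function(j) length(unique(m[, j])), 0L)
      best <- best[distinct == max(distinct)]
      best <- best[order(colnames(m)[best])]
    }
    out[pc] <- colnames(m)[best[1L]]
  }
  out
}

#' Seeded k-fold cross-validation of a linear model
#'
#' Shuffles compounds with the given seed into `k` folds of near-equal size,
#' refits the model on each training split and reports per-fold training
#' R-squared / adjusted R-squared and test R-squared (1 - PRESS/SS about the
#' training mean).
#'
#' @param x predictor matrix or data frame.
#' @param y response.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return object of class `cv_report`: data frame `folds` plus the fold
#'   assignment vector.
#' @export
kfold_cv <- function(x, y, k = 5L, seed = 1L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (k > n) stop("kfold_cv: k exceeds the number of compounds", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  dat <- cbind(x, .y = y)
  fml <- .reformulate(colnames(x))
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- lm(fml, data = dat[tr, , drop = FALSE])
    sm <- summary(fit)
    pred <- predict(fit, newdata = dat[!tr, , drop = FALSE])
    obs <- y[!tr]
    ss_tot <- sum((obs - mean(y[tr]))^2)
    r2_test <- if (ss_tot > 0) 1 - sum((obs - pred)^2) / ss_tot else NA_real_
    data.frame(fold = f, n_train = sum(tr), n_test = sum(!tr),
               r2_train = sm$r.squared, adj_r2_train = sm$adj.r.squared,
               r2_test = r2_test)
  })
  structure(list(folds = do.call(rbind, rows), assignment = fold, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", nrow(x$folds), "-fold cross-validation (seed ",
      x$seed, ")\n", sep = "")
  print(transform(x$folds, r2_train = round(r2_train, 3),
                  adj_r2_train = round(adj_r2_train, 3),
                  r2_test = round(r2_test, 3)), row.names = FALSE)
  invisible(x)
}

# ---- the fitted-model wrapper -------------------------------------------

#' Fit the chirality-sensitive QSAR model
#'
#' Runs the full modelling pipeline on a compounds-by-descriptors matrix:
#' ln(x+1) transform (optional), degenerate-column pruning,
#' correlation-matrix PCA retaining components with eigenvalue > 1,
#' stepwise regression of the activity on the retained component scores,
#' selection of the descriptor most correlated with each score in the final
#' model, a refit on those descriptors, and seeded k-fold cross-validation
#' of the refit.
#'
#' @param x nonnegative descriptor matrix (e.g. from
#'   [compute_rci_matrix()]).
#' @param y activity vector (e.g. pIC50), one value per row of `x`.
#' @param transform apply the ln(x+1) standardization (default TRUE).
#' @param p_enter,p_remove stepwise thresholds (defaults 0.05 / 0.10).
#' @param cv_k,cv_seed cross-validation folds and seed.
#' @return object of class `qcsar` with components `pca`, `score_model`,
#'   `selected` (descriptor per component), `descriptor_model` (the refit
#'   `stepwise-free` lm on the selected descriptors), `cv`, `screen`
#'   (activity correlation ranking), and bookkeeping fields.
#' @examples
#' d <- gen_qsar_dataset(20, 50, 2, noise_sd = 0.2, seed = 3, block_size = 10)
#' fit <- qcsar(d$x, d$y)
#' print(fit)
#' coef(fit)
#' @export
qcsar <- function(x, y, transform = TRUE, p_enter = 0.05, p_remove = 0.10,
                  cv_k = 5L, cv_seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  if (nrow(x) != length(y)) stop("qcsar: x and y disagree on compounds", call. = FALSE)
  xt <- if (transform) log_transform(x) else x
  xt <- prune_degenerate(xt)
  screen <- correlation_screen(xt, y)
  pca <- pca_extract(xt)
  step_fit <- stepwise_mlr(as.data.frame(pca$scores), y,
                           p_enter = p_enter, p_remove = p_remove)
  used_pcs <- step_fit$selected
  selected <- select_rci_per_pc(xt, pca$scores, pcs = used_pcs)
  if (length(selected)) {
    dat <- data.frame(xt[, selected, drop = FALSE], check.names = FALSE)
    dat$.y <- y
    desc_model <- lm(.reformulate(selected), data = dat)
    cv <- kfold_cv(xt[, selected, drop = FALSE], y, k = cv_k, seed = cv_seed)
  } else {
    desc_model <- lm(y ~ 1)
    cv <- NULL
  }
  structure(list(
    call = match.call(),
    x = x, x_transformed = xt, y = y, transform = transform,
    dropped = attr(xt, "dropped"),
    screen = screen, pca = pca,
    score_model = step_fit, used_pcs = used_pcs,
    selected = selected, descriptor_model = desc_model, cv = cv,
    cv_k = cv_k, cv_seed = cv_seed), class = "qcsar")
}

#' @export
print.qcsar <- function(x, ...) {
  cat("Chirality-sensitive QSAR model\n")
  cat("  compounds:", nrow(x$x), " descriptors:", ncol(x$x),
      "(", length(x$dropped), "dropped as degenerate )\n")
  cat("  retained components (eigenvalue > 1):", length(x$pca$retained), "\n")
  cat("  score model:", if (length(x$used_pcs)) paste(x$used_pcs, collapse = " + ")
      else "(intercept only)",
      " R2 =", round(x$score_model$r_squared, 3), "\n")
  if (length(x$selected)) {
    sm <- summary(x$descriptor_model)
    cat("  descriptor model:", paste(x$selected, collapse = " + "),
        " R2 =", round(sm$r.squared, 3), "\n")
  }
  invisible(x)
}

#' @export
summary.qcsar <- function(object, ...) {
  print(object)
  cat("\nEigenvalues (retained):\n")
  print(round(object$pca$eigenvalues[object$pca$retained], 2))
  cat("\nDescriptor model coefficients:\n")
  print(coef(object))
  if (!is.null(object$cv)) { cat("\n"); print(object$cv) }
  cat("\nTop activity correlations:\n")
  print(head(object$screen, 10L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.qcsar <- function(object, model = c("descriptor", "score"), ...) {
  model <- match.arg(model)
  coef(if (model == "descriptor") object$descriptor_model else object$score_model$model)
}

#' Predict activities for new compounds
#'
#' Uses the descriptor refit model (the score model would require repeating
#' the PCA for new compounds, which is why the pipeline re-expresses the
#' model in actual descriptors).
#'
#' @param object a `qcsar` fit.
#' @param newdata matrix/data frame containing the selected descriptor
#'   columns on the original (untransformed) scale; omitted = fitted values.
#' @param ... unused.
#' @export
predict.qcsar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$descriptor_model))
  nd <- as.matrix(newdata)[, object$selected, drop = FALSE]
  if (object$transform) nd <- log1p(nd)
  predict(object$descriptor_model, newdata = as.data.frame(nd))
}

#' @export
residuals.qcsar <- function(object, ...) residuals(object$descriptor_model)

#' @export
fitted.qcsar <- function(object, ...) stats::fitted(object$descriptor_model)

#' Observed-versus-predicted plot
#'
#' @param x a `qcsar` fit.
#' @param ... passed to [plot()].
#' @export
plot.qcsar <- function(x, ...) {
  p <- stats::fitted(x$descriptor_model)
  plot(p, x$y, xlab = "predicted activity", ylab = "observed activity", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
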