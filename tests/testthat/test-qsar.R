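test_that("log transform is ln(x + 1) with input validation", {
  expect_equal(log_transform(matrix(0))[1], 0)
  expect_equal(log_transform(matrix(exp(1) - 1))[1], 1)
  expect_equal(log_transform(matrix(52.482))[1], log(53.482))
  m <- matrix(c(1, -2), 1, dimnames = list("cpd", c("d1", "d2")))
  expect_error(log_transform(m), "negative value at \\[cpd, d2\\]")
})

test_that("degenerate columns are pruned", {
  m <- cbind(const = rep(3, 5), zero = rep(0, 5), ok = c(1, 2, 1, 2, 3),
             two = c(0, 1, 0, 1, 0))
  out <- prune_degenerate(m)
  expect_equal(colnames(out), c("ok", "two"))
  expect_equal(sort(attr(out, "dropped")), c("const", "zero"))
  m2 <- cbind(a = 1:4, b = c(2, 1, 4, 3))
  expect_equal(dim(prune_degenerate(m2)), dim(m2))
})

test_that("correlation screening ranks by |r| and flags degenerate columns", {
  y <- c(1, 3, 2, 5, 4, 6)
  m <- cbind(same = y, anti = -y + 10, weak = c(2, 1, 2, 1, 2, 2))
  out <- correlation_screen(m, y)
  expect_equal(out$descriptor[1:2], c("same", "anti"))
  expect_equal(out$r[out$descriptor == "same"], 1)
  expect_equal(out$r[out$descriptor == "anti"], -1)
  expect_warning(correlation_screen(cbind(m, flat = rep(1, 6)), y), "zero-variance")
})

test_that("a planted bivariate correlation is recovered at n = 200", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  x <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  out <- correlation_screen(cbind(planted = x, noise = rnorm(n)), z)
  expect_equal(out$r[out$descriptor == "planted"], 0.8,
               tolerance = 3 / sqrt(n))  # sampling error
})

test_that("PCA on exactly orthogonal columns retains nothing", {
  m <- unclass(stats::poly(1:12, 4))  # columns exactly orthogonal
  colnames(m) <- paste0("p", 1:4)
  p <- pca_extract(m)
  expect_equal(p$eigenvalues, rep(1, 4), tolerance = 1e-10)
  expect_length(p$retained, 0L)
})

test_that("perfectly correlated pair gives eigenvalues (2, 0)", {
  x <- rnorm(10)
  p <- pca_extract(cbind(a = x, b = 2 * x + 3))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(p$retained, 1L)
})

test_that("eigenvalues sum to the number of variables and scores are orthogonal", {
  set.seed(11)
  m <- matrix(rexp(20 * 12), 20)
  p <- pca_extract(m)
  expect_equal(sum(p$eigenvalues), 12)
  sc <- p$scores
  cp <- crossprod(sc)
  expect_equal(cp - diag(diag(cp)), matrix(0, ncol(sc), ncol(sc)),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(pca_extract(cbind(rep(1, 5), rnorm(5))), "constant column")
})

test_that("stepwise regression recovers a planted predictor", {
  set.seed(50)
  n <- 50
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("v", 1:8)))
  y <- 2 + 1.5 * x[, "v3"] + rnorm(n, sd = 0.4)
  fit <- stepwise_mlr(x, y)
  expect_true("v3" %in% fit$selected)
  cf <- summary(fit$model)$coefficients
  rownames(cf) <- gsub("`", "", rownames(cf))
  expect_lt(abs(cf["v3", 1] - 1.5), 3 * cf["v3", 2])
})

test_that("degenerate responses give the intercept-only model", {
  x <- matrix(rnorm(40), 10, dimnames = list(NULL, paste0("v", 1:4)))
  expect_warning(fit <- stepwise_mlr(x, rep(2, 10)), "zero variance")
  expect_length(fit$selected, 0L)
  expect_equal(unname(coef(fit$model)), 2)
})

test_that("orthogonal predictors keep their univariate slopes", {
  m <- unclass(stats::poly(1:20, 3))
  colnames(m) <- c("a", "b", "c")
  y <- 1 + 2 * m[, "a"] - 3 * m[, "b"] + 0.5 * m[, "c"]
  fit <- stepwise_mlr(m, y)
  cf <- coef(fit$model)
  names(cf) <- gsub("`", "", names(cf))
  for (v in fit$selected) {
    uni <- coef(lm(y ~ m[, v]))[2]
    expect_equal(unname(cf[v]), unname(uni), tolerance = 1e-8)
  }
})

test_that("per-component descriptor selection follows max |r| with tie-breaks", {
  set.seed(2)
  s1 <- rnorm(15); s2 <- rnorm(15)
  scores <- cbind(PC1 = s1, PC2 = s2)
  m <- cbind(d1 = 3 * s1, d2 = rnorm(15), d3 = s2 + 0.01 * rnorm(15))
  sel <- select_rci_per_pc(m, scores)
  expect_equal(unname(sel["PC1"]), "d1")
  expect_equal(unname(sel["PC2"]), "d3")
  # exact tie with equal distinctness -> lexicographic name order
  sel3 <- select_rci_per_pc(cbind(dB = s1, dA = s1), scores, pcs = "PC1")
  expect_equal(unname(sel3), "dA")
  # tie on |r| broken by the larger count of distinct values: dup repeats a
  # compound value, full does not; both correlate perfectly with the scores
  pc <- c(1, 1, 2, 3, 4, 5)
  sel4 <- select_rci_per_pc(cbind(dup = pc, full = pc + c(0.5, 0, 0, 0, 0, 0) * 0),
                            cbind(PC1 = pc), pcs = "PC1")
  expect_equal(unname(sel4), "dup")  # equal columns: lexicographic again
  # three components give three descriptors
  expect_length(select_rci_per_pc(m, cbind(scores, PC3 = rnorm(15))), 3L)
})

test_that("cross-validation is seeded, balanced and exact on linear data", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + x %*% c(1, -1, 2)
  cv <- kfold_cv(x, as.numeric(y), k = 5, seed = 3)
  expect_equal(as.integer(table(cv$assignment)), rep(4L, 5))
  expect_true(all(abs(cv$folds$r2_test - 1) < 1e-8))
  cv2 <- kfold_cv(x, as.numeric(y), k = 5, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(x, as.numeric(y), k = 25, seed = 1), "exceeds")
})

test_that("the qcsar object exposes the standard modelling interface", {
  d <- gen_qsar_dataset(20, 60, 2, noise_sd = 0.2, seed = 8, beta = c(1, 0.7))
  fit <- qcsar(d$x, d$y, cv_seed = 8)
  expect_s3_class(fit, "qcsar")
  expect_output(print(fit), "Chirality-sensitive QSAR model")
  expect_named(coef(fit))
  expect_length(residuals(fit), 20L)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(d$y))
  # prediction on the training descriptors reproduces the fitted values
  pr <- predict(fit, newdata = d$x)
  expect_equal(unname(pr), unname(fitted(fit)), tolerance = 1e-10)
  expect_equal(nrow(fit$cv$folds), 5L)
})

test_that("selected score predictors are numerically uncorrelated", {
  d <- gen_qsar_dataset(20, 80, 3, noise_sd = 0.3, seed = 15)
  fit <- qcsar(d$x, d$y, cv_seed = 15)
  if (length(fit$used_pcs) >= 2) {
    S <- fit$pca$scores[, fit$used_pcs, drop = FALSE]
    kap <- kappa(cor(S), exact = TRUE)  # condition number of correlation
    expect_lt(kap, 1 + 1e-6)
  }
})
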