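test_that("AUC equals exhaustive pair counting with the ties convention", {
  set.seed(11)
  scores <- c(2.3, 1.1, 5.0, 0.2, 3.3, 3.3, 0.9, 4.1, 2.2, 1.7)
  labels <- c(1, 0, 1, 0, 1, 0, 0, 1, 0, 1)
  expect_equal(auc_roc(scores, labels), oracle_auc_pairs(scores, labels))
  # frozen expected value from the pair-counting oracle
  expect_equal(auc_roc(scores, labels), 0.86)
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3)), 1.0)
  expect_equal(auc_roc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
  # more fixtures with heavy ties
  for (k in 1:20) {
    s <- sample(1:4, 12, replace = TRUE)
    y <- rep(c(0, 1), 6)
    expect_equal(auc_roc(s, y), oracle_auc_pairs(s, y))
  }
  # independent library cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc_roc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("AUC is antisymmetric and invariant under monotone transforms", {
  set.seed(5)
  s <- rnorm(40)
  y <- rep(0:1, 20)
  expect_equal(auc_roc(s, y) + auc_roc(-s, y), 1)
  expect_equal(auc_roc(exp(s), y), auc_roc(s, y))
  expect_equal(auc_roc(s^3, y), auc_roc(s, y))
})

test_that("logistic fit handles separation, sign and degenerate inputs", {
  expect_error(fit_linear_logodds(matrix(rnorm(10)), rep(1, 10)),
               "single class")
  # perfectly separated 1-D data: finite coefficients, training AUC 1
  X <- matrix(c(-(5:1), 1:5) / 3, ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rep(0:1, each = 5)
  fit <- fit_linear_logodds(X, y)
  expect_true(fit$separable)
  expect_true(is.finite(fit$coefficients[["x"]]))
  eta <- drop(X %*% fit$coefficients) + fit$intercept
  expect_equal(auc_roc(eta, y), 1.0)
  # coefficient sign follows the class mean shift
  set.seed(21)
  signs <- replicate(200, {
    x <- matrix(rnorm(60) + 0.8 * rep(0:1, each = 30), ncol = 1,
                dimnames = list(NULL, "f"))
    sign(fit_linear_logodds(x, rep(0:1, each = 30))$coefficients[["f"]])
  })
  expect_true(mean(signs > 0) > 0.95)
  # zero-variance feature dropped with a warning, coefficient zero
  X2 <- cbind(x = rnorm(40) + rep(c(0, 1), each = 20), z = 1)
  expect_warning(f2 <- fit_linear_logodds(X2, rep(0:1, each = 20)),
                 "zero-variance")
  expect_identical(f2$coefficients[["z"]], 0)
})

test_that("repeated holdout is deterministic and recovers the binormal AUC", {
  surr <- generate_surrogate(surrogate_spec(n_per_class = 150,
                                            delta = c(v_base = 2),
                                            cv = c(v_base = 0.08), seed = 31))
  ds <- surrogate_to_panel(surr)
  a <- repeated_holdout(ds, "main.PI", seed = 4)
  b <- repeated_holdout(ds, "main.PI", seed = 4)
  expect_identical(a, b)
  expect_lt(abs(a$auc - pnorm(2 / sqrt(2))), 0.03)
  expect_equal(length(a$auc_iter), 50)
  expect_true(all(a$auc_iter >= 0 & a$auc_iter <= 1))
  # null case: no class shift
  surr0 <- generate_surrogate(surrogate_spec(n_per_class = 100, seed = 32))
  ds0 <- surrogate_to_panel(surr0)
  expect_lt(abs(repeated_holdout(ds0, "main.PI", seed = 4)$auc - 0.5), 0.05)
  expect_error(repeated_holdout(ds, "nope", seed = 1), "unknown biomarker")
})

test_that("correlation matrix is exact on fixtures and well conditioned", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 7), c = -c(1, 2, 3))
  ds <- trial_dataset(X, c(0, 1, 1))
  cm <- correlation_matrix(ds)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(cm$r["a", "b"], 0.993399, tolerance = 1e-5)
  expect_equal(cm$r, t(cm$r))
  # PSD to tolerance on a random panel
  set.seed(9)
  Xr <- matrix(rnorm(200), 20, 10,
               dimnames = list(NULL, letters[1:10]))
  cr <- correlation_matrix(trial_dataset(Xr, rep(0:1, 10)))
  expect_gte(min(eigen(cr$r, symmetric = TRUE)$values), -1e-8)
  # zero-variance column flagged
  Xz <- cbind(Xr, z = 1)
  expect_warning(cz <- correlation_matrix(trial_dataset(Xz, rep(0:1, 10))),
                 "zero-variance")
  expect_true(all(is.na(cz$r["z", -11])))
})

test_that("combination search enumerates, caps and stays deterministic", {
  set.seed(2)
  X <- matrix(rnorm(600), 60, 10)
  colnames(X) <- c(paste0("f", 1:8), "Systolic Pressure", "Mean PWV")
  X[, 1] <- X[, 1] + rep(c(0, 2), each = 30)
  ds <- trial_dataset(X, rep(0:1, each = 30))
  res <- combination_search(ds, "full", dims = 2, cap_per_dim = 50,
                            n_iter = 10, seed = 3, auc_threshold = 0.6,
                            n_top = 10)
  expect_equal(nrow(res[["2"]]$results), choose(10, 2))
  expect_true(all(diff(res[["2"]]$results$auc) <= 0))
  # the shifted feature dominates the top combinations
  expect_equal(names(res[["2"]]$frequency)[1], "f1")
  # capped sampling: deterministic and distinct
  res2 <- combination_search(ds, "full", dims = 3, cap_per_dim = 20,
                             n_iter = 5, seed = 3)
  res3 <- combination_search(ds, "full", dims = 3, cap_per_dim = 20,
                             n_iter = 5, seed = 3)
  expect_identical(res2[["3"]]$results, res3[["3"]]$results)
  expect_equal(nrow(res2[["3"]]$results), 20)
  expect_equal(anyDuplicated(res2[["3"]]$results$biomarkers), 0)
  # the common group excludes pressure- and PWV-derived features
  expect_setequal(common_biomarker_group(colnames(X)), paste0("f", 1:8))
  expect_error(combination_search(ds, "common", dims = 9), "exceeds")
  # single-feature mode reproduces the univariate ranking
  r1 <- combination_search(ds, "full", dims = 1, cap_per_dim = 20,
                           n_iter = 10, seed = 5, auc_threshold = 0)
  u <- univariate_screen(ds, n_iter = 10, seed = 5)
  expect_equal(r1[["1"]]$results$biomarkers[1], u$feature[1])
})

test_that("univariate screen is centred under permuted labels", {
  surr <- generate_surrogate(surrogate_spec(n_per_class = 150, seed = 77))
  ds <- surrogate_to_panel(surr)
  set.seed(1)
  ds_perm <- trial_dataset(ds$X, sample(ds$y))
  u <- univariate_screen(ds_perm, n_iter = 20, seed = 2)
  # permutation null width: 27 correlated features, holdout-mean AUC
  expect_true(all(abs(u$auc - 0.5) < 0.09))
})

test_that("trial dataset construction enforces completeness and classes", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(trial_dataset(X, rep(1, 10)), "both classes")
  X[3, 1] <- NA
  expect_error(trial_dataset(X, rep(0:1, 5)), "missing feature")
})
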