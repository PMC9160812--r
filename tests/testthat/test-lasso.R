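make_lasso_instance <- function(n = 300, p = 8, beta = NULL, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(matrix(rnorm(n * p), n, p))
    colnames(x) <- paste0("g", seq_len(p))
    if (is.null(beta)) beta <- c(1.2, -0.8, rep(0, p - 2))
    y <- rbinom(n, 1, plogis(0.2 + drop(x %*% beta)))
    list(x = x, y = y)
  })
}

test_that("the penalty boundary and the unpenalized limit are exact", {
  inst <- make_lasso_instance(seed = 101)
  lmax <- lambda_max(inst$x, inst$y)
  path <- fit_l1_logistic_path(inst$x, inst$y,
                               lambda = c(lmax * 1.5, lmax, lmax * 0.9, 0),
                               tol = 1e-14)
  expect_equal(path$nonzero[1:2], c(0, 0))
  expect_gt(path$nonzero[3], 0)
  # lambda = 0 equals the unpenalized maximum-likelihood fit
  ref <- stats::glm.fit(cbind(1, inst$x), inst$y,
                        family = stats::binomial())$coefficients
  expect_lt(max(abs(c(path$a0[4], path$beta[, 4]) - ref)), 1e-4)
})

test_that("KKT optimality conditions hold along the path", {
  for (seed in c(7, 8, 9)) {
    inst <- make_lasso_instance(n = 250, p = 10, seed = seed)
    path <- fit_l1_logistic_path(inst$x, inst$y, nlambda = 30, tol = 1e-12)
    for (k in seq_along(path$lambda)) {
      eta <- path$a0[k] + drop(inst$x %*% path$beta[, k])
      grad <- drop(crossprod(inst$x, inst$y - plogis(eta))) / nrow(inst$x)
      act <- path$beta[, k] != 0
      lam <- path$lambda[k]
      if (any(act)) {
        expect_lt(max(abs(grad[act] - lam * sign(path$beta[act, k]))), 1e-5)
      }
      if (any(!act)) {
        expect_lt(max(abs(grad[!act])), lam + 1e-5)
      }
    }
  }
})

test_that("the path agrees with the reference coordinate-descent solver", {
  skip_if_not_installed("glmnet")
  inst <- make_lasso_instance(n = 400, p = 12, seed = 42)
  path <- fit_l1_logistic_path(inst$x, inst$y, nlambda = 50, tol = 1e-12)
  ref <- glmnet::glmnet(inst$x, inst$y, family = "binomial",
                        lambda = path$lambda, standardize = FALSE,
                        thresh = 1e-12)
  expect_lt(max(abs(as.matrix(ref$beta) - path$beta)), 1e-4)
  expect_lt(max(abs(ref$a0 - path$a0)), 1e-4)
})

test_that("noise coefficients die before informative ones as lambda grows", {
  inst <- make_lasso_instance(n = 600, p = 2,
                              beta = c(1.5, 0), seed = 11)
  path <- fit_l1_logistic_path(inst$x, inst$y, nlambda = 60)
  died <- apply(path$beta != 0, 1, function(nz) {
    if (any(nz)) min(which(nz)) else Inf # first grid index with support
  })
  expect_lt(died["g1"], died["g2"])
})

test_that("unscaled or degenerate inputs are rejected", {
  inst <- make_lasso_instance(seed = 5)
  expect_error(fit_l1_logistic_path(inst$x * 3, inst$y), "scaled")
  expect_error(fit_l1_logistic_path(inst$x, inst$y * 2), "binary")
  expect_error(fit_l1_logistic_path(inst$x, rep(1, nrow(inst$x))),
               "both classes")
  expect_error(fit_l1_logistic_path(inst$x, inst$y,
                                    lambda = c(0.1, 0.2)), "decreasing")
})

test_that("cross-validation is deterministic, stratified and sane", {
  inst <- make_lasso_instance(n = 300, p = 6, seed = 21)
  cv1 <- cv_l1_logistic(inst$x, inst$y, n_folds = 5, seed = 3, nlambda = 40)
  cv2 <- cv_l1_logistic(inst$x, inst$y, n_folds = 5, seed = 3, nlambda = 40)
  expect_identical(cv1$cv_mean_deviance, cv2$cv_mean_deviance)
  expect_identical(cv1$fold, cv2$fold)
  # class proportions preserved within each fold
  tab <- table(cv1$fold, inst$y)
  expect_true(all(abs(tab[, 2] / rowSums(tab) - mean(inst$y)) < 0.12))
  # held-out deviance at lambda_max is the null-model deviance
  ybar <- mean(inst$y)
  nulldev <- -2 * (ybar * log(ybar) + (1 - ybar) * log(1 - ybar))
  expect_equal(cv1$cv_mean_deviance[1], nulldev, tolerance = 0.02)
  # the one-standard-error lambda is never below the minimizer
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  expect_error(cv_l1_logistic(inst$x, rep(c(0, 1), c(295, 5)), n_folds = 10),
               "stratified")
})

test_that("selection rules pick the documented path points", {
  inst <- make_lasso_instance(n = 400, p = 8,
                              beta = c(1.5, -1, 0.8, rep(0, 5)), seed = 33)
  cv <- cv_l1_logistic(inst$x, inst$y, n_folds = 5, seed = 9, nlambda = 50)
  smin <- select_lambda(cv, "cv_min")
  s1se <- select_lambda(cv, "cv_1se")
  expect_equal(smin$chosen_lambda, cv$lambda_min)
  expect_gte(s1se$chosen_lambda, smin$chosen_lambda)
  expect_true(all(s1se$selected_genes %in% cv$genes))
  k <- sort(unique(cv$nonzero))[2]
  st <- select_lambda(cv, "target_support", support = k)
  expect_equal(length(st$selected_genes), k)
  expect_equal(st$chosen_lambda,
               max(cv$lambda[cv$nonzero == k]))
  expect_error(select_lambda(cv, "target_support", support = 999),
               "attained sizes")
})

test_that("cv-selected model dominates every single gene out of sample", {
  cfg <- generator_config(n_malignant = 300, n_normal = 1200,
                          n_noise_genes = 20, seed = 71)
  m <- simulate_cells(cfg)
  st <- fit_scaling(m)
  sc <- apply_scaling(m, st)
  y <- as.integer(cell_info(m)$label == "malignant")
  # 70/30 split
  withr::with_seed(72, idx <- sample(n_cells(m), 0.7 * n_cells(m)))
  xtr <- t(sc$values[, idx]); xte <- t(sc$values[, -idx])
  cv <- cv_l1_logistic(xtr, y[idx], n_folds = 5, seed = 73, nlambda = 50)
  sel <- select_lambda(cv, "cv_min")
  k <- which(cv$lambda == sel$chosen_lambda)
  prob <- predict(cv, xte, type = "response")[, k]
  model_auc <- gene_auc(prob, y[-idx])
  single <- apply(xte, 2, function(v) {
    a <- gene_auc(v, y[-idx]); max(a, 1 - a)
  })
  expect_gt(model_auc, max(single))
})

test_that("strong planted support is recovered among noise genes", {
  # scaled-down version of the recovery experiment: 7 calibrated genes
  # among 100 nulls at n = 2,000 cells
  cfg <- generator_config(n_malignant = 400, n_normal = 1600,
                          n_noise_genes = 100, seed = 81)
  m <- simulate_cells(cfg)
  sc <- apply_scaling(m, fit_scaling(m))
  y <- as.integer(cell_info(m)$label == "malignant")
  cv <- cv_l1_logistic(t(sc$values), y, n_folds = 10, seed = 82)
  sel <- select_lambda(cv, "cv_1se")
  # every planted gene survives selection, and the model stays far sparser
  # than the candidate set (the 1-SE rule tolerates a few stray noise genes;
  # exact support identification is not a guarantee of cv-based selection)
  expect_true(all(reference_auc_spectrum()$gene %in% sel$selected_genes))
  expect_lte(length(sel$selected_genes), 25)
  smin <- select_lambda(cv, "cv_min")
  expect_true(all(reference_auc_spectrum()$gene %in% smin$selected_genes))
})
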