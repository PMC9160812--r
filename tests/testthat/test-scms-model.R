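scaled_toy <- function(v, labels) {
  m <- toy_matrix(v, labels)
  apply_scaling(m, fit_scaling(m))
}

test_that("final logistic fit matches a likelihood-grid oracle", {
  # 1 gene, 20 cells: compare against brute-force likelihood maximization
  withr::with_seed(61, {
    v <- matrix(c(rnorm(10, 6.5), rnorm(10, 5)), 1, 20,
                dimnames = list("g1", paste0("c", 1:20)))
    labels <- rep(c("malignant", "normal"), each = 10)
    sc <- scaled_toy(v, labels)
    fit <- fit_final_logistic(sc)
    y <- as.integer(labels == "malignant")
    z <- sc$values[1, ]
    loglik <- function(b0, b1) sum(y * (b0 + b1 * z) -
                                     log1p(exp(b0 + b1 * z)))
    grid <- expand.grid(b0 = seq(-3, 3, 0.002), b1 = seq(0, 6, 0.002))
    best <- grid[which.max(mapply(loglik, grid$b0, grid$b1)), ]
    expect_equal(fit$intercept, best$b0, tolerance = 2e-3)
    expect_equal(unname(fit$coefficients), best$b1, tolerance = 2e-3)
  })
})

test_that("a symmetric balanced toy yields a near-zero intercept", {
  v <- matrix(c(5, 6, 7, 3, 4, 5), 1, 6,
              dimnames = list("g1", paste0("c", 1:6)))
  sc <- scaled_toy(v, rep(c("malignant", "normal"), each = 3))
  fit <- fit_final_logistic(sc)
  expect_lt(abs(fit$intercept), 1e-6)
})

test_that("parameter recovery from a known logistic model", {
  withr::with_seed(62, {
    n <- 10000
    z <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:n)))
    truth <- c(2, 1, 0.5); b0 <- -2
    y <- rbinom(n, 1, plogis(b0 + drop(crossprod(z, truth))))
    m <- cell_matrix(z + 10, ifelse(y == 1, "malignant", "normal"),
                     values_kind = "normalized")
    sc <- apply_scaling(m, fit_scaling(m))
    fit <- fit_final_logistic(sc)
    cf <- c(fit$intercept, unname(fit$coefficients))
    # asymptotic standard errors from the information matrix at the fit
    eta <- fit$intercept + drop(crossprod(sc$values, fit$coefficients))
    w <- plogis(eta) * (1 - plogis(eta))
    xd <- cbind(1, t(sc$values))
    se <- sqrt(diag(solve(crossprod(xd, w * xd))))
    # truth on the scaled axis: coefficients multiply z-scores of unit-sd z
    truth_scaled <- c(b0, truth * apply(z, 1, sd))
    expect_true(all(abs(cf - truth_scaled) < 3 * se))
  })
})

test_that("perfect separation is detected, with a ridge fallback", {
  v <- matrix(c(9, 8, 7, 2, 1, 3), 1, 6,
              dimnames = list("g1", paste0("c", 1:6)))
  sc <- scaled_toy(v, rep(c("malignant", "normal"), each = 3))
  expect_error(fit_final_logistic(sc), "separation")
  fit <- fit_final_logistic(sc, ridge_on_separation = TRUE)
  expect_true(is.finite(fit$intercept))
  expect_gt(unname(fit$coefficients), 0)
})

test_that("scoring evaluates the logistic formula and its monotonicity", {
  model <- attach_scaling(
    reference_model(),
    tibble::tibble(gene = names(reference_model()$coefficients),
                   mean = 5, sd = 1))
  genes <- names(model$coefficients)
  # all-zero scaled expression: scms = logistic(intercept) -> "normal"
  v <- matrix(5, 7, 2, dimnames = list(genes, c("c1", "c2")))
  m <- cell_matrix(v, c("malignant", "normal"), values_kind = "normalized")
  sc <- score_cells(model, m)
  expect_equal(sc$scms, rep(plogis(-4.7082), 2))
  expect_equal(sc$scms[1], 0.00894, tolerance = 1e-4)
  expect_identical(sc$predicted_label, rep("normal", 2))
  # increasing a positive-coefficient gene strictly increases the score
  v2 <- v; v2["SPINK13", 1] <- 6
  sc2 <- score_cells(model, cell_matrix(v2, c("malignant", "normal"),
                                        values_kind = "normalized"))
  expect_gt(sc2$scms[1], sc$scms[1])
  expect_equal(sc2$scms[2], sc$scms[2])
  # x = 0 -> scms = 0.5
  m0 <- scmalig:::new_scms_model(
    intercept = 0, coefficients = c(g1 = 1),
    scaling = tibble::tibble(gene = "g1", mean = 2, sd = 1))
  sc0 <- score_cells(m0, cell_matrix(
    matrix(2, 1, 1, dimnames = list("g1", "c1")), "normal",
    values_kind = "normalized"))
  expect_equal(sc0$scms, 0.5)
})

test_that("scoring guards its preconditions", {
  model <- reference_model()
  v <- matrix(5, 7, 1, dimnames = list(names(model$coefficients), "c1"))
  m <- cell_matrix(v, "normal", values_kind = "normalized")
  expect_error(score_cells(model, m), "scaling")
  model <- attach_scaling(model, tibble::tibble(
    gene = names(model$coefficients), mean = 5, sd = 1))
  raw <- cell_matrix(v, "normal", values_kind = "counts")
  expect_error(score_cells(model, raw), "lognormalize")
  sub <- subset_cells(m, genes = rownames(v)[1:5])
  expect_error(score_cells(model, sub), "CAPN8")
  expect_warning(sc <- score_cells(model, sub, impute_missing = TRUE),
                 "imputing")
  expect_equal(nrow(sc), 1)
  expect_error(attach_scaling(reference_model(),
                              tibble::tibble(gene = "KRT18", mean = 1,
                                             sd = 1)),
               "missing")
})

test_that("the packaged reference model prints the published signature", {
  ref <- reference_model()
  expect_equal(ref$intercept, -4.7082)
  expect_equal(ref$coefficients,
               c(KRT18 = 0.8449, IRX2 = 0.7221, NAPSA = 1.2584,
                 SPINK13 = 2.3251, KRT7 = 1.5488, CAPN8 = 0.4969,
                 GPRC5A = 0.6344))
  expect_equal(ref$cutoff, 0.046)
  expect_null(ref$scaling)
})

test_that("cut-point selection mirrors prevalence and duplication", {
  withr::with_seed(63, {
    cfg <- generator_config(n_malignant = 150, n_normal = 1350,
                            n_noise_genes = 0, seed = 63)
    m <- simulate_cells(cfg)
    sc <- apply_scaling(m, fit_scaling(m))
    fit <- fit_final_logistic(sc)
    scores <- score_cells(fit, m)
    cut <- choose_cutoff(scores$scms, cell_info(m)$label)
    expect_lt(cut, 0.5) # low prevalence drives the optimum far down
    # duplicating every cell leaves the cut-point unchanged
    cut2 <- choose_cutoff(rep(scores$scms, 2), rep(cell_info(m)$label, 2))
    expect_equal(cut2, cut)
    # oracle equivalence on the probability scale
    oracle <- brute_force_youden(scores$scms,
                                 cell_info(m)$label == "malignant")
    cp <- youden_cutpoint(scores$scms, cell_info(m)$label)
    expect_equal(cp$sensitivity + cp$specificity - 1, oracle$j)
  })
})

test_that("evaluation reports AUC and the confusion at the cutoff", {
  scms <- c(0.9, 0.8, 0.1, 0.2, 0.3)
  labels <- c("malignant", "malignant", "normal", "normal", "normal")
  v <- matrix(qlogis(scms), 1, 5, dimnames = list("g1", paste0("c", 1:5)))
  model <- scmalig:::new_scms_model(
    intercept = 0, coefficients = c(g1 = 1),
    scaling = tibble::tibble(gene = "g1", mean = 0, sd = 1),
    cutoff = 0.5)
  m <- cell_matrix(v, labels, values_kind = "normalized")
  res <- evaluate_model(model, m)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  # random scores hover at AUC one half
  withr::with_seed(64, {
    vr <- matrix(rnorm(2000), 1, 2000,
                 dimnames = list("g1", paste0("c", 1:2000)))
    lr <- sample(rep(c("malignant", "normal"), 1000))
    mr <- cell_matrix(vr, lr, values_kind = "normalized")
    expect_equal(evaluate_model(model, mr)$auc, 0.5, tolerance = 0.05)
  })
})

test_that("model serialization round-trips scores bit-for-bit", {
  withr::with_seed(65, {
    cfg <- generator_config(n_malignant = 50, n_normal = 200,
                            n_noise_genes = 0, seed = 65)
    m <- simulate_cells(cfg)
    sc <- apply_scaling(m, fit_scaling(m))
    fit <- set_cutoff(fit_final_logistic(sc), 0.2)
    path <- withr::local_tempfile(fileext = ".json")
    write_scms_model(fit, path)
    back <- read_scms_model(path)
    expect_equal(back$intercept, fit$intercept)
    expect_equal(back$coefficients, fit$coefficients)
    expect_equal(back$cutoff, fit$cutoff)
    expect_equal(back$scaling, fit$scaling, ignore_attr = TRUE)
    s1 <- score_cells(fit, m); s2 <- score_cells(back, m)
    expect_lt(max(abs(s1$scms - s2$scms)), 1e-12)
    expect_identical(s1$predicted_label, s2$predicted_label)
    # reference model round-trip with a null scaling block
    rp <- withr::local_tempfile(fileext = ".json")
    write_scms_model(reference_model(), rp)
    ref2 <- read_scms_model(rp)
    expect_equal(ref2$coefficients, reference_model()$coefficients)
    expect_null(ref2$scaling)
  })
})
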