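test_that("calibrated Gaussian shift reproduces the target AUC", {
  # closed form: AUC = pnorm(shift / (sd * sqrt(2)))
  expect_equal(pnorm(calibrate_auc_shift(0.927) / sqrt(2)), 0.927)
  expect_equal(pnorm(calibrate_auc_shift(0.725, sd = 2) / (2 * sqrt(2))),
               0.725)
  # Monte-Carlo oracle: empirical AUC of shifted Gaussian pairs
  withr::with_seed(99, {
    for (target in c(0.927, 0.725)) {
      d <- calibrate_auc_shift(target)
      mc <- mean(rnorm(2e5, mean = d) > rnorm(2e5))
      expect_equal(mc, target, tolerance = 0.005)
    }
  })
  expect_error(calibrate_auc_shift(0.5), "strictly in")
  expect_error(calibrate_auc_shift(1), "strictly in")
  expect_error(calibrate_auc_shift(0.9, sd = 0), "positive")
})

test_that("generator honors shape, determinism and the size cap", {
  cfg <- generator_config(
    n_malignant = 5, n_normal = 10,
    informative_genes = tibble::tibble(gene = "G1", target_auc = 0.9,
                                       direction = "up"),
    n_noise_genes = 0, seed = 42)
  m <- simulate_cells(cfg)
  expect_equal(n_genes(m), 1)
  expect_equal(n_cells(m), 15)
  expect_identical(cell_info(m)$label,
                   rep(c("malignant", "normal"), c(5, 10)))
  m2 <- simulate_cells(cfg)
  expect_identical(m$values, m2$values)
  expect_identical(m$cells, m2$cells)
  big <- generator_config(n_malignant = 1e5, n_normal = 1e5,
                          n_noise_genes = 10000)
  expect_error(simulate_cells(big), "size cap")
})

test_that("planted genes reach their target AUCs empirically", {
  cfg <- generator_config(n_malignant = 2000, n_normal = 2000,
                          n_noise_genes = 3, seed = 7)
  m <- simulate_cells(cfg)
  labels <- cell_info(m)$label
  spectrum <- reference_auc_spectrum()
  n1 <- 2000; n2 <- 2000
  for (i in seq_len(nrow(spectrum))) {
    emp <- gene_auc(m$values[spectrum$gene[i], ], labels)
    # 3 binomial-pair standard errors (Hanley-McNeil upper bound ~ A(1-A))
    a <- spectrum$target_auc[i]
    se <- sqrt(a * (1 - a) * (1 / n1 + 1 / n2))
    expect_lt(abs(emp - a), 3 * se + 0.005)
  }
  for (g in paste0("NOISE000", 1:3)) {
    expect_lt(abs(gene_auc(m$values[g, ], labels) - 0.5), 0.04)
  }
})

test_that("down-regulated informative genes invert the AUC", {
  cfg <- generator_config(
    n_malignant = 1000, n_normal = 1000, base_mean = 8,
    informative_genes = tibble::tibble(gene = "DOWN1", target_auc = 0.85,
                                       direction = "down"),
    n_noise_genes = 0, seed = 5)
  m <- simulate_cells(cfg)
  auc <- gene_auc(m$values["DOWN1", ], cell_info(m)$label)
  expect_lt(auc, 0.5)
  expect_lt(abs(auc - (1 - 0.85)), 0.03)
})

test_that("zero inflation pulls discriminability toward chance", {
  aucs <- vapply(c(0, 0.3, 0.6), function(rate) {
    cfg <- generator_config(
      n_malignant = 1500, n_normal = 1500,
      informative_genes = tibble::tibble(gene = "G1", target_auc = 0.9,
                                         direction = "up"),
      n_noise_genes = 0, zero_inflation_rate = rate, seed = 11)
    m <- simulate_cells(cfg)
    gene_auc(m$values["G1", ], cell_info(m)$label)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  expect_gt(min(aucs), 0.5)
})

test_that("injected QC failures violate exactly the intended rule", {
  cfg <- generator_config(n_malignant = 20, n_normal = 80,
                          n_noise_genes = 13, seed = 2)
  m <- simulate_cells(cfg) # 20 genes total
  thr <- qc_thresholds(min_genes = 5, max_genes = 50,
                       max_mito_fraction = 0.20)
  inj <- inject_qc_failures(m, n_low_gene_cells = 2, n_high_gene_cells = 2,
                            n_high_mito_cells = 3, thresholds = thr)
  expect_equal(nrow(inj$modified), 7)
  expect_equal(anyDuplicated(inj$modified$cell_id), 0L)
  info <- cell_info(inj$matrix)
  low <- inj$modified$cell_id[inj$modified$reason == "low_genes"]
  high <- inj$modified$cell_id[inj$modified$reason == "high_genes"]
  mito <- inj$modified$cell_id[inj$modified$reason == "high_mito"]
  expect_true(all(info$genes_detected[info$cell_id %in% low] < 5))
  expect_true(all(info$genes_detected[info$cell_id %in% high] > 50))
  expect_true(all(info$mito_fraction[info$cell_id %in% mito] > 0.20))
  expect_equal(sum(info$mito_fraction > 0.20), 3)

  # zero-injection call is the identity
  ident <- inject_qc_failures(m, 0, 0, 0, thresholds = thr)
  expect_identical(ident$matrix$values, m$values)
  expect_equal(nrow(ident$modified), 0)
  expect_error(inject_qc_failures(m, 60, 30, 20, thresholds = thr),
               "more designated cells")
})

test_that("injected failures round-trip through the QC filter", {
  cfg <- generator_config(n_malignant = 10, n_normal = 40,
                          n_noise_genes = 13, seed = 8)
  m <- simulate_cells(cfg)
  thr <- qc_thresholds(min_genes = 5, max_genes = 50,
                       max_mito_fraction = 0.20)
  inj <- inject_qc_failures(m, 1, 1, 1, thresholds = thr)
  out <- qc_filter(inj$matrix, thr)
  expect_setequal(out$removed$cell_id, inj$modified$cell_id)
  expect_equal(n_cells(out$matrix), 47)
})
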