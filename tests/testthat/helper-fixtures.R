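# Small in-code fixtures shared across test files.

toy_matrix <- function(values, labels, kind = "normalized",
                       mito_fraction = NULL) {
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(paste0("gene", seq_len(nrow(values))),
                             paste0("cell", seq_len(ncol(values))))
  }
  cell_matrix(values, labels, values_kind = kind,
              mito_fraction = mito_fraction)
}

# brute-force all-pairs AUC with half credit for ties (independent oracle)
brute_force_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive Youden search over every value-anchored threshold (oracle)
brute_force_youden <- function(scores, pos) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- list(j = -Inf)
  for (t in cand) {
    sens <- mean(scores[pos] >= t)
    spec <- mean(scores[!pos] < t)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, sens = sens, spec = spec)
  }
  best
}

# step-up BH from first principles (independent oracle)
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

random_labeled_scores <- function(n, tie_rate = 0.3) {
  scores <- rnorm(n)
  if (tie_rate > 0) {
    mask <- runif(n) < tie_rate
    scores[mask] <- round(scores[mask], 0)
  }
  pos <- rep(FALSE, n)
  pos[sample(n, max(1, min(n - 1, rbinom(1, n, 0.3))))] <- TRUE
  list(scores = scores, pos = pos)
}

single_gene_config <- function(target_auc, n_per_class = 5000, seed = 1,
                               gene = "G1") {
  generator_config(
    n_malignant = n_per_class, n_normal = n_per_class,
    informative_genes = tibble::tibble(gene = gene, target_auc = target_auc,
                                       direction = "up"),
    n_noise_genes = 0, seed = seed
  )
}
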