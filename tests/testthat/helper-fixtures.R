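# Shared fixture builders and seeding helper for the suite.

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Random log-normalized-style expression matrix (non-negative, sparse-ish).
random_expr <- function(n_cells, n_genes, seed = 1, zero_frac = 0.3) {
  with_test_seed(seed, {
    vals <- matrix(rexp(n_cells * n_genes), n_cells, n_genes)
    vals[matrix(runif(n_cells * n_genes) < zero_frac,
                n_cells, n_genes)] <- 0
    expression_matrix(vals,
                      gene_ids = sprintf("g%03d", seq_len(n_genes)),
                      cell_ids = sprintf("c%03d", seq_len(n_cells)))
  })
}

# Random signature collection with both signs populated.
random_collection <- function(n_cytokines = 4, genes_per_side = 3,
                              seed = 1, gene_pool = sprintf("g%03d", 1:60)) {
  with_test_seed(seed, {
    sets <- lapply(seq_len(n_cytokines), function(k) {
      picked <- sample(gene_pool, 2 * genes_per_side)
      list(
        positive = weighted_gene_set(
          paste0("CY", k), "positive",
          picked[seq_len(genes_per_side)],
          round(runif(genes_per_side, 0.2, 3), 6)),
        negative = weighted_gene_set(
          paste0("CY", k), "negative",
          picked[genes_per_side + seq_len(genes_per_side)],
          round(runif(genes_per_side, 0.2, 3), 6)))
    })
    names(sets) <- paste0("CY", seq_len(n_cytokines))
    signature_collection(sets)
  })
}

# Brute-force squared adjusted distance: explicit loops over cells/genes,
# independent of the matrix-algebra implementation.
brute_force_distances <- function(expr, set, sigma2, use_weights = TRUE) {
  genes <- intersect(set$genes, colnames(expr))
  g <- length(genes)
  w <- set$weights[match(genes, set$genes)]
  wt <- if (use_weights) w * g / sum(w) else rep(1, g)
  out <- numeric(nrow(expr))
  for (c in seq_len(nrow(expr))) {
    acc <- 0
    for (j in seq_len(g)) {
      x <- as.numeric(expr[c, genes[j]])
      acc <- acc + wt[j] * x^2 / sigma2[[genes[j]]]
    }
    out[c] <- acc
  }
  out
}
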