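test_that("unit and total-variance estimators behave as documented", {
  expr <- random_expr(10, 5, seed = 2)
  tv <- estimate_technical_variance(expr, "unit")
  expect_equal(tv$sigma2_tech, rep(1, 5))

  # a constant gene hits the variance floor
  vals <- as.matrix(expr)
  vals[, 1] <- 0.5
  expr2 <- expression_matrix(vals)
  tv2 <- estimate_technical_variance(expr2, "total_variance")
  expect_equal(tv2$sigma2_tech[1], 1e-8)
  expect_equal(tv2$sigma2_tech[-1],
               apply(vals[, -1], 2, var), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("trend fit recovers a variance curve quadratic in the mean", {
  rel_err <- vapply(1:50, function(s) {
    with_test_seed(s, {
      n_genes <- 150; n_cells <- 120
      mu <- runif(n_genes, 2, 8)
      true_var <- 0.05 + 0.02 * mu^2
      vals <- matrix(rnorm(n_cells * n_genes,
                           mean = rep(mu, each = n_cells),
                           sd = rep(sqrt(true_var), each = n_cells)),
                     n_cells, n_genes)
      vals[vals < 0] <- 0
      expr <- expression_matrix(vals,
                                gene_ids = sprintf("g%03d", 1:n_genes),
                                cell_ids = sprintf("c%03d", 1:n_cells))
      tv <- estimate_technical_variance(expr, "trend_fit")
      central <- mu > quantile(mu, 0.2) & mu < quantile(mu, 0.8)
      median(abs(tv$sigma2_tech[central] - true_var[central]) /
               true_var[central])
    })
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("trend fit falls back for tiny gene panels", {
  expr <- random_expr(20, 10, seed = 3)
  expect_warning(tv <- estimate_technical_variance(expr, "trend_fit"),
                 "falling back")
  expect_identical(tv$method, "total_variance")
})

test_that("squared adjusted distances match closed forms and brute force", {
  # single gene, weight 1, x = 3, sigma2 = 1 -> 9
  expr <- expression_matrix(matrix(c(3, 0), 2, 1),
                            gene_ids = "g1", cell_ids = c("c1", "c2"))
  tech <- structure(list(gene_ids = "g1", sigma2_tech = 1,
                         method = "unit"), class = "TechnicalVariance")
  set <- weighted_gene_set("X", "positive", "g1", 1)
  d <- squared_adjusted_distances(expr, set, tech)
  expect_equal(unname(d), c(9, 0))    # all-zero cell -> origin distance 0

  # random instances against the loop oracle, including weight
  # normalization and genes missing from the matrix
  for (s in 1:20) {
    with_test_seed(100 + s, {
      n_cells <- sample(2:6, 1); n_genes <- sample(2:4, 1)
      expr <- random_expr(n_cells, n_genes, seed = 200 + s)
      sigma2 <- setNames(runif(n_genes, 0.1, 2), colnames(expr))
      tech <- structure(list(gene_ids = colnames(expr),
                             sigma2_tech = unname(sigma2),
                             method = "total_variance"),
                        class = "TechnicalVariance")
      n_in <- sample(seq_len(n_genes), 1)
      set <- weighted_gene_set("X", "positive",
                               c(sample(colnames(expr), n_in), "absent"),
                               runif(n_in + 1, 0.2, 3))
      for (uw in c(TRUE, FALSE)) {
        expect_equal(
          unname(squared_adjusted_distances(expr, set, tech,
                                            use_weights = uw)),
          brute_force_distances(expr, set, as.list(sigma2),
                                use_weights = uw),
          tolerance = 1e-10)
      }
    })
  }
  bad <- weighted_gene_set("X", "positive", "nope", 1)
  expect_error(squared_adjusted_distances(random_expr(3, 2), bad, tech),
               "no gene")
})

test_that("distances are invariant to gene order within the set", {
  expr <- random_expr(6, 5, seed = 31)
  tech <- estimate_technical_variance(expr, "total_variance")
  with_test_seed(32, {
    genes <- sample(colnames(expr), 4)
    w <- runif(4, 0.5, 2)
  })
  set1 <- weighted_gene_set("X", "positive", genes, w)
  perm <- c(3, 1, 4, 2)
  set2 <- weighted_gene_set("X", "positive", genes[perm], w[perm])
  expect_equal(squared_adjusted_distances(expr, set1, tech),
               squared_adjusted_distances(expr, set2, tech),
               tolerance = 1e-12)
})

test_that("gamma MLE recovers known shapes and flags degenerate input", {
  for (case in list(c(shape = 2, seed = 41), c(shape = 1, seed = 42))) {
    v <- with_test_seed(case[["seed"]],
                        rgamma(10000, shape = case[["shape"]], rate = 1))
    fit <- fit_gamma_mle(v)
    expect_true(fit$converged)
    expect_lt(abs(fit$shape - case[["shape"]]),
              if (case[["shape"]] == 2) 0.1 else 0.05)
  }
  expect_false(fit_gamma_mle(c(2, 2))$converged)      # < 3 positives
  expect_false(fit_gamma_mle(c(2, 2, 2, 0))$converged) # all equal
})

test_that("gamma MLE agrees with an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  v <- with_test_seed(43, rgamma(2000, shape = 3.2, rate = 0.7))
  fit <- fit_gamma_mle(v)
  ref <- fitdistrplus::fitdist(v, "gamma", method = "mle")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$rate, unname(ref$estimate["rate"]), tolerance = 1e-4)
})

test_that("gamma CDF scores match quadrature and handle fallbacks", {
  v <- with_test_seed(44, rgamma(500, shape = 2, rate = 1.5))
  fit <- fit_gamma_mle(v)
  expect_equal(unname(score_gene_set(0, fit)), 0)
  med <- stats::qgamma(0.5, fit$shape, fit$rate)
  expect_equal(unname(score_gene_set(med, fit)), 0.5, tolerance = 1e-9)

  d <- with_test_seed(45, runif(20, 0, 6))
  quad <- vapply(d, function(x) {
    stats::integrate(stats::dgamma, 0, x, shape = fit$shape,
                     rate = fit$rate, rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(unname(score_gene_set(d, fit)), quad, tolerance = 1e-8)

  # non-converged fit: empirical mid-ranks over all cells, zeros -> 0
  bad <- fit_gamma_mle(c(1, 1))
  d2 <- c(0, 3, 1, 3)
  expect_equal(unname(score_gene_set(d2, bad)),
               c(0, 3.5 / 4, 2 / 4, 3.5 / 4))
})

test_that("combine_scores reproduces the convex-combination arithmetic", {
  expect_equal(combine_scores(0.8, 0.2, 30, 30), 0.8)
  expect_equal(combine_scores(0.9, 0.123, 40, 0), 0.9)
  expect_equal(combine_scores(0.5, 0.7, 0, 10), 0.3)
  expect_equal(combine_scores(0.9, 0.3, 40, 20), (2 / 3) * 0.9 + (1 / 3) * 0.7)
  expect_error(combine_scores(0.5, 0.5, 0, 0), ">= 1")
})

test_that("mousse skips unmatched cytokines with a report", {
  expr <- random_expr(8, 6, seed = 51)
  sets <- list(GHOST = list(
    positive = weighted_gene_set("GHOST", "positive", "zz1", 1),
    negative = weighted_gene_set("GHOST", "negative", "zz2", 1)))
  sm <- suppressWarnings(mousse(expr, signature_collection(sets)))
  expect_identical(ncol(sm$values), 0L)
  expect_identical(sm$skipped, "GHOST")
})

test_that("positive_only equals the combination with the negative side off", {
  expr <- random_expr(40, 30, seed = 52, zero_frac = 0.4)
  col <- random_collection(n_cytokines = 3, genes_per_side = 5, seed = 53,
                           gene_pool = colnames(expr))
  full <- mousse(expr, col, component = "positive_only",
                 tech_method = "total_variance")
  # drop every negative set and score combined
  pos_only <- lapply(col$sets, function(p) {
    list(positive = p$positive,
         negative = weighted_gene_set(p$positive$name, "negative"))
  })
  comb <- mousse(expr, signature_collection(pos_only),
                 component = "combined", tech_method = "total_variance")
  expect_equal(full$values, comb$values, tolerance = 1e-12)
})

test_that("scores are invariant to cell order", {
  expr <- random_expr(25, 20, seed = 54)
  col <- random_collection(n_cytokines = 2, genes_per_side = 4, seed = 55,
                           gene_pool = colnames(expr))
  ref <- mousse(expr, col, tech_method = "total_variance")
  perm <- with_test_seed(56, sample(nrow(expr)))
  out <- mousse(expr[perm, ], col, tech_method = "total_variance")
  expect_equal(out$values, ref$values[perm, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("raising an in-set gene raises the distance and the score", {
  expr <- random_expr(30, 10, seed = 57, zero_frac = 0.2)
  tech <- estimate_technical_variance(expr, "total_variance")
  set <- weighted_gene_set("X", "positive", colnames(expr)[1:4],
                           c(1, 2, 0.5, 1.5))
  d0 <- squared_adjusted_distances(expr, set, tech)
  fit <- fit_gamma_mle(d0)
  s0 <- score_gene_set(d0, fit)
  bumped <- as.matrix(expr)
  bumped[7, 2] <- bumped[7, 2] + 1
  d1 <- squared_adjusted_distances(expression_matrix(bumped), set, tech)
  expect_gt(d1[7], d0[7])
  expect_identical(unname(d1[-7]), unname(d0[-7]))
  s1 <- score_gene_set(d1, fit)
  expect_gte(s1[7], s0[7])
})

test_that("unweighted unit-variance scoring reduces to plain VAM", {
  # from-scratch reimplementation of the whole unweighted pipeline on a
  # fully present 5 x 5 instance
  expr <- random_expr(5, 5, seed = 58, zero_frac = 0.2)
  set <- weighted_gene_set("X", "positive", colnames(expr),
                           runif(5, 0.5, 2))
  sets <- signature_collection(list(
    X = list(positive = set,
             negative = weighted_gene_set("X", "negative"))))
  sm <- mousse(expr, sets, component = "positive_only",
               tech_method = "unit", use_weights = FALSE)

  x <- as.matrix(expr)
  d_ref <- rowSums(x^2)                      # distance = sum of squares
  v <- d_ref[d_ref > 0]
  s_stat <- log(mean(v)) - mean(log(v))
  k <- mean(v)^2 / var(v)
  for (i in 1:200) {
    f <- log(k) - digamma(k) - s_stat
    if (abs(f) < 1e-10) break
    k <- k - f / (1 / k - trigamma(k))
  }
  s_ref <- pgamma(d_ref, shape = k, rate = k / mean(v))
  s_ref[d_ref == 0] <- 0
  expect_equal(unname(sm$values[, "X"]), unname(s_ref), tolerance = 1e-8)
})
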