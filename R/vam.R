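#' Estimate per-gene technical variance
#'
#' The modified Mahalanobis distance standardizes each gene by an estimate of
#' its technical (noise) variance so that deviations along noisy genes are
#' discounted while biological covariance is preserved. Three estimators are
#' provided:
#' \describe{
#'   \item{`trend_fit`}{fit a loess trend of per-gene variance against
#'     per-gene mean of the log-normalized values and take the fitted value
#'     at each gene's mean — the mean-variance-decomposition idiom for
#'     log-normalized data. Requires >= 32 genes with non-zero mean; falls
#'     back to `total_variance` with a warning otherwise.}
#'   \item{`total_variance`}{each gene's empirical variance.}
#'   \item{`unit`}{all ones (plain squared Euclidean distance).}
#' }
#' All estimates are floored at `1e-8`.
#'
#' @param expr cells x genes [expression_matrix()].
#' @param method `"trend_fit"` (default), `"total_variance"` or `"unit"`.
#' @param span loess span for `trend_fit`, default 0.5.
#'
#' @return list of class `TechnicalVariance` with `gene_ids`, `sigma2_tech`
#'   and `method`.
#' @export
estimate_technical_variance <- function(expr,
                                        method = c("trend_fit",
                                                   "total_variance",
                                                   "unit"),
                                        span = 0.5) {
  method <- match.arg(method)
  if (ncol(expr) < 1L) stop("need at least one gene")
  genes <- colnames(expr)
  if (method == "unit") {
    return(structure(list(gene_ids = genes,
                          sigma2_tech = rep(1, length(genes)),
                          method = "unit"),
                     class = "TechnicalVariance"))
  }
  mu <- as.numeric(Matrix::colMeans(expr))
  # E[x^2] - E[x]^2 with the n-1 denominator, sparse-safe
  ex2 <- as.numeric(Matrix::colMeans(expr^2))
  n <- nrow(expr)
  v <- if (n > 1L) (ex2 - mu^2) * n / (n - 1L) else rep(0, length(mu))
  v[v < 0] <- 0
  if (method == "trend_fit") {
    usable <- mu > 0
    if (sum(usable) < 32L) {
      warning("fewer than 32 genes with non-zero mean; ",
              "falling back to total_variance")
      method <- "total_variance"
    } else {
      fit <- loess(v[usable] ~ mu[usable], span = span, degree = 2,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct"))
      s2 <- rep(.TECH_VAR_EPS, length(mu))
      s2[usable] <- pmax(predict(fit, newdata = mu[usable]), .TECH_VAR_EPS)
      return(structure(list(gene_ids = genes, sigma2_tech = s2,
                            method = "trend_fit"),
                       class = "TechnicalVariance"))
    }
  }
  structure(list(gene_ids = genes,
                 sigma2_tech = pmax(v, .TECH_VAR_EPS),
                 method = "total_variance"),
            class = "TechnicalVariance")
}

#' @export
print.TechnicalVariance <- function(x, ...) {
  cat(sprintf("<TechnicalVariance> %d genes, method = %s\n",
              length(x$gene_ids), x$method))
  invisible(x)
}

#' Squared variance-adjusted distances from the origin for one gene set
#'
#' One column of the distance matrix M: for each cell `c`,
#' `M_c = sum_j w~_j * x_cj^2 / sigma2_j` over the `g` set genes present in
#' the expression matrix, where `w~_j = w_j * g / sum(w)` are the set weights
#' normalized to mean one (all `w~_j = 1` when `use_weights = FALSE`,
#' recovering the unweighted `diag(X_k (I_g sigma2)^-1 X_k^T)` form).
#' Distances are taken from the origin and use no covariance terms.
#'
#' @param expr cells x genes [expression_matrix()].
#' @param set a [weighted_gene_set()]; at least one of its genes must be
#'   present in `expr`.
#' @param tech a `TechnicalVariance` for the genes of `expr`.
#' @param use_weights apply the set weights (default `TRUE`).
#'
#' @return Named non-negative numeric vector, one entry per cell.
#' @export
squared_adjusted_distances <- function(expr, set, tech, use_weights = TRUE) {
  stopifnot(is(set, "WeightedGeneSet"), is(tech, "TechnicalVariance"))
  idx <- match(set$genes, colnames(expr))
  present <- !is.na(idx)
  if (!any(present)) {
    stop("no gene of set ", set$name, "/", set$sign,
         " is present in the expression matrix")
  }
  genes <- set$genes[present]
  g <- length(genes)
  w <- if (use_weights) {
    wsub <- set$weights[present]
    wsub * g / sum(wsub)
  } else {
    rep(1, g)
  }
  s2 <- tech$sigma2_tech[match(genes, tech$gene_ids)]
  if (anyNA(s2)) stop("technical variance missing for some set genes")
  x <- expr[, idx[present], drop = FALSE]
  d <- as.numeric((x * x) %*% (w / s2))
  names(d) <- rownames(expr)
  d
}

#' Maximum-likelihood gamma fit
#'
#' Fits a gamma distribution to the strictly positive elements of a distance
#' vector by maximum likelihood: the profile equation
#' `log(k) - digamma(k) = log(mean(v)) - mean(log(v))` is solved for the
#' shape by safeguarded Newton iteration from the method-of-moments start,
#' and the rate follows as `shape / mean(v)`. At least 3 positive,
#' non-identical values are required; otherwise `converged = FALSE` and
#' downstream scoring falls back to empirical ranks (see
#' [score_gene_set()]).
#'
#' @param values non-negative numeric vector (one column of M).
#' @param tol convergence tolerance on the profile gradient, default 1e-10.
#' @param max_iter maximum Newton iterations, default 200.
#'
#' @return list of class `GammaFit` with `shape`, `rate`, `n_nonzero`,
#'   `converged`.
#' @export
fit_gamma_mle <- function(values, tol = 1e-10, max_iter = 200L) {
  v <- values[values > 0]
  fail <- structure(list(shape = NA_real_, rate = NA_real_,
                         n_nonzero = length(v), converged = FALSE),
                    class = "GammaFit")
  if (length(v) < 3L) return(fail)
  m <- mean(v)
  s <- log(m) - mean(log(v))
  if (!is.finite(s) || s <= 0) return(fail)   # all values identical (s = 0)
  # method-of-moments start; the classic closed-form approximation of the
  # profile root is used when the moment estimate is degenerate
  k <- m^2 / var(v)
  if (!is.finite(k) || k <= 0) k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    f <- log(k) - digamma(k) - s
    if (abs(f) < tol) { converged <- TRUE; break }
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    # safeguard: halve the step until the iterate stays positive
    while (k_new <= 0) { step <- step / 2; k_new <- k - step }
    k <- k_new
  }
  if (!converged) {
    f <- log(k) - digamma(k) - s
    converged <- is.finite(f) && abs(f) < tol
  }
  structure(list(shape = k, rate = k / m, n_nonzero = length(v),
                 converged = converged),
            class = "GammaFit")
}

#' @export
print.GammaFit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<GammaFit> shape = %.4g, rate = %.4g (n+ = %d)\n",
                x$shape, x$rate, x$n_nonzero))
  } else {
    cat(sprintf("<GammaFit> not converged (n+ = %d)\n", x$n_nonzero))
  }
  invisible(x)
}

#' Calibrate distances to [0, 1] scores
#'
#' Maps each cell's squared adjusted distance through the fitted gamma CDF.
#' A distance of zero maps to score zero. If the gamma fit did not converge,
#' scores fall back to empirical mid-ranks divided by the number of cells,
#' with zero distances again mapped to zero.
#'
#' @param distances non-negative numeric vector (one column of M).
#' @param fit a `GammaFit` from [fit_gamma_mle()].
#' @return Numeric vector of scores in `[0, 1]`, same names as `distances`.
#' @export
score_gene_set <- function(distances, fit) {
  stopifnot(is(fit, "GammaFit"), all(distances >= 0))
  if (fit$converged) {
    s <- pgamma(distances, shape = fit$shape, rate = fit$rate)
  } else {
    s <- rank(distances, ties.method = "average") / length(distances)
  }
  s[distances == 0] <- 0
  s
}

#' Combine positive- and negative-set VAM scores
#'
#' The overall activity score is the set-size-weighted convex combination of
#' the positive-set score and one minus the negative-set score:
#' `s = n_pos/(n_pos+n_neg) * vam_pos + n_neg/(n_pos+n_neg) * (1 - vam_neg)`.
#' With an empty negative set this reduces to `vam_pos`; with an empty
#' positive set, to `1 - vam_neg`.
#'
#' @param vam_pos positive-set score(s) in `[0, 1]`.
#' @param vam_neg negative-set score(s) in `[0, 1]`.
#' @param n_pos,n_neg non-negative matched set sizes; `n_pos + n_neg >= 1`.
#' @return Combined score(s) in `[0, 1]`.
#' @export
combine_scores <- function(vam_pos, vam_neg, n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg < 1) stop("n_pos + n_neg must be >= 1")
  if (n_pos == 0) return(1 - vam_neg)
  if (n_neg == 0) return(vam_pos)
  (n_pos * vam_pos + n_neg * (1 - vam_neg)) / (n_pos + n_neg)
}

#' Score cells against a signature collection
#'
#' The full scoring pipeline: estimate technical variance once on the target
#' matrix, then for every cytokine intersect its positive and negative sets
#' with the target genes, compute squared adjusted distances, fit a gamma to
#' the non-zero distances of each signed set, map distances through the
#' gamma CDF and combine the signed components. `n_pos`/`n_neg` in the
#' combination are the intersected (target-matched) set sizes. Cytokines
#' with zero matching genes in the set(s) the requested component needs are
#' omitted from the result and listed in `skipped`.
#'
#' @param expr cells x genes [expression_matrix()] of log-normalized values.
#' @param sets a [signature_collection()].
#' @param component `"combined"` (default), `"positive_only"` or
#'   `"negative_only"`. `positive_only` returns the positive-set VAM score;
#'   `negative_only` returns `1 - vam_neg`.
#' @param tech_method passed to [estimate_technical_variance()].
#' @param use_weights apply signature weights in the distances (default
#'   `TRUE`).
#'
#' @return A [score_matrix()] whose `details` element records per-cytokine
#'   matched sizes and gamma fits.
#' @export
mousse <- function(expr, sets,
                   component = c("combined", "positive_only",
                                 "negative_only"),
                   tech_method = c("trend_fit", "total_variance", "unit"),
                   use_weights = TRUE) {
  component <- match.arg(component)
  tech_method <- match.arg(tech_method)
  stopifnot(is(sets, "SignatureCollection"))
  if (length(sets) == 0L) stop("signature collection is empty")
  tech <- estimate_technical_variance(expr, method = tech_method)
  genes <- colnames(expr)
  n_cells <- nrow(expr)

  side_score <- function(set) {
    matched <- sum(set$genes %in% genes)
    if (matched == 0L) {
      return(list(n = 0L, score = NULL, fit = NULL))
    }
    d <- squared_adjusted_distances(expr, set, tech,
                                    use_weights = use_weights)
    fit <- fit_gamma_mle(d)
    list(n = matched, score = score_gene_set(d, fit), fit = fit)
  }

  cols <- list()
  details <- list()
  skipped <- character(0)
  for (cy in names(sets)) {
    pair <- sets$sets[[cy]]
    pos <- side_score(pair$positive)
    neg <- side_score(pair$negative)
    ok <- switch(component,
                 combined = pos$n + neg$n >= 1L,
                 positive_only = pos$n >= 1L,
                 negative_only = neg$n >= 1L)
    if (!ok) {
      skipped <- c(skipped, cy)
      next
    }
    s <- switch(component,
                combined = {
                  vp <- if (pos$n) pos$score else rep(0, n_cells)
                  vn <- if (neg$n) neg$score else rep(0, n_cells)
                  combine_scores(vp, vn, pos$n, neg$n)
                },
                positive_only = pos$score,
                negative_only = 1 - neg$score)
    cols[[cy]] <- s
    details[[cy]] <- list(n_pos = pos$n, n_neg = neg$n,
                          gamma_pos = pos$fit, gamma_neg = neg$fit)
  }
  values <- do.call(cbind, cols)
  if (is.null(values)) {
    values <- matrix(numeric(0), nrow = n_cells, ncol = 0,
                     dimnames = list(rownames(expr), character(0)))
  } else {
    rownames(values) <- rownames(expr)
  }
  score_matrix(values, component = component, skipped = skipped,
               details = details)
}
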