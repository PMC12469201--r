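#' Two-sided Wilcoxon rank-sum test
#'
#' Normal approximation with tie correction and continuity correction (the
#' convention of the single-cell DE toolchain), wrapping
#' [stats::wilcox.test()]. The statistic returned is the Mann-Whitney U for
#' `x`.
#'
#' @param x numeric vector, target group (length >= 1).
#' @param y numeric vector, reference group (length >= 1).
#' @return list with `statistic` (U for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be non-empty")
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Vectorized one-vs-rest rank-sum p-values for every column of `mat`
# (cells x genes) with the target group given by logical `in_group`.
# Column ranks are computed once by the caller and reused across labels;
# `tie_term` is sum(t^3 - t) per gene for the tie-corrected variance.
# Returns two-sided normal-approximation p-values with continuity
# correction, matching wilcox.test(exact = FALSE, correct = TRUE).
.rank_sum_pvalues <- function(ranks, tie_term, in_group) {
  n1 <- sum(in_group)
  n2 <- nrow(ranks) - n1
  N <- n1 + n2
  r1 <- Matrix::colSums(ranks[in_group, , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  z <- abs(u - mu) - 0.5
  z[z < 0] <- 0
  p <- ifelse(sigma2 <= 0, 1, 2 * pnorm(-z / sqrt(sigma2)))
  pmin(p, 1)
}

.column_ranks <- function(mat) {
  apply(as.matrix(mat), 2L, rank, ties.method = "average")
}

.tie_terms <- function(mat) {
  apply(as.matrix(mat), 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
}

#' Average log2 fold-change between two groups of log-normalized values
#'
#' De-logs the natural-log values, takes group means, adds a pseudocount and
#' returns the log2 ratio:
#' `log2((mean(exp(x) - 1) + pc) / (mean(exp(y) - 1) + pc))`.
#'
#' @param x numeric vector of log-normalized values, target group.
#' @param y numeric vector, reference group.
#' @param pseudocount positive stabilizer added to each de-logged mean,
#'   default 1.
#' @return the average log2 fold-change.
#' @export
avg_log2fc <- function(x, y, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2((mean(expm1(x)) + pseudocount) / (mean(expm1(y)) + pseudocount))
}

#' Build signed weighted cytokine signatures by one-vs-rest DE
#'
#' For every non-control condition, compares its cells against all other
#' cells (all other cytokines plus the control) with a Wilcoxon rank-sum
#' test per gene, keeps genes significant at `alpha` (Bonferroni-adjusted by
#' default), ranks them by absolute average log2 fold-change and retains the
#' top `num_genes`. Retained genes are split by fold-change sign into a
#' positive and a negative [weighted_gene_set()], weighted by `|log2fc|`;
#' genes with a fold-change of exactly zero are discarded. Ties at the
#' retention boundary break by smaller p-value, then lexicographic gene id.
#'
#' @param data a [labeled_dataset()] of log-normalized expression with >= 2
#'   distinct labels and >= 3 cells per condition.
#' @param num_genes per-cytokine cap on `n_pos + n_neg`, default 60.
#' @param alpha significance level applied to the (adjusted) p-values,
#'   default 0.05.
#' @param control_label optional label whose cells join every rest group but
#'   receive no signature of their own.
#' @param min_pct optional pre-filter: test only genes detected (value > 0)
#'   in at least this fraction of cells in the target or rest group.
#'   Default 0 (off).
#' @param adjust `"bonferroni"` (default) or `"none"` — which p-value the
#'   `alpha` filter applies to.
#' @param pseudocount passed to [avg_log2fc()].
#'
#' @return A [signature_collection()] with full per-gene provenance.
#' @export
build_signatures <- function(data, num_genes = 60L, alpha = 0.05,
                             control_label = NULL, min_pct = 0,
                             adjust = c("bonferroni", "none"),
                             pseudocount = 1) {
  stopifnot(is(data, "LabeledDataset"), num_genes >= 1L,
            alpha > 0, alpha <= 1, min_pct >= 0, min_pct <= 1)
  adjust <- match.arg(adjust)
  expr <- data$expr
  labels <- data$labels
  conditions <- sort(unique(labels))
  if (length(conditions) < 2L) stop("need >= 2 distinct labels")
  counts <- table(labels)
  if (any(counts < 3L)) {
    stop("condition(s) with < 3 cells: ",
         paste(names(counts)[counts < 3L], collapse = ", "))
  }
  targets <- setdiff(conditions, control_label)
  if (length(targets) == 0L) stop("no non-control conditions to test")

  dense <- as.matrix(expr)
  ranks <- .column_ranks(dense)
  tie_term <- .tie_terms(dense)
  demeans <- expm1(dense)            # de-logged values, reused per label
  pct_pos <- dense > 0

  sets <- list()
  prov <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    cy <- targets[ti]
    in_group <- labels == cy
    keep <- rep(TRUE, ncol(dense))
    if (min_pct > 0) {
      pct1 <- colMeans(pct_pos[in_group, , drop = FALSE])
      pct2 <- colMeans(pct_pos[!in_group, , drop = FALSE])
      keep <- pmax(pct1, pct2) >= min_pct
    }
    genes <- colnames(dense)[keep]
    p <- .rank_sum_pvalues(ranks[, keep, drop = FALSE], tie_term[keep],
                           in_group)
    lfc <- log2((colMeans(demeans[in_group, keep, drop = FALSE]) +
                   pseudocount) /
                (colMeans(demeans[!in_group, keep, drop = FALSE]) +
                   pseudocount))
    p_adj <- pmin(1, p * sum(keep))
    p_filter <- if (adjust == "bonferroni") p_adj else p
    sig <- if (alpha >= 1) which(lfc != 0) else
      which(p_filter < alpha & lfc != 0)
    if (length(sig) == 0L) {
      warning("no gene passes alpha = ", alpha, " for condition ", cy,
              "; its signature is empty")
      sel <- integer(0)
    } else {
      ord <- sig[order(-abs(lfc[sig]), p[sig], genes[sig])]
      sel <- ord[seq_len(min(num_genes, length(ord)))]
    }
    up <- sel[lfc[sel] > 0]
    dn <- sel[lfc[sel] < 0]
    sets[[cy]] <- list(
      positive = weighted_gene_set(cy, "positive", genes[up],
                                   abs(lfc[up])),
      negative = weighted_gene_set(cy, "negative", genes[dn],
                                   abs(lfc[dn])))
    prov[[ti]] <- data.frame(
      cytokine = rep(cy, length(sel)), gene = genes[sel],
      log2fc = lfc[sel],
      p_value = p[sel], p_adjusted = p_adj[sel],
      stringsAsFactors = FALSE)
  }
  provenance <- do.call(rbind, c(prov, list(make.row.names = FALSE)))
  signature_collection(sets, provenance,
                       num_genes_requested = num_genes)
}

#' Per-cytokine minimum absolute log2 fold-change of retained genes
#'
#' The effective selection threshold each cytokine's signature implies: the
#' smallest `|log2fc|` (equivalently the smallest weight) among its retained
#' genes. Cytokines whose signature is empty are reported as `NA`.
#'
#' @param collection a [signature_collection()].
#' @return Named numeric vector, one entry per cytokine.
#' @export
min_abs_log2fc_report <- function(collection) {
  stopifnot(is(collection, "SignatureCollection"))
  if (length(collection$sets) == 0L) stop("collection is empty")
  vapply(collection$sets, function(pair) {
    w <- c(pair$positive$weights, pair$negative$weights)
    if (length(w) == 0L) NA_real_ else min(w)
  }, numeric(1))
}
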