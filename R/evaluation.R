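#' Stratified k-fold assignment
#'
#' Within each label, cells are shuffled (seeded) and dealt round-robin into
#' `k` folds, so per-label fold counts differ by at most one.
#'
#' @param labels per-cell condition labels.
#' @param k number of folds, default 5.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return Integer vector of fold indices in `1..k`, one per cell.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(k >= 2L)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("label(s) with fewer than k = ", k, " cells: ",
         paste(names(counts)[counts < k], collapse = ", "))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' One-vs-rest AUC-ROC
#'
#' The probability that a randomly chosen positive cell outranks a randomly
#' chosen negative cell, ties counted one half (the Mann-Whitney
#' formulation). Scores are taken as-is: higher must mean more active; no
#' direction auto-selection is performed.
#'
#' @param scores per-cell continuous activity estimates.
#' @param is_positive per-cell logical, `TRUE` for the target class.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc_ovr <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC
#'
#' Interpolation-free step integration over the distinct score thresholds:
#' operating points are visited from the highest threshold down, and the
#' area accrues as `sum((recall_i - recall_{i-1}) * precision_i)`. With all
#' scores tied, this yields the prevalence of positives.
#'
#' @inheritParams roc_auc_ovr
#' @return PR-AUC in `[0, 1]`, or `NA` when there are no positives.
#' @export
pr_auc <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  if (n_pos == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_positive[ord]
  # cumulative counts at each distinct threshold (score >= thr)
  idx <- findInterval(-thr, -s, left.open = FALSE)  # last index with s >= thr
  tp <- cumsum(pos)[idx]
  n_at <- idx
  recall <- tp / n_pos
  precision <- tp / n_at
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)
}

#' Optimal ROC threshold by closest-to-top-left criterion
#'
#' Evaluates `(1 - sensitivity)^2 + (1 - specificity)^2` at every ROC
#' operating point — midpoints between consecutive distinct scores plus
#' sentinels below and above all scores — under the strict binarization
#' `predicted positive iff score > threshold`. Returns the minimizing
#' threshold; ties break toward higher specificity, then lower threshold.
#'
#' @inheritParams roc_auc_ovr
#' @return list with `threshold`, `sensitivity`, `specificity`, `criterion`.
#' @export
optimal_threshold <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to pick a threshold")
  }
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            max(u) + 1)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & is_positive) / n_pos
    spec <- sum(!pred & !is_positive) / n_neg
    crit <- (1 - sens)^2 + (1 - spec)^2
    if (is.null(best) || crit < best$criterion - 1e-15 ||
        (abs(crit - best$criterion) <= 1e-15 &&
         (spec > best$specificity + 1e-15 ||
          (abs(spec - best$specificity) <= 1e-15 && t < best$threshold)))) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   criterion = crit)
    }
  }
  best
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Binarizes with the strict rule `predicted positive iff score >
#' threshold` and returns the nine threshold metrics. Ratios with a zero
#' denominator are reported as `NA` rather than zero.
#'
#' @inheritParams roc_auc_ovr
#' @param threshold binarization cut.
#' @return Named numeric vector: `sensitivity`, `specificity`, `precision`,
#'   `npv`, `f1`, `prevalence`, `detection_rate`, `detection_prevalence`,
#'   `balanced_accuracy`.
#' @export
binarize_and_confusion <- function(scores, is_positive, threshold) {
  is_positive <- as.logical(is_positive)
  stopifnot(length(scores) == length(is_positive))
  pred <- scores > threshold
  tp <- sum(pred & is_positive)
  fp <- sum(pred & !is_positive)
  fn <- sum(!pred & is_positive)
  tn <- sum(!pred & !is_positive)
  n <- tp + fp + fn + tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec, precision = prec, npv = npv,
    f1 = f1, prevalence = (tp + fn) / n, detection_rate = tp / n,
    detection_prevalence = (tp + fp) / n,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else
      (sens + spec) / 2)
}

.METRIC_NAMES <- c("auc_roc", "pr_auc", "sensitivity", "specificity",
                   "precision", "npv", "f1", "prevalence", "detection_rate",
                   "detection_prevalence", "balanced_accuracy")

# All eleven metrics for one cytokine's scores on one fold's test cells.
.metrics_one <- function(scores, is_positive) {
  out <- setNames(rep(NA_real_, length(.METRIC_NAMES)), .METRIC_NAMES)
  if (sum(is_positive) == 0L || sum(!is_positive) == 0L) return(out)
  out["auc_roc"] <- roc_auc_ovr(scores, is_positive)
  out["pr_auc"] <- pr_auc(scores, is_positive)
  thr <- optimal_threshold(scores, is_positive)
  out[names(binarize_and_confusion(scores, is_positive, thr$threshold))] <-
    binarize_and_confusion(scores, is_positive, thr$threshold)
  out
}

#' Built-in benchmark scorers
#'
#' Scorer factories for [benchmark()]. Every scorer is a function
#' `f(test_expr, signatures, train_expr, train_labels)` returning a cells x
#' cytokines numeric matrix for the test cells (columns it cannot produce
#' are simply absent).
#'
#' * `scorer_mousse(component, ...)` — the signed weighted VAM pipeline.
#' * `scorer_naive(cytokine_to_gene)` — ligand-expression baseline; with
#'   `NULL` the cytokine name itself is used as the gene id.
#' * `scorer_mean_set(side)` — unweighted mean over the signature's
#'   positive (default) or negative genes.
#'
#' @param component,tech_method,use_weights passed to [mousse()].
#' @param cytokine_to_gene named map for [naive_ligand_score()].
#' @param side which signed set feeds the mean-of-set baseline.
#' @return A scorer function.
#' @name scorers
NULL

#' @rdname scorers
#' @export
scorer_mousse <- function(component = "combined",
                          tech_method = "trend_fit", use_weights = TRUE) {
  function(test_expr, signatures, train_expr, train_labels) {
    sm <- mousse(test_expr, signatures, component = component,
                 tech_method = tech_method, use_weights = use_weights)
    sm$values
  }
}

#' @rdname scorers
#' @export
scorer_naive <- function(cytokine_to_gene = NULL) {
  function(test_expr, signatures, train_expr, train_labels) {
    map <- cytokine_to_gene
    if (is.null(map)) {
      map <- setNames(as.list(names(signatures)), names(signatures))
    }
    naive_ligand_score(test_expr, map)$values
  }
}

#' @rdname scorers
#' @export
scorer_mean_set <- function(side = c("positive", "negative")) {
  side <- match.arg(side)
  function(test_expr, signatures, train_expr, train_labels) {
    plain <- lapply(signatures$sets, function(p) p[[side]]$genes)
    plain <- plain[lengths(plain) > 0]
    if (length(plain) == 0L) {
      return(matrix(numeric(0), nrow = nrow(test_expr), ncol = 0,
                    dimnames = list(rownames(test_expr), NULL)))
    }
    mean_set_score(test_expr, plain)$values
  }
}

#' Cross-validated benchmark of scoring methods
#'
#' Runs stratified k-fold cross-validation on a labeled stimulation
#' dataset: per fold, signatures are built on the training cells only, every
#' scorer is applied to the held-out cells, and all eleven metrics are
#' computed per cytokine (positives = test cells carrying that cytokine's
#' label) and averaged over folds. A best-method summary reports, per
#' metric, the proportion of cytokines for which each method attains the
#' highest value; ties are split fractionally so proportions sum to one.
#'
#' @param data a [labeled_dataset()] of log-normalized expression.
#' @param methods named list of scorer functions (see [scorers]).
#' @param k folds, default 5.
#' @param seed seed for the fold assignment.
#' @param num_genes,alpha,control_label,min_pct passed to
#'   [build_signatures()] on each training split.
#'
#' @return list with `metrics` (data frame keyed by cytokine x method) and
#'   `best_proportion` (metric x method proportion matrix).
#' @export
benchmark <- function(data, methods, k = 5L, seed = 1L, num_genes = 60L,
                      alpha = 0.05, control_label = NULL, min_pct = 0) {
  stopifnot(is(data, "LabeledDataset"), length(methods) >= 1L,
            !is.null(names(methods)))
  folds <- stratified_kfold(data$labels, k = k, seed = seed)
  cytokines <- sort(setdiff(unique(data$labels), control_label))

  acc <- list()   # acc[[method]][[cytokine]] = matrix folds x metrics
  for (f in seq_len(k)) {
    train <- folds != f
    sig <- suppressWarnings(build_signatures(
      labeled_dataset(data$expr[train, , drop = FALSE],
                      data$labels[train]),
      num_genes = num_genes, alpha = alpha,
      control_label = control_label, min_pct = min_pct))
    test_expr <- data$expr[!train, , drop = FALSE]
    test_labels <- data$labels[!train]
    for (m in names(methods)) {
      sc <- methods[[m]](test_expr, sig,
                         data$expr[train, , drop = FALSE],
                         data$labels[train])
      for (cy in cytokines) {
        vals <- if (!is.null(colnames(sc)) && cy %in% colnames(sc)) {
          .metrics_one(sc[, cy], test_labels == cy)
        } else {
          setNames(rep(NA_real_, length(.METRIC_NAMES)), .METRIC_NAMES)
        }
        acc[[m]][[cy]] <- rbind(acc[[m]][[cy]], vals)
      }
    }
  }

  rows <- list()
  for (m in names(methods)) {
    for (cy in cytokines) {
      avg <- colMeans(acc[[m]][[cy]], na.rm = TRUE)
      avg[is.nan(avg)] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cytokine = cy, method = m, t(avg), stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  best <- matrix(0, nrow = length(.METRIC_NAMES), ncol = length(methods),
                 dimnames = list(.METRIC_NAMES, names(methods)))
  for (met in .METRIC_NAMES) {
    n_counted <- 0L
    for (cy in cytokines) {
      v <- vapply(names(methods), function(m) {
        metrics[metrics$cytokine == cy & metrics$method == m, met]
      }, numeric(1))
      if (all(is.na(v))) next
      n_counted <- n_counted + 1L
      top <- which(v == max(v, na.rm = TRUE))
      best[met, top] <- best[met, top] + 1 / length(top)
    }
    if (n_counted > 0L) best[met, ] <- best[met, ] / n_counted
  }
  list(metrics = metrics, best_proportion = best)
}

#' Pairwise one-vs-one benchmark
#'
#' For every ordered pair of distinct cytokines, trains a signature for the
#' first cytokine against only the second (two-condition dataset) on the
#' training cells and evaluates the requested metric on the held-out cells
#' of those two conditions — the discrimination analysis for functionally
#' similar cytokines.
#'
#' @inheritParams benchmark
#' @param metric one of the eleven metric names, default `"pr_auc"`.
#' @return Square matrix (target cytokine x contrast cytokine) of the
#'   metric; the diagonal is `NA`.
#' @export
pairwise_benchmark <- function(data, metric = "pr_auc", k = 5L, seed = 1L,
                               num_genes = 60L, alpha = 0.05,
                               control_label = NULL) {
  stopifnot(metric %in% .METRIC_NAMES)
  folds <- stratified_kfold(data$labels, k = k, seed = seed)
  cytokines <- sort(setdiff(unique(data$labels), control_label))
  out <- matrix(NA_real_, length(cytokines), length(cytokines),
                dimnames = list(cytokines, cytokines))
  for (a in cytokines) {
    for (b in setdiff(cytokines, a)) {
      vals <- numeric(0)
      for (f in seq_len(k)) {
        sel_train <- folds != f & data$labels %in% c(a, b)
        sel_test <- folds == f & data$labels %in% c(a, b)
        sig <- suppressWarnings(build_signatures(
          labeled_dataset(data$expr[sel_train, , drop = FALSE],
                          data$labels[sel_train]),
          num_genes = num_genes, alpha = alpha))
        sm <- mousse(data$expr[sel_test, , drop = FALSE], sig)
        if (!a %in% colnames(sm$values)) next
        vals <- c(vals, .metrics_one(sm$values[, a],
                                     data$labels[sel_test] == a)[metric])
      }
      if (length(vals)) out[a, b] <- mean(vals, na.rm = TRUE)
    }
  }
  out
}
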