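#' Baseline: normalized ligand expression as activity proxy
#'
#' For each cytokine whose name maps to a gene present in the expression
#' matrix, the cytokine's score column is that gene's normalized expression,
#' verbatim. Unmappable cytokines are omitted and reported — an
#' intentionally naive baseline.
#'
#' @param expr cells x genes [expression_matrix()].
#' @param cytokine_to_gene named character vector or list mapping cytokine
#'   name to its ligand gene id (matching is case-insensitive on the gene
#'   id).
#' @return list with `values` (cells x cytokines matrix) and `skipped`.
#' @export
naive_ligand_score <- function(expr, cytokine_to_gene) {
  if (length(cytokine_to_gene) == 0L) stop("cytokine_to_gene map is empty")
  map <- unlist(cytokine_to_gene)
  idx <- match(tolower(map), tolower(colnames(expr)))
  keep <- !is.na(idx)
  values <- as.matrix(expr[, idx[keep], drop = FALSE])
  colnames(values) <- names(map)[keep]
  list(values = values, skipped = names(map)[!keep])
}

#' Read a ligand-to-receptor mapping table
#'
#' Two TAB-separated columns: ligand gene id, then a comma-separated list of
#' receptor gene ids.
#'
#' @param path path to the mapping file.
#' @return Named list (ligand -> character vector of receptors).
#' @export
read_lr_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("ligand-receptor map needs two TAB columns")
  receptors <- strsplit(tab[[2L]], ",", fixed = TRUE)
  receptors <- lapply(receptors, trimws)
  if (any(lengths(receptors) == 0L)) {
    stop("every ligand needs at least one receptor")
  }
  setNames(receptors, tab[[1L]])
}

.receptor_means <- function(expr, lr_map, cytokine_to_gene) {
  map <- unlist(cytokine_to_gene)
  out <- list()
  skipped <- character(0)
  for (cy in names(map)) {
    ligand <- map[[cy]]
    receptors <- lr_map[[ligand]]
    idx <- match(tolower(receptors), tolower(colnames(expr)))
    idx <- idx[!is.na(idx)]
    if (is.null(receptors) || length(idx) == 0L) {
      skipped <- c(skipped, cy)
      next
    }
    out[[cy]] <- as.numeric(Matrix::rowMeans(expr[, idx, drop = FALSE]))
  }
  list(cols = out, skipped = skipped)
}

#' Baseline: mean receptor expression as activity proxy
#'
#' Per cytokine, the mean of its receptors' normalized expression columns;
#' receptors absent from the matrix are dropped, and a cytokine with no
#' remaining receptor (or no map entry) is omitted and reported.
#'
#' @inheritParams naive_ligand_score
#' @param lr_map named list from [read_lr_map()] (ligand gene -> receptors).
#' @return list with `values` and `skipped`.
#' @export
receptor_score <- function(expr, lr_map, cytokine_to_gene) {
  if (length(cytokine_to_gene) == 0L) stop("cytokine_to_gene map is empty")
  res <- .receptor_means(expr, lr_map, cytokine_to_gene)
  values <- do.call(cbind, res$cols)
  if (is.null(values)) {
    values <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
  }
  rownames(values) <- rownames(expr)
  list(values = values, skipped = res$skipped)
}

#' Baseline: ligand x mean-receptor product score
#'
#' Per cell, the ligand's normalized expression multiplied by the mean of
#' its receptors' expression — the ligand-receptor co-expression idiom of
#' cell-cell communication methods. Requires both the ligand and at least
#' one receptor in the matrix; other cytokines are omitted and reported.
#'
#' @inheritParams receptor_score
#' @return list with `values` and `skipped`.
#' @export
product_score <- function(expr, lr_map, cytokine_to_gene) {
  if (length(cytokine_to_gene) == 0L) stop("cytokine_to_gene map is empty")
  map <- unlist(cytokine_to_gene)
  rec <- .receptor_means(expr, lr_map, cytokine_to_gene)
  lig_idx <- match(tolower(map), tolower(colnames(expr)))
  out <- list()
  skipped <- character(0)
  for (i in seq_along(map)) {
    cy <- names(map)[i]
    if (is.na(lig_idx[i]) || is.null(rec$cols[[cy]])) {
      skipped <- c(skipped, cy)
      next
    }
    out[[cy]] <- as.numeric(expr[, lig_idx[i]]) * rec$cols[[cy]]
  }
  values <- do.call(cbind, out)
  if (is.null(values)) {
    values <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
  }
  rownames(values) <- rownames(expr)
  list(values = values, skipped = skipped)
}

#' Baseline: unweighted mean expression over a plain gene set
#'
#' Per cell and per set, the unweighted mean of the matched genes'
#' normalized expression — the mean-of-markers scoring used by
#' perturbation-signature baselines. Sets with no gene in the matrix are
#' omitted and reported.
#'
#' @param expr cells x genes [expression_matrix()].
#' @param sets named list of character vectors (plain gene sets).
#' @return list with `values` (cells x sets) and `skipped`.
#' @export
mean_set_score <- function(expr, sets) {
  if (length(sets) == 0L) stop("no gene sets supplied")
  out <- list()
  skipped <- character(0)
  for (nm in names(sets)) {
    idx <- match(sets[[nm]], colnames(expr))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    out[[nm]] <- as.numeric(Matrix::rowMeans(expr[, idx, drop = FALSE]))
  }
  values <- do.call(cbind, out)
  if (is.null(values)) {
    values <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
  }
  rownames(values) <- rownames(expr)
  list(values = values, skipped = skipped)
}

#' Truncate ranked gene sets to their top k genes
#'
#' Helper reproducing the "top 30 genes by positive average log-fold
#' change" construction of mean-of-set baselines: each input set is assumed
#' already ranked (best first) and is cut to its first `k` members.
#'
#' @param ranked_sets named list of ranked character vectors.
#' @param k number of genes to keep, default 30.
#' @return Named list of truncated sets, rank order preserved.
#' @export
top_k_sets <- function(ranked_sets, k = 30L) {
  stopifnot(k >= 1L)
  lapply(ranked_sets, function(g) g[seq_len(min(k, length(g)))])
}
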