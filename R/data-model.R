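#' @importFrom methods as is
#' @importFrom stats loess median pgamma predict pnorm quantile rank runif
#'   rnbinom var setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal floor applied to technical variances so near-constant genes cannot
# blow up the standardized distances.
.TECH_VAR_EPS <- 1e-8

#' Construct a validated expression matrix
#'
#' The package-wide convention for expression data is a cells x genes matrix
#' (base `matrix` or any `Matrix` sparse class) of finite, non-negative,
#' log-normalized values, with unique cell identifiers as row names and
#' unique gene identifiers as column names.
#'
#' @param values cells x genes numeric matrix (dense or sparse).
#' @param gene_ids character vector of unique gene identifiers
#'   (`ncol(values)`); defaults to `colnames(values)`.
#' @param cell_ids character vector of unique cell identifiers
#'   (`nrow(values)`); defaults to `rownames(values)`.
#'
#' @return The matrix with dimnames set, after validation.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values)) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("expression matrix requires both gene_ids and cell_ids")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) [", length(gene_ids), "] != ncol(values) [",
         ncol(values), "]")
  }
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) [", length(cell_ids), "] != nrow(values) [",
         nrow(values), "]")
  }
  .check_unique(gene_ids, "gene_ids")
  .check_unique(cell_ids, "cell_ids")
  vals <- if (is(values, "sparseMatrix")) values@x else as.numeric(values)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals)))) {
    stop("expression values must all be finite")
  }
  if (length(vals) && any(vals < 0)) {
    stop("expression values must be non-negative")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

.check_unique <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(what, " contains missing or empty identifiers")
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, ": ",
         paste(head(dups, 10L), collapse = ", "),
         if (length(dups) > 10L) " ..." else "")
  }
  invisible(TRUE)
}

#' Construct a signed weighted gene set
#'
#' One signed set (positive = up-regulated, negative = down-regulated) for a
#' single cytokine: genes plus strictly positive weights, conventionally the
#' absolute log2 fold-change of each gene under that cytokine's stimulation.
#'
#' @param name cytokine identifier.
#' @param sign either `"positive"` or `"negative"`.
#' @param genes character vector of unique gene identifiers (may be empty).
#' @param weights numeric vector of finite, strictly positive weights, same
#'   length as `genes`.
#'
#' @return An object of class `WeightedGeneSet`.
#' @export
weighted_gene_set <- function(name, sign = c("positive", "negative"),
                              genes = character(), weights = numeric()) {
  sign <- match.arg(sign)
  genes <- as.character(genes)
  weights <- as.numeric(weights)
  if (length(genes) != length(weights)) {
    stop("genes and weights must have the same length")
  }
  if (length(genes)) {
    .check_unique(genes, paste0("genes of set ", name, "/", sign))
    if (anyNA(weights) || any(!is.finite(weights)) || any(weights <= 0)) {
      stop("weights of set ", name, "/", sign,
           " must be finite and strictly positive")
    }
  }
  structure(list(name = as.character(name), sign = sign,
                 genes = genes, weights = weights),
            class = "WeightedGeneSet")
}

#' @export
length.WeightedGeneSet <- function(x) length(x$genes)

#' @export
print.WeightedGeneSet <- function(x, ...) {
  cat(sprintf("<WeightedGeneSet> %s (%s): %d genes\n",
              x$name, x$sign, length(x$genes)))
  invisible(x)
}

#' Construct a signature collection
#'
#' A per-cytokine pair of positive/negative [weighted_gene_set()]s with
#' per-gene provenance (log2 fold-change, raw and adjusted p-values). The
#' weight of every stored gene equals the absolute value of its log2
#' fold-change.
#'
#' @param sets named list; each element is `list(positive = , negative = )`
#'   of `WeightedGeneSet`s for one cytokine.
#' @param provenance data frame with columns `cytokine`, `gene`, `log2fc`,
#'   `p_value`, `p_adjusted` (p columns may be `NA`, e.g. after reading a
#'   signature file that does not carry them).
#' @param num_genes_requested the per-cytokine cap on `n_pos + n_neg`.
#'
#' @return An object of class `SignatureCollection`.
#' @export
signature_collection <- function(sets, provenance = NULL,
                                 num_genes_requested = NA_integer_) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list keyed by cytokine")
  }
  if (is.null(provenance)) {
    provenance <- do.call(rbind, c(lapply(names(sets), function(cy) {
      pos <- sets[[cy]]$positive
      neg <- sets[[cy]]$negative
      n <- length(pos$genes) + length(neg$genes)
      data.frame(
        cytokine = rep(cy, n),
        gene = c(pos$genes, neg$genes),
        log2fc = c(pos$weights, -neg$weights),
        p_value = rep(NA_real_, n), p_adjusted = rep(NA_real_, n),
        stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  }
  for (cy in names(sets)) {
    pair <- sets[[cy]]
    if (!is(pair$positive, "WeightedGeneSet") ||
        !is(pair$negative, "WeightedGeneSet")) {
      stop("cytokine ", cy, " must hold a positive and a negative set")
    }
    overlap <- intersect(pair$positive$genes, pair$negative$genes)
    if (length(overlap)) {
      stop("cytokine ", cy, ": gene(s) ",
           paste(head(overlap, 5L), collapse = ", "),
           " appear in both the positive and negative set")
    }
    if (!is.na(num_genes_requested) &&
        length(pair$positive) + length(pair$negative) > num_genes_requested) {
      stop("cytokine ", cy, ": n_pos + n_neg exceeds num_genes_requested")
    }
  }
  structure(list(sets = sets, provenance = provenance,
                 num_genes_requested = as.integer(num_genes_requested)),
            class = "SignatureCollection")
}

#' @export
length.SignatureCollection <- function(x) length(x$sets)

#' @export
names.SignatureCollection <- function(x) names(x$sets)

#' @export
print.SignatureCollection <- function(x, ...) {
  np <- vapply(x$sets, function(p) length(p$positive), integer(1))
  nn <- vapply(x$sets, function(p) length(p$negative), integer(1))
  cat(sprintf(
    "<SignatureCollection> %d cytokines (%d non-empty signed sets)\n",
    length(x$sets), sum(np > 0) + sum(nn > 0)))
  cat(sprintf("  genes per cytokine: median %s (cap %s)\n",
              median(np + nn),
              ifelse(is.na(x$num_genes_requested), "none",
                     x$num_genes_requested)))
  invisible(x)
}

#' Construct a score matrix
#'
#' Cells x cytokines activity scores in `[0, 1]`, with the component that was
#' scored and a report of skipped cytokines (those with zero matching genes
#' in the target data: absent, never silently zero).
#'
#' @param values cells x cytokines numeric matrix, all entries in `[0, 1]`.
#' @param component one of `"combined"`, `"positive_only"`,
#'   `"negative_only"`.
#' @param skipped character vector of cytokines that could not be scored.
#' @param details optional per-cytokine list (matched set sizes, gamma fits).
#'
#' @return An object of class `ScoreMatrix`.
#' @export
score_matrix <- function(values,
                         component = c("combined", "positive_only",
                                       "negative_only"),
                         skipped = character(), details = list()) {
  component <- match.arg(component)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("score matrix requires cell and cytokine identifiers as dimnames")
  }
  if (length(values) &&
      (anyNA(values) || any(values < -1e-12) || any(values > 1 + 1e-12))) {
    stop("scores must lie in [0, 1]")
  }
  values[] <- pmin(pmax(values, 0), 1)
  structure(list(values = values,
                 cell_ids = rownames(values),
                 cytokine_ids = colnames(values) %||% character(0),
                 component = component,
                 skipped = as.character(skipped),
                 details = details),
            class = "ScoreMatrix")
}

#' @export
as.matrix.ScoreMatrix <- function(x, ...) x$values

#' @export
dim.ScoreMatrix <- function(x) dim(x$values)

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("<ScoreMatrix> %d cells x %d cytokines (%s)\n",
              nrow(x$values), ncol(x$values), x$component))
  if (length(x$skipped)) {
    cat("  skipped (no matching genes):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a labeled stimulation dataset
#'
#' @param expr cells x genes expression matrix (see [expression_matrix()]).
#' @param labels per-cell condition label (cytokine name or control label),
#'   length `nrow(expr)`, all non-empty.
#'
#' @return An object of class `LabeledDataset`.
#' @export
labeled_dataset <- function(expr, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(expr)) {
    stop("labels must have one entry per cell")
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("labels must all be non-empty")
  }
  structure(list(expr = expr, labels = labels), class = "LabeledDataset")
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("<LabeledDataset> %d cells x %d genes, %d conditions\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$labels))))
  invisible(x)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
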