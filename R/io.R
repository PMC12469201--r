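#' Read an expression matrix from disk
#'
#' Supports the two interchange formats used throughout the single-cell
#' ecosystem:
#' \describe{
#'   \item{`mtx_dir`}{a 10x-style directory holding `matrix.mtx(.gz)` in
#'     MatrixMarket coordinate format (genes x cells on disk, transposed on
#'     read), a features/genes TSV (gene id in column 1 or 2, auto-detected)
#'     and a barcodes TSV. Gzipped members are read transparently.}
#'   \item{`dense_delim`}{a comma- or tab-delimited table with a header row
#'     of gene ids and cell ids in the first column (cells x genes on disk).}
#' }
#'
#' @param path directory (for `mtx_dir`) or file (for `dense_delim`).
#' @param format `"mtx_dir"` or `"dense_delim"`.
#'
#' @return A validated cells x genes [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "dense_delim")) {
  format <- match.arg(format)
  if (format == "mtx_dir") .read_expression_mtx(path)
  else .read_expression_dense(path)
}

.find_member <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop("no file matching ", paste(stems, collapse = "/"), " under ", dir)
}

.read_id_column <- function(path, what) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(tab) == 0L) stop(what, " file ", path, " is empty")
  # 10x features files carry accession in column 1 and symbol in column 2;
  # prefer the symbol column when it is usable as a unique key.
  col <- 1L
  if (what == "features" && ncol(tab) >= 2L &&
      !anyDuplicated(tab[[2L]]) && all(nzchar(tab[[2L]]))) {
    col <- 2L
  }
  tab[[col]]
}

.read_expression_mtx <- function(path) {
  if (!dir.exists(path)) stop("mtx_dir path is not a directory: ", path)
  mtx <- .find_member(path, "matrix.mtx")
  feat <- .find_member(path, c("features.tsv", "genes.tsv"))
  bc <- .find_member(path, "barcodes.tsv")
  m <- Matrix::readMM(mtx)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) {
    stop("matrix file ", mtx, " holds an empty matrix")
  }
  genes <- .read_id_column(feat, "features")
  cells <- .read_id_column(bc, "barcodes")
  if (nrow(m) != length(genes)) {
    stop("matrix has ", nrow(m), " rows but features file lists ",
         length(genes), " genes")
  }
  if (ncol(m) != length(cells)) {
    stop("matrix has ", ncol(m), " columns but barcodes file lists ",
         length(cells), " cells")
  }
  # on-disk convention is genes x cells; internal is cells x genes
  expression_matrix(as(Matrix::t(m), "CsparseMatrix"),
                    gene_ids = genes, cell_ids = cells)
}

.read_expression_dense <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L || !nzchar(first)) {
    stop("dense expression file ", path, " is empty")
  }
  sep <- if (lengths(gregexpr("\t", first, fixed = TRUE)) >=
             lengths(gregexpr(",", first, fixed = TRUE))) "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("dense expression file ", path, " holds an empty matrix")
  }
  expression_matrix(as.matrix(tab),
                    gene_ids = colnames(tab), cell_ids = rownames(tab))
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: `mtx_dir` writes `matrix.mtx` (genes x
#' cells, the on-disk convention), `features.tsv` and `barcodes.tsv` into
#' `path`; `dense_delim` writes a single tab-delimited table (cells x genes).
#'
#' @param expr cells x genes [expression_matrix()].
#' @param path output directory (`mtx_dir`) or file (`dense_delim`).
#' @param format `"mtx_dir"` or `"dense_delim"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             format = c("mtx_dir", "dense_delim")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(as(Matrix::t(Matrix::Matrix(expr, sparse = TRUE)),
                       "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(expr), file.path(path, "features.tsv"))
    writeLines(rownames(expr), file.path(path, "barcodes.tsv"))
  } else {
    tab <- as.matrix(expr)
    out <- data.frame(cell_id = rownames(tab), tab, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by the natural-log transform
#' `ln(1 + count * scale_factor / total)`, the standard normalization of the
#' single-cell toolchain. Cells with zero total counts are dropped with a
#' warning.
#'
#' @param counts cells x genes non-negative count matrix (dense or sparse)
#'   with dimnames.
#' @param scale_factor positive scale, default `1e4`.
#'
#' @return A cells x genes [expression_matrix()] of log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  vals <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals)))) {
    stop("counts must be finite")
  }
  if (length(vals) && any(vals < 0)) stop("counts must be non-negative")
  totals <- Matrix::rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts dropped")
    counts <- counts[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  if (nrow(counts) == 0L) stop("no cells remain after dropping empty cells")
  if (is(counts, "sparseMatrix")) {
    # triplet form exposes each entry's row index for per-cell scaling
    norm <- as(counts, "TsparseMatrix")
    norm@x <- log1p(norm@x * scale_factor / totals[norm@i + 1L])
    norm <- as(norm, "CsparseMatrix")
  } else {
    norm <- log1p(sweep(as.matrix(counts), 1L, totals, "/") * scale_factor)
  }
  expression_matrix(norm, gene_ids = colnames(counts),
                    cell_ids = rownames(counts))
}

# ---- weighted GMT (wGMT) dialect ------------------------------------------

#' Read a signed weighted gene-set file
#'
#' Parses the wGMT dialect: a `#wgmt1` header line, then one set per line
#' with TAB-separated fields `set-name`, `sign` (`positive`/`negative`), and
#' `gene=weight` tokens. Each cytokine may contribute one positive and one
#' negative line; a gene may not appear on both lines of the same cytokine.
#'
#' @param path path to a wGMT file.
#' @return A [signature_collection()]. Provenance log2 fold-changes are
#'   reconstructed as signed weights; p-values are `NA` (the dialect does not
#'   carry them).
#' @export
read_weighted_sets <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1L]) != "#wgmt1") {
    stop("not a wGMT file (missing '#wgmt1' header): ", path)
  }
  sets <- list()
  for (i in seq_along(lines)[-1L]) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("line ", i, ": expected at least set-name and sign")
    }
    name <- fields[1L]
    sign <- fields[2L]
    if (!sign %in% c("positive", "negative")) {
      stop("line ", i, ": sign must be 'positive' or 'negative', got '",
           sign, "'")
    }
    tokens <- fields[-(1:2)]
    genes <- character(0)
    weights <- numeric(0)
    if (length(tokens)) {
      parts <- strsplit(tokens, "=", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) {
        stop("line ", i, ": malformed gene=weight token '",
             tokens[which(bad)[1L]], "'")
      }
      genes <- vapply(parts, `[`, character(1), 1L)
      weights <- suppressWarnings(
        as.numeric(vapply(parts, `[`, character(1), 2L)))
      if (anyNA(weights)) {
        stop("line ", i, ": non-numeric weight for gene '",
             genes[which(is.na(weights))[1L]], "'")
      }
    }
    if (is.null(sets[[name]])) sets[[name]] <- list()
    if (!is.null(sets[[name]][[sign]])) {
      stop("line ", i, ": duplicate ", sign, " set for cytokine ", name)
    }
    sets[[name]][[sign]] <- tryCatch(
      weighted_gene_set(name, sign, genes, weights),
      error = function(e) stop("line ", i, ": ", conditionMessage(e)))
  }
  if (length(sets) == 0L) stop("wGMT file ", path, " holds no sets")
  sets <- lapply(names(sets), function(cy) {
    pair <- sets[[cy]]
    if (is.null(pair$positive)) pair$positive <- weighted_gene_set(cy, "positive")
    if (is.null(pair$negative)) pair$negative <- weighted_gene_set(cy, "negative")
    overlap <- intersect(pair$positive$genes, pair$negative$genes)
    if (length(overlap)) {
      stop("cytokine ", cy, ": gene(s) ",
           paste(head(overlap, 5L), collapse = ", "),
           " duplicated across the positive and negative set")
    }
    pair[c("positive", "negative")]
  }) |> setNames(names(sets))
  signature_collection(sets)
}

#' Write a signed weighted gene-set file
#'
#' Serializes a [signature_collection()] in the wGMT dialect read by
#' [read_weighted_sets()]. Weights are printed with 17 significant digits so
#' that `read_weighted_sets(write_weighted_sets(x))` reproduces them exactly.
#'
#' @param collection a `SignatureCollection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weighted_sets <- function(collection, path) {
  stopifnot(is(collection, "SignatureCollection"))
  lines <- "#wgmt1"
  for (cy in names(collection$sets)) {
    for (sign in c("positive", "negative")) {
      set <- collection$sets[[cy]][[sign]]
      tokens <- if (length(set)) {
        paste0(set$genes, "=", sprintf("%.17g", set$weights))
      } else character(0)
      lines <- c(lines, paste(c(cy, sign, tokens), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
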