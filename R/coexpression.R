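# Single-cell trypsin co-expression statistics: expressing-cell counts,
# trypsins-per-cell histogram, and the ubiquity vs co-expression
# relationship across genes.

#' Construct a cell-by-gene count container
#'
#' @param counts Non-negative integer matrix (dense or `Matrix` sparse),
#'   cells as rows and genes as columns, with dimnames set.
#' @param trypsin_genes Character vector naming the trypsin gene subset
#'   (must be a subset of the column names).
#' @return An object of class `cell_counts`.
#' @export
cell_counts <- function(counts, trypsin_genes = colnames(counts)) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (!all(trypsin_genes %in% colnames(counts))) {
    stop("trypsin_genes must be a subset of the matrix columns")
  }
  structure(list(counts = counts, trypsin_genes = trypsin_genes),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d cells x %d genes (%d trypsins)\n",
              nrow(x$counts), ncol(x$counts), length(x$trypsin_genes)))
  invisible(x)
}

#' Boolean expression mask
#'
#' A gene counts as expressed in a cell when its read count reaches
#' `min_reads` (the deliberately permissive default of a single read).
#'
#' @param cc A [cell_counts()] object (or a bare matrix).
#' @param min_reads Expression threshold in reads.
#' @return Logical cell-by-gene matrix.
#' @export
expression_mask <- function(cc, min_reads = 1) {
  counts <- if (inherits(cc, "cell_counts")) cc$counts else cc
  m <- counts >= min_reads
  as.matrix(m)
}

#' Trypsin co-expression summary
#'
#' Restricting to the trypsin gene set, computes: the number of cells
#' expressing at least one trypsin; the histogram of trypsins expressed per
#' cell; per gene, its ubiquity (cells expressing it) and its co-expression
#' count (cells where it is expressed together with at least one other
#' trypsin); and the correlation between ubiquity and co-expression across
#' genes (Pearson reported by default, Spearman alongside).
#'
#' @param cc A [cell_counts()] object.
#' @param min_reads Expression threshold in reads.
#' @return An object of class `coexpression_summary`: a list with elements
#'   `n_expressing_cells`, `histogram` (named integer vector over k =
#'   trypsins per cell), `per_gene` (data frame `gene`, `ubiquity`,
#'   `co_cells`), and `correlation` (list with `pearson`, `spearman`, each
#'   holding `estimate` and `p_value`; both `NA` and flagged `undefined`
#'   when no cell expresses a trypsin or the inputs are constant).
#' @examples
#' sim <- sim_cell_matrix(n_genes = 12, seed = 3)
#' cc <- cell_counts(sim$counts, sim$trypsin_genes)
#' s <- coexpression_summary(cc)
#' s$n_expressing_cells
#' head(s$per_gene)
#' @export
coexpression_summary <- function(cc, min_reads = 1) {
  stopifnot(inherits(cc, "cell_counts"))
  if (length(cc$trypsin_genes) == 0L) stop("trypsin gene set is empty")
  m <- expression_mask(cc, min_reads)[, cc$trypsin_genes, drop = FALSE]
  k <- rowSums(m)
  expressing <- k >= 1L
  n_exp <- sum(expressing)
  if (n_exp == 0L) {
    hist <- integer(0)
  } else {
    tab <- table(k[expressing])
    hist <- as.integer(tab)
    names(hist) <- names(tab)
  }
  ubiquity <- colSums(m)
  co_cells <- colSums(m[k >= 2L, , drop = FALSE])
  per_gene <- data.frame(gene = colnames(m),
                         ubiquity = as.integer(ubiquity),
                         co_cells = as.integer(co_cells),
                         row.names = NULL, stringsAsFactors = FALSE)
  correlation <- .ubiquity_correlation(per_gene)
  structure(list(n_expressing_cells = n_exp,
                 histogram = hist,
                 per_gene = per_gene,
                 correlation = correlation,
                 min_reads = min_reads),
            class = "coexpression_summary")
}

.ubiquity_correlation <- function(per_gene) {
  u <- per_gene$ubiquity
  co <- per_gene$co_cells
  undef <- length(u) < 3L || stats::sd(u) == 0 || stats::sd(co) == 0
  if (undef) {
    return(list(undefined = TRUE,
                pearson = list(estimate = NA_real_, p_value = NA_real_),
                spearman = list(estimate = NA_real_, p_value = NA_real_)))
  }
  pe <- stats::cor.test(u, co, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(u, co, method = "spearman",
                                         exact = FALSE))
  list(undefined = FALSE,
       pearson = list(estimate = unname(pe$estimate),
                      p_value = pe$p.value),
       spearman = list(estimate = unname(sp$estimate),
                       p_value = sp$p.value))
}

#' @export
print.coexpression_summary <- function(x, ...) {
  cat("Trypsin co-expression summary (min reads =", x$min_reads, ")\n")
  cat("  cells expressing >= 1 trypsin:", x$n_expressing_cells, "\n")
  if (length(x$histogram)) {
    cat("  trypsins per cell: ",
        paste(sprintf("%s:%d", names(x$histogram), x$histogram),
              collapse = "  "), "\n")
  }
  if (!x$correlation$undefined) {
    cat(sprintf("  ubiquity~co-expression: Pearson r = %.3f, Spearman rho = %.3f\n",
                x$correlation$pearson$estimate,
                x$correlation$spearman$estimate))
  } else {
    cat("  ubiquity~co-expression correlation undefined\n")
  }
  invisible(x)
}

#' Co-expression partners of one trypsin
#'
#' @param cc A [cell_counts()] object.
#' @param gene A gene in the trypsin set.
#' @param min_reads Expression threshold in reads.
#' @return Data frame of partners (`gene`, `shared_cells`) sorted by
#'   descending shared-cell count, ties broken by gene identifier; partners
#'   sharing no cell are omitted.
#' @export
coexpression_partners <- function(cc, gene, min_reads = 1) {
  stopifnot(inherits(cc, "cell_counts"))
  if (!gene %in% cc$trypsin_genes) {
    stop("unknown trypsin gene: ", gene)
  }
  m <- expression_mask(cc, min_reads)[, cc$trypsin_genes, drop = FALSE]
  on <- m[, gene]
  shared <- colSums(m[on, , drop = FALSE])
  shared <- shared[names(shared) != gene]
  shared <- shared[shared > 0]
  ord <- order(-shared, names(shared))
  data.frame(gene = names(shared)[ord],
             shared_cells = as.integer(shared[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a cell-by-gene count matrix
#'
#' Supports a TSV with cell identifiers in the first column and genes as
#' remaining columns, or a MatrixMarket `.mtx` file with sidecar row
#' (cells) and column (genes) label files, one identifier per line.
#'
#' @param path Matrix path (`.tsv`/`.txt` or `.mtx`).
#' @param row_labels,col_labels Label file paths (MatrixMarket only;
#'   default `<path>.rows` / `<path>.cols`).
#' @return Integer matrix (sparse for MatrixMarket input), cells as rows.
#' @export
read_count_matrix <- function(path, row_labels = NULL, col_labels = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    rn <- readLines(row_labels %||% paste0(path, ".rows"))
    cn <- readLines(col_labels %||% paste0(path, ".cols"))
    stopifnot(length(rn) == nrow(m), length(cn) == ncol(m))
    dimnames(m) <- list(rn, cn)
    methods::as(m, "CsparseMatrix")
  } else {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
  }
}

#' Write a cell-by-gene count matrix as MatrixMarket plus label files
#'
#' @param counts Matrix with dimnames (cells x genes).
#' @param path Output `.mtx` path; labels are written to `<path>.rows` and
#'   `<path>.cols`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, path)
  writeLines(rownames(counts), paste0(path, ".rows"))
  writeLines(colnames(counts), paste0(path, ".cols"))
  invisible(path)
}
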