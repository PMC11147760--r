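#' Construct a single-cell count container
#'
#' Bundles a sparse gene x cell count matrix with per-cell metadata and
#' computed QC fields (total counts, genes detected, mitochondrial fraction).
#' Mitochondrial genes are recognised by the `"MT-"` name prefix, following
#' human gene nomenclature.
#'
#' @param counts Nonnegative integer matrix (genes x cells); coerced to
#'   `Matrix::dgCMatrix`. Row names are gene identifiers, column names
#'   cell barcodes.
#' @param cell_meta Data frame with one row per cell; must contain a
#'   `barcode` column plus `patient`, `timepoint`, `replicate`, `population`.
#' @return A `cell_matrix` object: list with `counts` (sparse matrix),
#'   `genes` (character), `cells` (tibble of metadata + QC columns
#'   `total_counts`, `n_genes_detected`, `mito_fraction`).
#' @export
cell_matrix <- function(counts, cell_meta) {
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must carry gene row names and barcode column names")
  if (any(counts < 0)) abort("negative counts", class = "amlprog_negative_count")
  counts <- methods::as(
    methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
                "generalMatrix"),
    "CsparseMatrix")
  if (any(counts@x != floor(counts@x)))
    abort("non-integer counts", class = "amlprog_noninteger_count")
  cell_meta <- as_tibble(cell_meta)
  assert_that("barcode" %in% names(cell_meta),
              "cell_meta must contain a barcode column")
  missing <- setdiff(colnames(counts), cell_meta$barcode)
  if (length(missing))
    abort(paste0("metadata incomplete: no rows for barcodes ",
                 paste(head(missing, 3), collapse = ", ")),
          class = "amlprog_metadata_incomplete")
  unknown <- setdiff(cell_meta$barcode, colnames(counts))
  if (length(unknown))
    abort(paste0("unknown barcode in metadata: ",
                 paste(head(unknown, 3), collapse = ", ")),
          class = "amlprog_unknown_barcode")
  # collapse duplicated gene identifiers by summing their counts
  if (anyDuplicated(rownames(counts))) {
    warn("duplicate gene identifiers collapsed by sum")
    grp <- factor(rownames(counts), levels = unique(rownames(counts)))
    agg <- Matrix::sparse.model.matrix(~ 0 + grp)
    counts2 <- Matrix::t(agg) %*% counts
    rownames(counts2) <- levels(grp)
    counts <- methods::as(counts2, "CsparseMatrix")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ]
  total <- Matrix::colSums(counts)
  mito <- is_mito_gene(rownames(counts))
  mito_counts <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
                 else rep(0, ncol(counts))
  qc <- tibble(
    total_counts = as.numeric(total),
    n_genes_detected = as.integer(Matrix::colSums(counts > 0)),
    mito_fraction = unname(ifelse(total > 0, mito_counts / total, 0))
  )
  structure(list(counts = counts,
                 genes = rownames(counts),
                 cells = dplyr::bind_cols(cell_meta, qc)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", length(x$genes), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  cat("populations:", paste(names(table(x$cells$population)),
                            table(x$cells$population), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a count matrix with cell metadata
#'
#' Supports the 10x-style MatrixMarket triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` in one directory) and a dense CSV dialect with genes as
#' rows, cells as columns, and a header row of barcodes. Metadata must cover
#' every barcode and provide `patient`, `timepoint`, `replicate`,
#' `population` columns.
#'
#' @param path Directory (mtx_triplet) or file (dense_csv).
#' @param format One of `"mtx_triplet"`, `"dense_csv"`.
#' @param metadata_path CSV of per-cell metadata with a `barcode` column.
#' @return A [cell_matrix()].
#' @export
read_counts_matrix <- function(path,
                               format = c("mtx_triplet", "dense_csv"),
                               metadata_path) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("no such path:", path))
  assert_that(file.exists(metadata_path),
              paste("no such metadata file:", metadata_path))
  if (format == "mtx_triplet") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- read.delim(file.path(path, "features.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)
    bcs <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != nrow(feats) || ncol(m) != length(bcs))
      abort("dimension mismatch between matrix and features/barcodes",
            class = "amlprog_dim_mismatch")
    counts <- methods::as(m, "CsparseMatrix")
    rownames(counts) <- feats[[1]]
    colnames(counts) <- bcs
  } else {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    counts <- as.matrix(df)
  }
  if (any(counts < 0)) abort("negative counts", class = "amlprog_negative_count")
  if (any(counts != floor(counts)))
    abort("non-integer counts", class = "amlprog_noninteger_count")
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  cell_matrix(counts, meta)
}

#' Write a cell_matrix as a 10x-style MTX triplet plus metadata CSV
#'
#' @param cm A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = cm$genes, symbol = cm$genes),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(colnames(cm$counts)),
              file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- cm$cells[, setdiff(names(cm$cells),
                             c("total_counts", "n_genes_detected",
                               "mito_fraction"))]
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Filter cells on genes detected and mitochondrial fraction
#'
#' Retains cells with at least `min_genes` genes detected and a mitochondrial
#' read fraction of at most `max_mito`. The numbers removed under each
#' criterion are recorded in the `qc_log` attribute. Defaults mirror the
#' conventional thresholds (200 genes, 20% mitochondrial reads).
#'
#' @param cm A [cell_matrix()].
#' @param min_genes Minimum genes detected per cell.
#' @param max_mito Maximum mitochondrial fraction per cell.
#' @return Filtered [cell_matrix()] with attribute `qc_log`.
#' @export
qc_filter_cells <- function(cm, min_genes = 200, max_mito = 0.20) {
  assert_that(min_genes >= 0 && max_mito >= 0, "thresholds must be nonnegative")
  keep_genes <- cm$cells$n_genes_detected >= min_genes
  keep_mito <- cm$cells$mito_fraction <= max_mito
  keep <- keep_genes & keep_mito
  if (!any(keep)) abort("all cells removed by QC",
                        class = "amlprog_all_cells_removed")
  out <- cell_matrix(cm$counts[, keep, drop = FALSE],
                     cm$cells[keep, setdiff(names(cm$cells),
                                            c("total_counts",
                                              "n_genes_detected",
                                              "mito_fraction"))])
  attr(out, "qc_log") <- tibble(
    criterion = c("min_genes", "max_mito"),
    removed = c(sum(!keep_genes), sum(!keep_mito))
  )
  out
}

#' Log-normalise counts to log1p counts-per-scale
#'
#' `value(g, c) = log(1 + scale * count(g, c) / total(c))`, the standard
#' library-size normalisation for droplet data.
#'
#' @param cm A [cell_matrix()].
#' @param scale Scale factor (default 10,000).
#' @return A `normalized_matrix`: list with dense `values` (genes x cells),
#'   `genes`, `cells` (metadata tibble carried over), and `scale`.
#' @export
normalize_log_cpm <- function(cm, scale = 10000) {
  total <- cm$cells$total_counts
  if (any(total == 0)) abort("zero-total cell: run QC first",
                             class = "amlprog_zero_total")
  vals <- as.matrix(cm$counts)
  vals <- log1p(sweep(vals, 2, scale / total, `*`))
  structure(list(values = vals, genes = cm$genes, cells = cm$cells,
                 scale = scale),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", length(x$genes), " genes x ", ncol(x$values),
      " cells (log1p CP", format(x$scale, scientific = FALSE), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Select highly variable genes
#'
#' Genes are ranked by their variance of normalised expression standardised
#' against a binned-median mean-variance trend: genes are grouped into
#' `n_bins` equal-occupancy bins of mean expression and each gene's variance
#' is divided by the median variance of its bin. Ties break by gene
#' identifier so the selection is deterministic.
#'
#' @param nm A [normalize_log_cpm()] result.
#' @param n_top Number of genes to return.
#' @param n_bins Number of mean-expression bins for the trend.
#' @return Character vector of `n_top` gene identifiers, ranked.
#' @export
select_hvgs <- function(nm, n_top = 2000, n_bins = 20) {
  assert_that(n_top <= length(nm$genes), "n_top exceeds number of genes")
  mu <- rowMeans(nm$values)
  v <- apply(nm$values, 1, var)
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  med <- tapply(v, bin, median)
  med[med == 0 | is.na(med)] <- 1
  std_v <- v / med[as.character(bin)]
  ord <- order(-std_v, nm$genes)
  nm$genes[ord][seq_len(n_top)]
}

# subset helpers ---------------------------------------------------------

#' Subset a normalized matrix by cells and/or genes
#' @param nm A `normalized_matrix`.
#' @param cells Logical or integer index over cells, or NULL.
#' @param genes Character gene ids, or NULL.
#' @return A `normalized_matrix` restricted accordingly.
#' @export
subset_cells <- function(nm, cells = NULL, genes = NULL) {
  out <- nm
  if (!is.null(cells)) {
    out$values <- out$values[, cells, drop = FALSE]
    out$cells <- out$cells[cells, ]
  }
  if (!is.null(genes)) {
    out$values <- out$values[genes, , drop = FALSE]
    out$genes <- genes
  }
  out
}
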