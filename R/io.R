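#' Construct a cells x genes count matrix
#'
#' Light container for single-cell (or spatial spot) expression data:
#' a sparse cells x genes matrix plus a layer tag saying whether the values
#' are raw integer counts or log-normalized expression.
#'
#' @param values Matrix-like, cells in rows and genes in columns. Coerced to
#'   a sparse `dgCMatrix`.
#' @param cell_ids Character vector of unique cell (or spot) identifiers;
#'   defaults to `rownames(values)`.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `colnames(values)`.
#' @param layer Either `"counts"` (non-negative integers) or `"lognorm"`.
#'
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (sparse matrix with dimnames) and `layer`.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values),
                         layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("cell_ids and gene_ids are required (or set dimnames on `values`)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d cell ids and %d gene ids supplied",
      nrow(values), ncol(values), length(cell_ids), length(gene_ids)
    ))
  }
  .check_unique(cell_ids, "cell")
  .check_unique(gene_ids, "gene")
  if (any(values@x < 0)) stop("expression values must be non-negative")
  if (layer == "counts" && any(values@x != round(values@x))) {
    stop("counts layer must be integer-valued")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, layer = layer), class = "count_matrix")
}

.check_unique <- function(ids, what) {
  dup <- anyDuplicated(ids)
  if (dup) {
    stop(sprintf("duplicate %s id: '%s'", what, ids[dup]))
  }
  invisible(TRUE)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$values)

#' Cell and gene identifiers of a count matrix
#' @param x A [count_matrix()].
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d cells x %d genes, layer '%s', %.1f%% nonzero\n",
    nrow(x$values), ncol(x$values), x$layer,
    100 * length(x$values@x) / prod(dim(x$values))
  ))
  invisible(x)
}

#' Read a sparse-triplet (Matrix Market) count matrix
#'
#' Reads the 10x-style trio of files: a Matrix Market coordinate matrix plus
#' one-identifier-per-line gene and barcode files. On-disk orientation
#' (genes x cells, the 10x convention, or cells x genes) is auto-detected by
#' matching the matrix dimensions against the lengths of the two identifier
#' files; the returned matrix is always cells x genes.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene-identifier file (one per line).
#' @param barcodes_path Path to the cell-barcode file (one per line).
#' @param layer Layer tag for the loaded values, default `"counts"`.
#'
#' @return A [count_matrix()].
#' @export
read_counts_triplet <- function(matrix_path, genes_path, barcodes_path,
                                layer = "counts") {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  ng <- length(genes)
  nb <- length(barcodes)
  cells_by_genes <- nrow(m) == nb && ncol(m) == ng
  genes_by_cells <- nrow(m) == ng && ncol(m) == nb
  if (cells_by_genes && genes_by_cells && ng != nb) {
    # impossible; kept for clarity
  }
  if (cells_by_genes && genes_by_cells) {
    if (nrow(m) == ncol(m) && ng == nb) {
      stop(sprintf(
        "square %d x %d matrix with equal id-file lengths: orientation is ambiguous",
        nrow(m), ncol(m)
      ))
    }
  }
  if (genes_by_cells && !cells_by_genes) {
    m <- Matrix::t(m)
  } else if (!cells_by_genes) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but genes file has %d entries and barcodes file has %d",
      nrow(m), ncol(m), ng, nb
    ))
  }
  count_matrix(m, cell_ids = barcodes, gene_ids = genes, layer = layer)
}

#' Write a count matrix as a sparse triplet trio
#'
#' Inverse of [read_counts_triplet()]: writes `matrix.mtx`, `genes.txt` and
#' `barcodes.txt` (cells x genes orientation) into `dir`.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_counts_triplet <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.txt", "barcodes.txt"))
  Matrix::writeMM(x$values, paths[1])
  writeLines(gene_ids(x), paths[2])
  writeLines(cell_ids(x), paths[3])
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Lines with fewer than three fields are skipped with a warning; duplicate
#' members within a set are dropped (first occurrence kept) with a warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with one row per gene set: `set_name`, `description`,
#'   and a list-column `genes` of unique member identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    warning(sprintf("skipping %d GMT line(s) with fewer than 3 fields", sum(n_fields < 3)))
    fields <- fields[n_fields >= 3]
  }
  if (length(fields) == 0) stop(sprintf("no valid gene-set lines in %s", path))
  sets <- purrr::map(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate members dropped", f[1]))
      genes <- genes[!duplicated(genes)]
    }
    tibble::tibble(set_name = f[1], description = f[2], genes = list(genes))
  })
  dplyr::bind_rows(sets)
}

#' Write gene sets to a GMT file
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    collection[c("set_name", "description", "genes")],
    function(set_name, description, genes) {
      paste(c(set_name, description, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read/write tabular reports
#'
#' All tabular outputs (QC reports, score panels, DE tables, module tables,
#' selection reports) are plain UTF-8 TSV with a header row and `.` decimal
#' separator; `read_report()` round-trips anything `write_report()` wrote.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_report()` returns `path` invisibly; `read_report()` a tibble.
#' @export
write_report <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Match a gene set against the genes of a matrix
#'
#' Exact, case-sensitive matching; reports the matched fraction so that
#' identifier-namespace or symbol-case problems surface instead of silently
#' shrinking the signature.
#'
#' @param genes Character vector of gene-set members.
#' @param universe Character vector of matrix gene identifiers.
#' @param warn_below Warn when the matched fraction falls below this value.
#' @return Character vector of matched genes, with attribute
#'   `matched_fraction`.
#' @export
match_gene_set <- function(genes, universe, warn_below = 0.5) {
  matched <- genes[genes %in% universe]
  frac <- if (length(genes)) length(matched) / length(genes) else 0
  if (frac < warn_below) {
    warning(sprintf(
      "only %.1f%% of gene-set members matched the matrix (check identifier case/namespace)",
      100 * frac
    ))
  }
  attr(matched, "matched_fraction") <- frac
  matched
}
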