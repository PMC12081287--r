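#' Joint single-nucleus expression / antibody-capture dataset
#'
#' Container holding a gene-count matrix, an antibody-capture count matrix
#' and per-nucleus metadata for the same set of nuclei. Nuclei are rows in
#' every in-memory matrix; gene counts are stored sparse
#' (`Matrix::dgCMatrix`), the antibody panel is small and kept dense.
#'
#' @param X nuclei-by-genes non-negative integer count matrix (sparse or
#'   dense; coerced to `dgCMatrix`). Row names are nucleus barcodes, column
#'   names gene symbols.
#' @param A nuclei-by-antibodies non-negative integer count matrix with the
#'   same row names as `X`; column names are antibody names and must contain
#'   `reference` exactly once.
#' @param meta data.frame of per-nucleus metadata, one row per barcode
#'   (row names = barcodes, same order as `X`). Required columns:
#'   `donor_id`, `disease_group`, `batch`, `hashtag_counts`. A
#'   `total_counts` column is (re)computed as the per-nucleus gene-count
#'   sum. Optional columns such as `cell_type`, `cluster`, `age` are kept.
#' @param reference name of the reference antibody (default `"H3"`), the
#'   per-nucleus denominator controlling for antibody capture efficiency.
#'
#' @return An object of class `nucleus_dataset`: a list with elements `X`,
#'   `A`, `meta`, `reference`.
#' @examples
#' sim <- simulate_incite(sim_config(n_donors_per_group = 1,
#'                                   groups = c("young", "AD"),
#'                                   nuclei_per_donor_mean = 50,
#'                                   n_genes = 40, seed = 1))
#' ds <- sim$dataset
#' ds
#' dim(ds$X)
#' @export
nucleus_dataset <- function(X, A, meta, reference = "H3") {
  X <- methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  A <- as.matrix(A)
  if (is.null(rownames(X)) || is.null(rownames(A)) || is.null(rownames(meta)))
    stop("X, A and meta must all carry barcode row names")
  if (!identical(rownames(X), rownames(A)) ||
      !identical(rownames(X), rownames(meta)))
    stop("barcode sets of X, A and meta must be identical and in the same order")
  if (anyDuplicated(rownames(X)))
    stop("barcodes must be unique")
  check_counts(X@x, "X")
  check_counts(A, "A")
  n_ref <- sum(colnames(A) == reference)
  if (n_ref == 0L)
    stop("reference antibody '", reference, "' absent from the antibody panel")
  if (n_ref > 1L)
    stop("reference antibody '", reference, "' appears more than once in the panel")
  req <- c("donor_id", "disease_group", "batch", "hashtag_counts")
  miss <- setdiff(req, colnames(meta))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  meta$total_counts <- Matrix::rowSums(X)
  structure(list(X = X, A = A, meta = meta, reference = reference),
            class = "nucleus_dataset")
}

check_counts <- function(v, what) {
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0))
    stop(what, " must contain finite non-negative counts")
  if (any(abs(v - round(v)) > 1e-8))
    stop(what, " must contain integral counts")
  invisible(TRUE)
}

#' @export
print.nucleus_dataset <- function(x, ...) {
  cat(sprintf("<nucleus_dataset> %d nuclei x %d genes; %d antibodies (reference: %s)\n",
              nrow(x$X), ncol(x$X), ncol(x$A), x$reference))
  cat("  donors:", length(unique(x$meta$donor_id)),
      " groups:", paste(sort(unique(as.character(x$meta$disease_group))),
                        collapse = "/"),
      " batches:", length(unique(x$meta$batch)), "\n")
  invisible(x)
}

#' @export
dim.nucleus_dataset <- function(x) dim(x$X)

#' Subset a dataset by nuclei
#'
#' @param x a [nucleus_dataset()]
#' @param i nucleus index (logical, integer or barcode character vector)
#' @param ... ignored
#' @return a `nucleus_dataset` restricted to the selected nuclei
#' @export
`[.nucleus_dataset` <- function(x, i, ...) {
  nucleus_dataset(x$X[i, , drop = FALSE], x$A[i, , drop = FALSE],
                  x$meta[i, , drop = FALSE], reference = x$reference)
}

#' Read a 10x-style MatrixMarket bundle
#'
#' Reads `matrix.mtx(.gz)`, `barcodes.tsv(.gz)` and `features.tsv(.gz)` from
#' a directory. Files follow the 10x convention (features as matrix rows);
#' the returned matrix is transposed to the in-memory convention, nuclei as
#' rows.
#'
#' @param dir_path directory containing the three files
#' @return list with `counts` (nuclei-by-features sparse matrix with
#'   dimnames), `barcodes`, `features`
#' @export
read_matrix_bundle <- function(dir_path) {
  find1 <- function(base) {
    for (f in file.path(dir_path, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing file in bundle '", dir_path, "': ", base, "(.gz)")
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  barcodes <- readLines(find1("barcodes.tsv"))
  feat_raw <- utils::read.table(find1("features.tsv"), sep = "\t",
                                header = FALSE, quote = "",
                                colClasses = "character")
  features <- feat_raw[[1L]]
  if (nrow(m) != length(features))
    stop("format error: matrix declares ", nrow(m), " feature rows but ",
         "features.tsv has ", length(features))
  if (ncol(m) != length(barcodes))
    stop("format error: matrix declares ", ncol(m), " barcode columns but ",
         "barcodes.tsv has ", length(barcodes))
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(barcodes, features)
  list(counts = m, barcodes = barcodes, features = features)
}

#' Write a 10x-style MatrixMarket bundle
#'
#' Inverse of [read_matrix_bundle()]: writes `matrix.mtx` (features as
#' rows), `barcodes.tsv` and `features.tsv` into `dir_path` (created if
#' needed).
#'
#' @param counts nuclei-by-features non-negative count matrix
#' @param barcodes,features axis labels; must be unique and match `counts`
#'   dimensions (defaults: dimnames of `counts`)
#' @param dir_path output directory
#' @return `dir_path`, invisibly
#' @export
write_matrix_bundle <- function(counts, dir_path,
                                barcodes = rownames(counts),
                                features = colnames(counts)) {
  if (length(barcodes) != nrow(counts) || length(features) != ncol(counts))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(barcodes)) stop("duplicate barcode labels")
  if (anyDuplicated(features)) stop("duplicate feature labels")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir_path)
  m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(dir_path, "matrix.mtx"))
  writeLines(barcodes, file.path(dir_path, "barcodes.tsv"))
  writeLines(features, file.path(dir_path, "features.tsv"))
  invisible(dir_path)
}

#' Assemble a dataset from expression, antibody and metadata sources
#'
#' Joins an expression bundle, an antibody-capture bundle and a metadata
#' table on their common barcodes (exact string match, no suffix stripping)
#' and validates the result. The intersection size is reported via
#' `message()`.
#'
#' @param expr bundle directory path or the list returned by
#'   [read_matrix_bundle()] for the gene-expression modality
#' @param adt same, for the antibody-capture modality
#' @param meta path to a metadata CSV (first column or a `barcode` column
#'   holds barcodes) or a data.frame with barcode row names
#' @param reference reference antibody name, default `"H3"`
#' @return a [nucleus_dataset()]
#' @export
assemble_dataset <- function(expr, adt, meta, reference = "H3") {
  if (is.character(expr)) expr <- read_matrix_bundle(expr)
  if (is.character(adt)) adt <- read_matrix_bundle(adt)
  if (is.character(meta)) {
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
    bc_col <- if ("barcode" %in% colnames(meta)) "barcode" else colnames(meta)[1L]
    rownames(meta) <- meta[[bc_col]]
    meta[[bc_col]] <- NULL
  }
  req <- c("donor_id", "disease_group", "batch", "hashtag_counts")
  miss <- setdiff(req, colnames(meta))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  common <- intersect(intersect(expr$barcodes, rownames(adt$counts)),
                      rownames(meta))
  if (length(common) == 0L)
    stop("no barcodes shared by expression, antibody and metadata inputs")
  message("assemble_dataset: ", length(common), " nuclei in barcode intersection (",
          length(expr$barcodes), " expr, ", nrow(adt$counts), " adt, ",
          nrow(meta), " meta)")
  nucleus_dataset(expr$counts[common, , drop = FALSE],
                  as.matrix(adt$counts[common, , drop = FALSE]),
                  meta[common, , drop = FALSE],
                  reference = reference)
}

#' Read gene sets from a tab-separated file
#'
#' One set per line: set name, then member gene symbols, tab-separated
#' (GMT-like, without a description column).
#'
#' @param path file path
#' @return named list of unique character vectors
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) unique(f[-1L]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (any(!lengths(sets))) stop("gene set with no members in ", path)
  sets
}
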