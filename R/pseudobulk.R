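#' Donor-by-cell-type pseudobulk aggregation
#'
#' Sums raw gene counts over all nuclei of each donor-by-cell-type unit
#' and drops units with fewer than `min_cells` nuclei or fewer than
#' `min_counts` total counts. Count mass is conserved: the unit sums
#' (kept plus dropped) equal the total counts of their member nuclei.
#' The retained table is ready for downstream donor-level differential
#' testing (e.g., DESeq2) together with the unit metadata sheet.
#'
#' @param ds a [nucleus_dataset()] whose metadata has a `cell_type` column
#' @param min_cells minimum nuclei per unit
#' @param min_counts minimum summed counts per unit
#' @return list with `counts` (kept units-by-genes matrix), `units`
#'   (data.frame: unit, donor_id, cell_type, n_cells, total_counts, kept -
#'   covering kept and dropped units), and `dropped` (unit names)
#' @export
aggregate_pseudobulk <- function(ds, min_cells = 10L, min_counts = 800L) {
  if (!"cell_type" %in% colnames(ds$meta))
    stop("metadata must contain a cell_type column")
  unit <- paste(ds$meta$donor_id, ds$meta$cell_type, sep = "|")
  fac <- factor(unit)
  agg <- rowsum_sparse(ds$X, fac)
  n_cells <- as.integer(table(fac))
  totals <- rowSums(agg)
  kept <- n_cells >= min_cells & totals >= min_counts
  if (!any(kept))
    stop("no donor/cell-type unit passes the pseudobulk filters")
  parts <- do.call(rbind, strsplit(levels(fac), "|", fixed = TRUE))
  units <- data.frame(unit = levels(fac), donor_id = parts[, 1],
                      cell_type = parts[, 2], n_cells = n_cells,
                      total_counts = as.numeric(totals), kept = kept,
                      row.names = NULL)
  list(counts = agg[kept, , drop = FALSE], units = units,
       dropped = levels(fac)[!kept])
}

# group-wise row sums of a sparse matrix, dense result (units x genes)
rowsum_sparse <- function(X, fac) {
  ind <- Matrix::sparseMatrix(i = seq_along(fac), j = as.integer(fac),
                              x = 1, dims = c(length(fac), nlevels(fac)))
  out <- as.matrix(Matrix::t(ind) %*% X)
  rownames(out) <- levels(fac)
  out
}

#' Donor-profile correlation matrix with hierarchical clustering
#'
#' For one cell type: log-normalized expression of eligible donors'
#' nuclei (at least `min_nuclei` nuclei each) is reduced by PCA to
#' `n_pcs` components fit on nuclei, optionally centered per batch in PC
#' space (a simple stand-in for full batch integration), averaged per
#' donor, and compared by pairwise Pearson correlation; donors are then
#' grouped by average-linkage hierarchical clustering on distance
#' `1 - r`.
#'
#' @param ds a [nucleus_dataset()] with `cell_type` metadata
#' @param cell_type cell type to profile
#' @param n_pcs number of principal components
#' @param min_nuclei minimum nuclei per eligible donor
#' @param batch_centering subtract per-batch PC means before averaging
#' @return object of class `donor_correlation`: `donors`, `correlation`
#'   (symmetric matrix, unit diagonal), `linkage` (hclust), `order`
#'   (dendrogram leaf order)
#' @export
donor_correlation_matrix <- function(ds, cell_type, n_pcs = 50L,
                                     min_nuclei = 10L,
                                     batch_centering = FALSE) {
  i <- which(ds$meta$cell_type == cell_type)
  if (!length(i)) stop("no nuclei of cell type '", cell_type, "'")
  donors <- ds$meta$donor_id[i]
  sizes <- table(donors)
  eligible <- names(sizes)[sizes >= min_nuclei]
  if (length(eligible) < 3)
    stop("fewer than 3 donors with at least ", min_nuclei,
         " nuclei of cell type '", cell_type, "'")
  i <- i[donors %in% eligible]
  donors <- ds$meta$donor_id[i]
  norm_X <- normalize_expression(ds$X[i, , drop = FALSE])
  M <- as.matrix(norm_X)
  sds <- apply(M, 2, stats::sd)
  M <- scale(M[, sds > 0, drop = FALSE])
  n_pcs <- min(n_pcs, nrow(M) - 1L, ncol(M))
  pcs <- stats::prcomp(M, center = FALSE, rank. = n_pcs)$x
  if (batch_centering) {
    batch <- ds$meta$batch[i]
    for (b in unique(batch)) {
      j <- batch == b
      pcs[j, ] <- sweep(pcs[j, , drop = FALSE], 2,
                        colMeans(pcs[j, , drop = FALSE]))
    }
  }
  prof <- rowsum(pcs, donors) / as.vector(table(donors)[sort(unique(donors))])
  r <- stats::cor(t(prof))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(donors = rownames(prof), correlation = r, linkage = hc,
                 order = hc$order),
            class = "donor_correlation")
}

#' @export
print.donor_correlation <- function(x, ...) {
  cat(sprintf("<donor_correlation> %d donors; mean off-diagonal r = %.3f\n",
              length(x$donors),
              mean(x$correlation[upper.tri(x$correlation)])))
  invisible(x)
}

#' Per-donor cluster composition table
#'
#' Proportion of each donor's nuclei falling into each cluster; rows sum
#' to 1. Donors with no nuclei are absent. Feeds [group_anova_tukey()]
#' and [correlate_age_proportions()].
#'
#' @param ds a [nucleus_dataset()], or a data.frame with `donor_id`
#' @param cluster_labels per-nucleus cluster labels (default: the
#'   metadata `cluster` column)
#' @return donors-by-clusters proportion matrix
#' @export
cluster_proportions <- function(ds, cluster_labels = NULL) {
  meta <- if (inherits(ds, "nucleus_dataset")) ds$meta else ds
  if (is.null(cluster_labels)) cluster_labels <- meta$cluster
  if (is.null(cluster_labels)) stop("no cluster labels available")
  if (anyNA(cluster_labels)) stop("every nucleus needs a cluster label")
  tab <- table(meta$donor_id, cluster_labels)
  prop <- tab / rowSums(tab)
  out <- matrix(prop, nrow(prop), ncol(prop),
                dimnames = dimnames(prop))
  out[rowSums(tab) > 0, , drop = FALSE]
}
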