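#' Quality-control thresholds for nuclei and genes
#'
#' Defaults follow standard single-nucleus practice for postmortem brain
#' inCITE-seq data: nuclei must express at least 50 genes, carry at most 5
#' percent mitochondrial counts, at most 4,000 nuclear-pore hashtag counts
#' and at most 3,000 TDP-43 antibody counts (a guard against staining
#' artifacts, applied only when the antibody modality is present); genes
#' must be detected in at least 5 nuclei.
#'
#' @param min_genes_per_nucleus minimum genes detected per nucleus
#' @param min_cells_per_gene minimum nuclei a gene must be detected in
#' @param max_mito_fraction maximum mitochondrial count fraction
#' @param max_hashtag_counts maximum hashtag counts
#' @param max_tdp43_ab_counts maximum TDP-43 antibody counts
#' @param tdp43_antibody antibody column name the TDP-43 bound applies to
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_genes_per_nucleus = 50L,
                          min_cells_per_gene = 5L,
                          max_mito_fraction = 0.05,
                          max_hashtag_counts = 4000L,
                          max_tdp43_ab_counts = 3000L,
                          tdp43_antibody = "TDP-43",
                          mito_prefix = "MT-") {
  stopifnot(min_genes_per_nucleus > 0, min_cells_per_gene > 0,
            max_mito_fraction > 0, max_hashtag_counts > 0,
            max_tdp43_ab_counts > 0)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Filter nuclei and genes by quality-control rules
#'
#' Applies the nucleus-level rules (genes detected, mitochondrial fraction,
#' hashtag counts, TDP-43 antibody counts) and the gene detection rule,
#' iterating the two to a fixed point so that a second application removes
#' nothing. The report tallies, for each rule, how many nuclei (or genes)
#' failed it at the moment it was applied.
#'
#' @param ds a [nucleus_dataset()]
#' @param thr a [qc_thresholds()]
#' @return list with `dataset` (filtered) and `report` (data.frame with
#'   columns rule, n_removed)
#' @export
qc_filter <- function(ds, thr = qc_thresholds()) {
  rules <- c("min_genes_per_nucleus", "max_mito_fraction",
             "max_hashtag_counts", "max_tdp43_ab_counts",
             "min_cells_per_gene")
  tally <- stats::setNames(numeric(length(rules)), rules)
  has_tdp <- thr$tdp43_antibody %in% colnames(ds$A)
  repeat {
    X <- ds$X
    genes_detected <- Matrix::rowSums(X > 0)
    total <- Matrix::rowSums(X)
    mito <- startsWith(colnames(X), thr$mito_prefix)
    mito_frac <- if (any(mito))
      Matrix::rowSums(X[, mito, drop = FALSE]) / pmax(total, 1) else
      numeric(nrow(X))
    keep <- rep(TRUE, nrow(X))
    fail <- genes_detected < thr$min_genes_per_nucleus
    tally["min_genes_per_nucleus"] <- tally["min_genes_per_nucleus"] + sum(fail & keep)
    keep <- keep & !fail
    fail <- mito_frac > thr$max_mito_fraction
    tally["max_mito_fraction"] <- tally["max_mito_fraction"] + sum(fail & keep)
    keep <- keep & !fail
    fail <- ds$meta$hashtag_counts > thr$max_hashtag_counts
    tally["max_hashtag_counts"] <- tally["max_hashtag_counts"] + sum(fail & keep)
    keep <- keep & !fail
    if (has_tdp) {
      fail <- ds$A[, thr$tdp43_antibody] > thr$max_tdp43_ab_counts
      tally["max_tdp43_ab_counts"] <- tally["max_tdp43_ab_counts"] + sum(fail & keep)
      keep <- keep & !fail
    }
    if (!any(keep))
      stop("qc_filter removed all nuclei; removals per rule: ",
           paste(names(tally), tally, sep = "=", collapse = ", "))
    gene_keep <- Matrix::colSums(ds$X[keep, , drop = FALSE] > 0) >=
      thr$min_cells_per_gene
    tally["min_cells_per_gene"] <- tally["min_cells_per_gene"] + sum(!gene_keep)
    changed <- any(!keep) || any(!gene_keep)
    ds <- nucleus_dataset(ds$X[keep, gene_keep, drop = FALSE],
                          ds$A[keep, , drop = FALSE],
                          ds$meta[keep, , drop = FALSE],
                          reference = ds$reference)
    if (!changed) break
  }
  list(dataset = ds,
       report = data.frame(rule = rules, n_removed = as.numeric(tally)))
}

#' Depth-normalize and log-transform gene counts
#'
#' Scales every nucleus to `target_sum` total counts and applies
#' `ln(x + 1)`. Zeros map to zero and the zero pattern is preserved; a
#' nucleus's normalized vector is invariant to scaling its depth.
#'
#' @param X nuclei-by-genes count matrix (sparse)
#' @param target_sum per-nucleus target total (counts per 10k by default)
#' @return sparse matrix of log-normalized values
#' @export
normalize_expression <- function(X, target_sum = 1e4) {
  X <- methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  tot <- Matrix::rowSums(X)
  if (any(tot <= 0))
    stop("nucleus with zero total counts; run qc_filter first")
  Xn <- Matrix::Diagonal(x = target_sum / tot) %*% X
  Xn <- methods::as(Xn, "CsparseMatrix")
  Xn@x <- log1p(Xn@x)
  dimnames(Xn) <- dimnames(X)
  Xn
}

#' Highly-variable-gene selection parameters
#'
#' Bounds on the (back-transformed) per-gene mean and on the mean-binned
#' normalized dispersion of log-normalized expression.
#'
#' @param min_mean,max_mean open interval the per-gene mean must fall in
#' @param min_disp minimum binned dispersion z-score
#' @param n_bins number of mean bins for dispersion normalization
#' @return list of class `hvg_params`
#' @export
hvg_params <- function(min_mean = 0.0015, max_mean = 0.18, min_disp = 0.30,
                       n_bins = 20L) {
  stopifnot(min_mean < max_mean)
  structure(as.list(environment()), class = "hvg_params")
}

#' Select highly variable genes
#'
#' Mean/dispersion selection on log-normalized data in the style of the
#' classic Seurat recipe: values are back-transformed with `expm1`, the
#' per-gene dispersion is variance over mean, log dispersions are z-scored
#' within 20 equal-width mean bins, and genes are kept when the mean lies
#' strictly inside `(min_mean, max_mean)` and the normalized dispersion
#' exceeds `min_disp`. The result is independent of gene ordering.
#'
#' @param norm_X nuclei-by-genes log-normalized matrix
#' @param params an [hvg_params()]
#' @return character vector of selected gene names, with a `stats`
#'   attribute (per-gene mean, dispersion, normalized dispersion)
#' @export
select_variable_genes <- function(norm_X, params = hvg_params()) {
  E <- expm1(as.matrix(norm_X))
  mu <- colMeans(E)
  v <- apply(E, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  disp[disp == 0] <- NA_real_
  ldisp <- log(disp)
  bins <- cut(mu, breaks = params$n_bins)
  bm <- stats::ave(ldisp, bins, FUN = function(z) mean(z, na.rm = TRUE))
  bs <- stats::ave(ldisp, bins, FUN = function(z) stats::sd(z, na.rm = TRUE))
  dn <- ifelse(is.na(bs) | bs == 0, 0, (ldisp - bm) / bs)
  keep <- !is.na(disp) & mu > params$min_mean & mu < params$max_mean &
    dn > params$min_disp
  keep[is.na(keep)] <- FALSE
  if (sum(keep) < 2L)
    stop("fewer than 2 genes pass the variable-gene criteria")
  structure(colnames(norm_X)[keep],
            stats = data.frame(gene = colnames(norm_X), mean = mu,
                               dispersion = disp, dispersion_norm = dn,
                               row.names = NULL))
}

#' PCA embedding, kNN graph and Leiden clustering
#'
#' Scales the (optionally variable-gene-restricted) matrix, runs PCA to
#' `n_pcs` components (clamped with a warning when it exceeds the data
#' rank), optionally centers principal components per batch as a simple
#' stand-in for full batch integration, builds a k-nearest-neighbor graph
#' with Jaccard shared-neighbor edge weights and clusters it with the
#' Leiden algorithm. The first two principal components serve as the 2-D
#' embedding used by density analyses.
#'
#' @param norm_X nuclei-by-genes log-normalized matrix
#' @param hvg optional character vector of genes to use
#' @param n_pcs number of principal components
#' @param k neighbors per nucleus
#' @param resolution Leiden resolution parameter
#' @param batch optional per-nucleus batch labels; when given, per-batch PC
#'   means are subtracted
#' @param seed RNG seed for the Leiden refinement
#' @return list with `embedding` (n x 2), `pcs`, `clusters` (factor) and
#'   `graph` (igraph object)
#' @export
embed_and_cluster <- function(norm_X, hvg = NULL, n_pcs = 40L, k = 10L,
                              resolution = 0.8, batch = NULL, seed = 0L) {
  M <- as.matrix(norm_X)
  if (!is.null(hvg)) M <- M[, hvg, drop = FALSE]
  n <- nrow(M)
  if (k >= n) stop("k (", k, ") must be smaller than the number of nuclei (", n, ")")
  sds <- apply(M, 2, stats::sd)
  M <- scale(M[, sds > 0, drop = FALSE])
  max_rank <- min(n - 1L, ncol(M))
  if (n_pcs > max_rank) {
    warning("n_pcs clamped from ", n_pcs, " to data rank ", max_rank)
    n_pcs <- max_rank
  }
  pcs <- stats::prcomp(M, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  if (!is.null(batch)) {
    for (b in unique(batch)) {
      i <- batch == b
      pcs[i, ] <- sweep(pcs[i, , drop = FALSE], 2,
                        colMeans(pcs[i, , drop = FALSE]))
    }
  }
  nn <- knn_indices(pcs, k)
  g <- knn_jaccard_graph(nn)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = 5)
  clusters <- factor(igraph::membership(cl))
  names(clusters) <- rownames(norm_X)
  emb <- pcs[, 1:2, drop = FALSE]
  rownames(emb) <- rownames(norm_X)
  list(embedding = emb, pcs = pcs, clusters = clusters, graph = g)
}

# k nearest neighbors by full pairwise distance (adequate at desk scale;
# memory is O(n^2))
knn_indices <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# undirected graph with Jaccard shared-neighbor weights over the union of
# directed kNN edges (Seurat-style SNN)
knn_jaccard_graph <- function(nn) {
  n <- nrow(nn)
  k <- ncol(nn)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  key <- ifelse(from < to, paste0(from, "_", to), paste0(to, "_", from))
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  w <- vapply(seq_along(from), function(e) {
    a <- sets[[from[e]]]; b <- sets[[to[e]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}
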