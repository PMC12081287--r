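#' Residualize gene expression on nuisance covariates (step 1)
#'
#' Per-gene ordinary least squares of log-normalized expression on the
#' nuisance covariates `gene ~ log_ncounts + log_hashtag_counts + batch`
#' (batch as a categorical fixed effect with intercept), returning the
#' residual matrix that step 2 relates to nuclear protein levels. Genes
#' detected in fewer than `min_nuclei` nuclei are skipped. Collinear
#' design columns are dropped with a warning.
#'
#' @param norm_X nuclei-by-genes log-normalized matrix (zero pattern of the
#'   raw counts preserved, so detection can be read off it)
#' @param meta per-nucleus metadata with `total_counts`, `hashtag_counts`
#'   and `batch`
#' @param covariates subset of
#'   `c("log_ncounts", "log_hashtag_counts", "batch")`; empty for an
#'   intercept-only fit (residuals are then mean-centered expression)
#' @param min_nuclei minimum nuclei a gene must be detected in
#' @return nuclei-by-genes residual matrix (dense) with attributes
#'   `design` (the model matrix actually used), `n_detected` (per kept
#'   gene)
#' @export
residualize_expression <- function(norm_X, meta,
                                   covariates = c("log_ncounts",
                                                  "log_hashtag_counts",
                                                  "batch"),
                                   min_nuclei = 25L) {
  bad <- setdiff(covariates, c("log_ncounts", "log_hashtag_counts", "batch"))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  n <- nrow(norm_X)
  stopifnot(nrow(meta) == n)
  detected <- Matrix::colSums(norm_X > 0)
  keep <- detected >= min_nuclei
  if (!any(keep)) stop("no gene detected in at least ", min_nuclei, " nuclei")
  Y <- as.matrix(norm_X[, keep, drop = FALSE])
  df <- data.frame(row.names = rownames(meta))
  if ("log_ncounts" %in% covariates) {
    if (any(meta$total_counts <= 0)) stop("total_counts must be positive")
    df$log_ncounts <- log(meta$total_counts)
  }
  if ("log_hashtag_counts" %in% covariates)
    df$log_hashtag_counts <- log1p(meta$hashtag_counts)
  if ("batch" %in% covariates) {
    b <- factor(meta$batch)
    if (nlevels(b) < 2L)
      warning("dropping collinear design column(s): batch (single level)")
    else df$batch <- b
  }
  D <- if (ncol(df) == 0L) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~ ., data = df)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    drop_cols <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    warning("dropping collinear design column(s): ",
            paste(drop_cols, collapse = ", "))
    D <- D[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    qd <- qr(D)
  }
  res <- qr.resid(qd, Y)
  dimnames(res) <- list(rownames(norm_X), colnames(norm_X)[keep])
  attr(res, "design") <- D
  attr(res, "n_detected") <- detected[keep]
  res
}

#' Fit the protein-transcript association model (step 2)
#'
#' Per-gene linear regression of step-1 expression residuals on selected
#' nCLR protein columns, jointly over the panel by default, with two-sided
#' t tests per coefficient and Benjamini-Hochberg adjustment across all
#' gene-by-protein tests in one family. When `residualize_protein = TRUE`
#' (default) the protein columns are first residualized on the step-1
#' covariate design, so by the Frisch-Waugh-Lovell theorem the
#' coefficients (and, with the matching degrees of freedom, the t
#' statistics) equal those of the single joint regression of expression on
#' covariates plus proteins. `residualize_protein = FALSE` reproduces the
#' literal two-step procedure on raw nCLR columns.
#'
#' @param residuals nuclei-by-genes residual matrix from
#'   [residualize_expression()]
#' @param nclr nuclei-by-antibodies nCLR matrix from [clr_transform()],
#'   aligned on nuclei
#' @param proteins antibody columns to model (default: every nCLR column;
#'   exclude the reference, whose nCLR is constant)
#' @param mode `"joint"` (all proteins in one regression) or `"single"`
#'   (one regression per protein)
#' @param residualize_protein see above
#' @param fdr significance level on BH-adjusted q values
#' @return object of class `protein_assoc`; its `table` element is a
#'   data.frame with columns gene, protein, coefficient, t_stat, p_value,
#'   q_value, n_nuclei_used
#' @seealso [protein_assoc()] for the full two-step model from a dataset
#' @export
fit_protein_associations <- function(residuals, nclr,
                                     proteins = colnames(nclr),
                                     mode = c("joint", "single"),
                                     residualize_protein = TRUE,
                                     fdr = 0.05) {
  mode <- match.arg(mode)
  n <- nrow(residuals)
  if (nrow(nclr) != n)
    stop("residuals and nclr must be aligned on the same nuclei")
  P <- as.matrix(nclr[, proteins, drop = FALSE])
  design <- attr(residuals, "design")
  df_cov <- if (!is.null(design)) qr(design)$rank - 1L else 0L
  if (residualize_protein && !is.null(design))
    P <- qr.resid(qr(design), P)
  sds <- apply(P, 2, stats::sd)
  if (any(sds == 0))
    stop("constant protein column(s): ",
         paste(proteins[sds == 0], collapse = ", "))
  Y <- as.matrix(residuals)
  fit_block <- function(cols) {
    Z <- cbind(`(Intercept)` = 1, P[, cols, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) stop("collinear protein columns")
    B <- qr.coef(qz, Y)
    R <- qr.resid(qz, Y)
    dfree <- n - qz$rank - df_cov
    if (dfree <= 0) stop("not enough nuclei for the requested model")
    sigma2 <- colSums(R^2) / dfree
    xtx_inv <- chol2inv(chol(crossprod(Z)))
    se <- sqrt(outer(diag(xtx_inv), sigma2))
    tt <- B / se
    lapply(cols, function(p) {
      j <- which(colnames(Z) == p)
      data.frame(gene = colnames(Y), protein = p,
                 coefficient = B[j, ], t_stat = tt[j, ],
                 p_value = 2 * stats::pt(-abs(tt[j, ]), dfree),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
  }
  parts <- if (mode == "joint") fit_block(proteins)
  else unlist(lapply(proteins, function(p) fit_block(p)), recursive = FALSE)
  tab <- do.call(rbind, parts)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  nd <- attr(residuals, "n_detected")
  tab$n_nuclei_used <- if (!is.null(nd)) as.integer(nd[tab$gene]) else n
  structure(list(table = tab, proteins = proteins, mode = mode,
                 residualize_protein = residualize_protein,
                 n_nuclei = n, fdr = fdr, call = match.call()),
            class = "protein_assoc")
}

#' Two-step protein-transcript association model from a dataset
#'
#' Convenience front end running the full model on a (QC-passed)
#' [nucleus_dataset()]: depth normalization and `ln(x + 1)`, reference
#' normalization of antibody counts, nCLR transform, step-1 covariate
#' residualization and the step-2 protein fit.
#'
#' @param ds a [nucleus_dataset()] (after [qc_filter()])
#' @param proteins antibodies to model (default: the panel minus the
#'   reference)
#' @param pseudocount passed to [normalize_to_reference()]
#' @param cohort_mask passed to [clr_transform()]
#' @param ... passed on to [fit_protein_associations()] and
#'   [residualize_expression()] (`covariates`, `min_nuclei`, `mode`,
#'   `residualize_protein`, `fdr`)
#' @param covariates,min_nuclei see [residualize_expression()]
#' @return a `protein_assoc` object; the nCLR matrix is attached as
#'   element `nclr`
#' @examples
#' sim <- simulate_incite(sim_config(n_donors_per_group = 2,
#'                                   groups = c("young", "AD"),
#'                                   nuclei_per_donor_mean = 150,
#'                                   n_genes = 60, seed = 3))
#' ds <- qc_filter(sim$dataset)$dataset
#' fit <- protein_assoc(ds)
#' fit
#' head(summary(fit))
#' @export
protein_assoc <- function(ds, proteins = setdiff(colnames(ds$A), ds$reference),
                          pseudocount = 1, cohort_mask = NULL,
                          covariates = c("log_ncounts", "log_hashtag_counts",
                                         "batch"),
                          min_nuclei = 25L, ...) {
  norm_X <- normalize_expression(ds$X)
  n_p <- normalize_to_reference(ds$A, reference = ds$reference,
                                pseudocount = pseudocount)
  nclr <- clr_transform(n_p, cohort_mask = cohort_mask)
  res <- residualize_expression(norm_X, ds$meta, covariates = covariates,
                                min_nuclei = min_nuclei)
  fit <- fit_protein_associations(res, nclr, proteins = proteins, ...)
  fit$nclr <- nclr
  fit$call <- match.call()
  fit
}

#' @export
print.protein_assoc <- function(x, ...) {
  cat(sprintf("<protein_assoc> %s fit of %d genes x %d proteins on %d nuclei\n",
              x$mode, length(unique(x$table$gene)), length(x$proteins),
              x$n_nuclei))
  sig <- sum(x$table$q_value < x$fdr)
  cat(sprintf("  %d of %d tests significant at BH q < %.2g\n",
              sig, nrow(x$table), x$fdr))
  invisible(x)
}

#' Summarize significant associations per protein
#'
#' @param object a `protein_assoc`
#' @param fdr significance level (default: the fit's)
#' @param ... ignored
#' @return data.frame with one row per protein: number of tested genes and
#'   of significantly positive / negative associations
#' @export
summary.protein_assoc <- function(object, fdr = object$fdr, ...) {
  tab <- object$table
  out <- do.call(rbind, lapply(split(tab, tab$protein), function(d) {
    sig <- d$q_value < fdr
    data.frame(protein = d$protein[1], n_genes = nrow(d),
               n_positive = sum(sig & d$coefficient > 0),
               n_negative = sum(sig & d$coefficient < 0),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' @export
coef.protein_assoc <- function(object, ...) {
  tab <- object$table
  genes <- unique(tab$gene)
  out <- matrix(NA_real_, length(genes), length(object$proteins),
                dimnames = list(genes, object$proteins))
  out[cbind(tab$gene, tab$protein)] <- tab$coefficient
  out
}

#' Significant gene sets from a fitted association model
#'
#' @param fit a `protein_assoc`
#' @param protein protein name
#' @param sign `"positive"`, `"negative"` or `"both"`
#' @param fdr significance level (default: the fit's)
#' @return character vector of gene names
#' @export
significant_genes <- function(fit, protein, sign = c("positive", "negative",
                                                     "both"),
                              fdr = fit$fdr) {
  sign <- match.arg(sign)
  tab <- fit$table[fit$table$protein == protein, ]
  sig <- tab$q_value < fdr
  sig <- switch(sign,
                positive = sig & tab$coefficient > 0,
                negative = sig & tab$coefficient < 0,
                both = sig)
  tab$gene[sig]
}

#' Fisher overlap of associated genes with a target gene set
#'
#' 2x2 contingency of membership in the associated set versus a target set
#' (e.g., CLIP-derived TDP-43-bound transcripts) over the tested universe;
#' two-sided Fisher exact p value and the sample cross-product odds ratio
#' `(a*d)/(b*c)`.
#'
#' @param assoc_genes character vector of associated genes (a subset of
#'   `universe`)
#' @param target_set character vector, the reference gene set
#' @param universe all genes tested
#' @return list with `odds_ratio`, `p_value`, `table` (2x2 matrix)
#' @export
overlap_enrichment <- function(assoc_genes, target_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  assoc_genes <- unique(assoc_genes)
  target_set <- intersect(unique(target_set), universe)
  if (length(setdiff(assoc_genes, universe)))
    stop("assoc_genes must be a subset of the universe")
  a <- length(intersect(assoc_genes, target_set))
  b <- length(assoc_genes) - a
  cc <- length(target_set) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("associated", "not_associated"),
                                c("in_set", "out_set")))
  list(odds_ratio = (a * d) / (b * cc),
       p_value = stats::fisher.test(tab, alternative = "two.sided")$p.value,
       table = tab)
}

#' Percentage overlap of two gene sets
#'
#' `100 * |A intersect B| / |A union B|` - genes in common divided by all
#' genes in either set.
#'
#' @param set_a,set_b character vectors
#' @return percentage in [0, 100]
#' @export
gene_set_overlap_pct <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- union(set_a, set_b)
  if (length(u) == 0L) stop("both sets are empty")
  100 * length(intersect(set_a, set_b)) / length(u)
}
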