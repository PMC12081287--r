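#' Normalize antibody counts to the reference antibody
#'
#' Divides every antibody's counts by the histone H3 reference counts of
#' the same nucleus:
#' `n_p[i, p] = (A[i, p] + pseudocount) / (A[i, ref] + pseudocount)`.
#' Because per-nucleus antibody capture efficiency multiplies the whole
#' panel including the reference, it cancels in this ratio. With
#' `pseudocount = 0`, nuclei with zero reference counts are flagged
#' (`NaN`/`Inf` rows) and should be excluded from protein analyses.
#'
#' @param A nuclei-by-antibodies count matrix
#' @param reference reference antibody column name
#' @param pseudocount added to numerator and denominator before the ratio;
#'   the default 1 keeps zero-heavy antibody counts loggable downstream
#' @return nuclei-by-antibodies matrix of reference-normalized values, with
#'   attribute `flagged` marking nuclei whose reference count was zero
#' @export
normalize_to_reference <- function(A, reference = "H3", pseudocount = 1) {
  A <- as.matrix(A)
  if (!reference %in% colnames(A))
    stop("reference antibody '", reference, "' absent from the antibody matrix")
  ref <- A[, reference] + pseudocount
  n_p <- (A + pseudocount) / ref
  flagged <- A[, reference] == 0
  if (pseudocount == 0 && any(flagged))
    warning(sum(flagged), " nuclei have zero reference counts; ",
            "their values are undefined and flagged")
  attr(n_p, "flagged") <- flagged
  n_p
}

#' Centered log-ratio (nCLR) transform of reference-normalized values
#'
#' `nclr[i, p] = ln(n_p[i, p] / g_p)`, with `g_p` the geometric mean of
#' antibody `p` over the nuclei of the centering cohort: the log of the
#' reference-normalized value, centered per antibody so the cohort log-mean
#' is exactly zero. The alternative compositional reading - geometric mean
#' across antibodies within each nucleus - is available via `axis`; under
#' that reading the reference denominator cancels algebraically, so
#' per-antibody centering across nuclei is the default.
#'
#' @param n_p nuclei-by-antibodies reference-normalized matrix (positive
#'   within the cohort)
#' @param cohort_mask logical/integer selection of nuclei defining the
#'   centering cohort (default: all nuclei)
#' @param axis `"nuclei"` (center each antibody across cohort nuclei,
#'   default) or `"antibodies"` (center each nucleus across its panel)
#' @return matrix of nCLR values, same shape as `n_p`
#' @export
clr_transform <- function(n_p, cohort_mask = NULL, axis = c("nuclei", "antibodies")) {
  axis <- match.arg(axis)
  n_p <- as.matrix(n_p)
  if (is.null(cohort_mask)) cohort_mask <- rep(TRUE, nrow(n_p))
  cohort <- n_p[cohort_mask, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("empty centering cohort")
  if (any(cohort <= 0) || any(!is.finite(cohort)))
    stop("non-positive or non-finite values in the centering cohort; ",
         "use a pseudocount in normalize_to_reference")
  lg <- log(n_p)
  if (axis == "nuclei") {
    center <- colMeans(log(cohort))
    sweep(lg, 2, center)
  } else {
    sweep(lg, 1, rowMeans(lg))
  }
}

#' Assign percentile bins for one protein
#'
#' Computes quantile thresholds on a stated nucleus subset only and labels
#' each subset nucleus with its bin; nuclei outside the subset get `NA`.
#' The default cuts (0.25, 0.75, 0.90) produce the labels `bottom25`,
#' `mid`, `top10_25`, `top10`; quintile cuts (0.2, 0.4, 0.6, 0.8) produce
#' `Q1`..`Q5`. Values exactly equal to a threshold go to the lower bin.
#' Bins are invariant to strictly monotone transforms of the values.
#'
#' @param values numeric vector of protein values (e.g., one nCLR column)
#' @param cuts increasing quantile cut points in (0, 1)
#' @param within logical/integer subset on which thresholds are computed
#'   and labels assigned (default: all)
#' @return factor of bin labels, `NA` outside `within`
#' @export
assign_percentile_bins <- function(values, cuts = c(0.25, 0.75, 0.90),
                                   within = NULL) {
  stopifnot(all(diff(cuts) > 0), all(cuts > 0 & cuts < 1))
  if (is.null(within)) within <- rep(TRUE, length(values))
  idx <- seq_along(values)[within]
  if (length(idx) == 0L) stop("empty subset")
  min_gap <- min(diff(c(0, cuts, 1)))
  if (length(idx) < 1 / min_gap)
    warning("subset smaller than 1/min(cut spacing); bins still assigned")
  labels <- if (isTRUE(all.equal(cuts, c(0.25, 0.75, 0.90))))
    c("bottom25", "mid", "top10_25", "top10")
  else if (isTRUE(all.equal(cuts, c(0.2, 0.4, 0.6, 0.8))))
    paste0("Q", 1:5)
  else paste0("bin", seq_len(length(cuts) + 1L))
  q <- stats::quantile(values[idx], probs = cuts, names = FALSE, type = 7)
  bin <- findInterval(values[idx], q, left.open = TRUE) + 1L
  out <- factor(rep(NA_character_, length(values)), levels = labels)
  out[idx] <- labels[bin]
  names(out) <- names(values)
  out
}

#' Gaussian-kernel embedding density of a nucleus subset
#'
#' Evaluates a 2-D Gaussian product-kernel density of the subset nuclei at
#' every nucleus's embedding position and min-max scales the result to
#' [0, 1], so regions of the embedding crowded with subset nuclei (e.g.,
#' the top decile of a protein) score near 1.
#'
#' @param embedding n-by-2 matrix of 2-D coordinates
#' @param subset_mask logical/integer selection of the nuclei whose
#'   density is mapped (default: all)
#' @param bandwidth optional length-2 bandwidth; default is the normal
#'   reference rule per axis on the subset
#' @return numeric vector of length n in [0, 1]
#' @export
embedding_density <- function(embedding, subset_mask = NULL, bandwidth = NULL) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2L)
  if (is.null(subset_mask)) subset_mask <- rep(TRUE, nrow(embedding))
  sub <- embedding[subset_mask, , drop = FALSE]
  if (nrow(sub) < 10L) stop("subset must contain at least 10 nuclei")
  if (is.null(bandwidth))
    bandwidth <- c(stats::bw.nrd0(sub[, 1]), stats::bw.nrd0(sub[, 2]))
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("degenerate embedding: zero spread in the subset")
  z1 <- outer(embedding[, 1], sub[, 1], "-") / bandwidth[1]
  z2 <- outer(embedding[, 2], sub[, 2], "-") / bandwidth[2]
  dens <- rowMeans(exp(-0.5 * (z1^2 + z2^2)))
  rng <- range(dens)
  if (rng[2] == rng[1]) stop("degenerate embedding: constant density")
  out <- (dens - rng[1]) / (rng[2] - rng[1])
  names(out) <- rownames(embedding)
  out
}
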