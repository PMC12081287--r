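#' Pooled Cohen's d implied by a two-sample t statistic
#'
#' Under the pooled-variance two-sample t test,
#' `d = t * sqrt(1/n1 + 1/n2)`. Useful for recovering the standardized
#' effect size from a reported t statistic and group sizes.
#'
#' @param t_stat pooled two-sample t statistic
#' @param n1,n2 group sizes
#' @return Cohen's d (pooled convention)
#' @examples
#' cohens_d_from_t(12.91, 6297, 4507) # ~0.252
#' @export
cohens_d_from_t <- function(t_stat, n1, n2) t_stat * sqrt(1 / n1 + 1 / n2)

#' Two-group contrast of protein levels with effect size
#'
#' Unpaired pooled-variance two-sample t test of `values` between two
#' nucleus groups, with pooled Cohen's d. The pooled convention makes the
#' internal identity `d = t * sqrt(1/n1 + 1/n2)` hold exactly, and it is
#' asserted on every computation.
#'
#' @param values numeric vector (e.g., reference-normalized or nCLR protein
#'   levels)
#' @param group_mask_1,group_mask_2 logical/integer selections of the two
#'   groups (each at least 2 nuclei)
#' @param labels optional length-2 character labels
#' @return object of class `contrast_result`: group labels and sizes,
#'   means, `t_stat`, `p_value` (two-sided), `cohens_d`
#' @export
percentile_contrast <- function(values, group_mask_1, group_mask_2,
                                labels = c("group1", "group2")) {
  x <- values[group_mask_1]
  y <- values[group_mask_2]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 nuclei")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  stopifnot(abs(d - cohens_d_from_t(t_stat, n1, n2)) < 1e-10)
  structure(list(group_labels = labels, n1 = n1, n2 = n2,
                 mean1 = mean(x), mean2 = mean(y), t_stat = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), n1 + n2 - 2),
                 cohens_d = d),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$group_labels[1], x$n1, x$mean1,
              x$group_labels[2], x$n2, x$mean2))
  cat(sprintf("  pooled t = %.3f, p = %.3g, Cohen's d = %.3f\n",
              x$t_stat, x$p_value, x$cohens_d))
  invisible(x)
}

#' Protein-protein stoichiometry curve
#'
#' Summarizes the relationship between two nuclear proteins (e.g., p65 on
#' x, TDP-43 on y) as equal-count bins on the x protein with per-bin means
#' of the y protein, smoothed by a running mean, one curve per group.
#' Groups with fewer nuclei than `n_bins` are skipped with a warning. The
#' result is invariant to nucleus ordering.
#'
#' @param nclr nuclei-by-antibodies nCLR matrix
#' @param x_protein,y_protein antibody column names
#' @param groups optional per-nucleus group labels (e.g., disease group);
#'   `NULL` pools all nuclei as one group `"all"`
#' @param n_bins number of equal-count bins
#' @param window running-mean window (odd; 3 by default)
#' @return data.frame with columns group, bin, bin_center, bin_mean
#'   (smoothed), bin_mean_raw, bin_count
#' @export
stoichiometry_curve <- function(nclr, x_protein, y_protein, groups = NULL,
                                n_bins = 20L, window = 3L) {
  stopifnot(x_protein %in% colnames(nclr), y_protein %in% colnames(nclr))
  if (is.null(groups)) groups <- rep("all", nrow(nclr))
  out <- lapply(unique(groups), function(g) {
    i <- which(groups == g)
    if (length(i) < n_bins) {
      warning("group '", g, "' has fewer nuclei (", length(i),
              ") than bins (", n_bins, "); skipped")
      return(NULL)
    }
    x <- nclr[i, x_protein]
    y <- nclr[i, y_protein]
    o <- order(x)
    bin <- rep(seq_len(n_bins), diff(round(seq(0, length(i),
                                               length.out = n_bins + 1L))))
    centers <- tapply(x[o], bin, mean)
    means <- tapply(y[o], bin, mean)
    counts <- tapply(y[o], bin, length)
    data.frame(group = g, bin = seq_len(n_bins),
               bin_center = as.numeric(centers),
               bin_mean = running_mean(as.numeric(means), window),
               bin_mean_raw = as.numeric(means),
               bin_count = as.integer(counts), row.names = NULL)
  })
  do.call(rbind, out)
}

# running mean with shrinking window at the edges
running_mean <- function(v, window) {
  h <- (window - 1L) %/% 2L
  vapply(seq_along(v), function(i) {
    mean(v[max(1L, i - h):min(length(v), i + h)])
  }, 0)
}

#' One-way ANOVA with Tukey HSD on donor-level values
#'
#' Donor (not nucleus) is the intended unit for composition comparisons:
#' e.g., the per-donor proportion of capillary nuclei in a cluster, by
#' disease group. Groups with fewer than 2 units are excluded with a
#' warning. Returns the omnibus F test and the full `k*(k-1)/2` Tukey
#' honest-significant-difference table.
#'
#' @param values numeric vector, one entry per unit (donor)
#' @param groups group labels per unit
#' @return list with `f_stat`, `p_value`, `tukey` (data.frame: comparison,
#'   diff, lwr, upr, p_adj)
#' @export
group_anova_tukey <- function(values, groups) {
  groups <- factor(as.character(groups))
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("excluding group(s) with a single unit: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 units")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(f_stat = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

#' Spearman correlation of cluster proportions with donor age
#'
#' Rank correlation (two-sided) of each cluster's per-donor proportion
#' against donor age. Clusters with constant proportions are flagged with
#' `NA` correlation.
#'
#' @param donor_proportions donors-by-clusters proportion matrix (rows sum
#'   to 1), e.g. from [cluster_proportions()]
#' @param donor_age numeric age per donor, aligned on rows
#' @return data.frame with columns cluster, rho, p_value, flagged
#' @export
correlate_age_proportions <- function(donor_proportions, donor_age) {
  stopifnot(nrow(donor_proportions) == length(donor_age))
  if (nrow(donor_proportions) < 4) stop("need at least 4 donors")
  out <- lapply(colnames(donor_proportions), function(cl) {
    p <- donor_proportions[, cl]
    if (stats::sd(p) == 0)
      return(data.frame(cluster = cl, rho = NA_real_, p_value = NA_real_,
                        flagged = TRUE))
    ct <- suppressWarnings(stats::cor.test(p, donor_age, method = "spearman",
                                           alternative = "two.sided",
                                           exact = FALSE))
    data.frame(cluster = cl, rho = unname(ct$estimate),
               p_value = ct$p.value, flagged = FALSE)
  })
  do.call(rbind, out)
}
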