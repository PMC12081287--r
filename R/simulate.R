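#' Simulation configuration for a synthetic inCITE-seq cohort
#'
#' Builds the parameter list consumed by [simulate_incite()] and its
#' component stages. Defaults describe a desk-scale multi-donor brain
#' cohort: five donor groups (healthy young and aged plus three
#' neurodegenerative diagnoses), 10x-well batches that each pool donors
#' from several groups, a four-antibody nuclear panel including the histone
#' H3 reference, log-normal per-nucleus antibody capture efficiency shared
#' across the panel, latent nuclear protein levels on the natural-log
#' scale, and negative-binomial counts for both modalities.
#'
#' @param n_donors_per_group donors per disease group
#' @param groups disease groups, a subset of
#'   `c("young", "aged", "AD", "ALS", "FTD")`
#' @param nuclei_per_donor_mean,nuclei_per_donor_size mean and size
#'   (dispersion) of the negative-binomial draw of nuclei per donor
#' @param n_genes total genes including `n_mito` mitochondrial genes
#' @param n_batches number of 10x-well batches; donors are interleaved
#'   across batches so every batch mixes groups
#' @param panel antibody names; must contain `reference`
#' @param reference reference antibody name
#' @param effect_table data.frame with columns `gene`, `protein`, `beta`
#'   giving true gene-protein effects on the log expression scale; `NULL`
#'   plants the default block of ten positive and ten negative unit effects
#'   on TDP-43; use a zero-row data.frame for a global null
#' @param capture_efficiency_sd log-normal SD of the per-nucleus capture
#'   efficiency scalar applied to every antibody including the reference
#' @param depth_mean,depth_sdlog expected per-nucleus total gene counts and
#'   log-normal SD of the per-nucleus depth factor
#' @param gene_dispersion,ab_dispersion negative-binomial size parameters
#'   for gene and antibody counts (`Inf` gives Poisson noise)
#' @param latent_sd nucleus-level SD of latent non-reference protein levels
#' @param donor_sd donor-level random-effect SD for latent protein
#' @param h3_sd nucleus-level SD of the latent reference level (the
#'   reference is constant across nuclei up to this noise)
#' @param batch_effect_sd SD of per-gene-per-batch log expression shifts
#' @param tdp43_rev1_shift,tdp43_disease_shift,bcat_rev1_shift,p65_rev1_shift
#'   latent shifts (log scale) applied in the reactive capillary cluster
#'   (REV1); `tdp43_disease_shift` applies additionally in REV1 nuclei of
#'   AD/ALS/FTD donors
#' @param frac_capillary,frac_microglia cell-type mixture (remainder
#'   "other")
#' @param rev1_prob_disease,rev1_prob_healthy probability that a capillary
#'   nucleus belongs to REV1 rather than HC, by donor health status
#' @param hashtag_meanlog,hashtag_sdlog,frac_hashtag_high,hashtag_high_meanlog
#'   log-normal hashtag-count model with a small contaminating
#'   high-hashtag component exercising the QC bound at 4,000
#' @param n_mito,mito_beta,frac_mito_high,mito_high_beta number of `MT-`
#'   genes, Beta parameters of the per-nucleus mitochondrial count
#'   fraction, and a contaminating high-mitochondria component exercising
#'   the 5 percent QC bound
#' @param seed integer seed; a fixed seed makes [simulate_incite()] fully
#'   reproducible
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_donors_per_group = 4,
                       groups = c("young", "aged", "AD", "ALS", "FTD"),
                       nuclei_per_donor_mean = 250,
                       nuclei_per_donor_size = 8,
                       n_genes = 300,
                       n_batches = 4,
                       panel = c("H3", "TDP-43", "p65", "beta-catenin"),
                       reference = "H3",
                       effect_table = NULL,
                       capture_efficiency_sd = 0.4,
                       depth_mean = 2000,
                       depth_sdlog = 0.3,
                       gene_dispersion = 2,
                       ab_dispersion = 10,
                       latent_sd = 1,
                       donor_sd = 0.2,
                       h3_sd = 0.1,
                       batch_effect_sd = 0.2,
                       tdp43_rev1_shift = -0.4,
                       tdp43_disease_shift = -0.6,
                       bcat_rev1_shift = -0.25,
                       p65_rev1_shift = 0.1,
                       frac_capillary = 0.5,
                       frac_microglia = 0.25,
                       rev1_prob_disease = 0.6,
                       rev1_prob_healthy = 0.15,
                       hashtag_meanlog = log(500),
                       hashtag_sdlog = 0.6,
                       frac_hashtag_high = 0.02,
                       hashtag_high_meanlog = log(8000),
                       n_mito = 10,
                       mito_beta = c(2, 98),
                       frac_mito_high = 0.03,
                       mito_high_beta = c(8, 92),
                       seed = 1L) {
  if (length(groups) == 0L) stop("at least one disease group is required")
  groups <- match.arg(groups, c("young", "aged", "AD", "ALS", "FTD"),
                      several.ok = TRUE)
  stopifnot(n_donors_per_group >= 1, n_genes >= 1, n_batches >= 1,
            nuclei_per_donor_mean >= 1, capture_efficiency_sd >= 0,
            n_mito < n_genes)
  if (!reference %in% panel)
    stop("panel must contain the reference antibody '", reference, "'")
  if (is.null(effect_table)) {
    effect_table <- data.frame(
      gene = sprintf("G%04d", 1:20),
      protein = "TDP-43",
      beta = rep(c(1, -1), each = 10),
      stringsAsFactors = FALSE)
    effect_table <- effect_table[effect_table$protein %in% panel, , drop = FALSE]
  }
  if (nrow(effect_table) && any(!is.finite(effect_table$beta)))
    stop("effect_table betas must be finite")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

mito_gene_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP6",
                     "MT-CYB", "MT-ND3", "MT-ND4", "MT-CO3", "MT-ATP8",
                     "MT-ND5", "MT-ND6")

sim_gene_names <- function(config) {
  n_reg <- config$n_genes - config$n_mito
  c(sprintf("G%04d", seq_len(n_reg)),
    mito_gene_names[seq_len(config$n_mito)])
}

#' Simulate donors and a nucleus metadata skeleton
#'
#' Assigns each donor to one disease group, an age drawn from a
#' group-appropriate range and a 10x-well batch; donors are interleaved
#' across batches so every batch pools donors from multiple groups
#' (mirroring pooled 10x reactions). Nuclei counts per donor are
#' negative-binomial; each nucleus receives a cell type, a capillary
#' subcluster (REV1 or HC, with REV1 enriched in disease donors) and
#' hashtag counts. Uses the current RNG state; seed via
#' [simulate_incite()] or `set.seed()`.
#'
#' @param config a [sim_config()]
#' @return list with `donors` (one row per donor) and `meta` (one row per
#'   nucleus, barcode row names)
#' @export
simulate_cohort <- function(config) {
  g <- config$groups
  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(length(g) * config$n_donors_per_group)),
    disease_group = rep(g, each = config$n_donors_per_group),
    stringsAsFactors = FALSE)
  age_range <- list(young = c(15, 29), aged = c(67, 95), AD = c(60, 95),
                    ALS = c(45, 80), FTD = c(45, 75))
  donors$age <- vapply(donors$disease_group, function(gr) {
    r <- age_range[[gr]]
    round(stats::runif(1, r[1], r[2]))
  }, 0)
  # interleave groups, then deal donors to batches round-robin: every batch
  # mixes healthy and disease donors
  inter <- order(stats::ave(seq_len(nrow(donors)), donors$disease_group,
                            FUN = seq_along))
  donors$batch <- NA_character_
  donors$batch[inter] <- paste0("B", rep_len(seq_len(config$n_batches),
                                             nrow(donors)))
  n_nuc <- pmax(1L, stats::rnbinom(nrow(donors),
                                   mu = config$nuclei_per_donor_mean,
                                   size = config$nuclei_per_donor_size))
  donors$n_nuclei <- n_nuc
  idx <- rep(seq_len(nrow(donors)), n_nuc)
  n <- length(idx)
  meta <- data.frame(
    donor_id = donors$donor_id[idx],
    disease_group = donors$disease_group[idx],
    batch = donors$batch[idx],
    age = donors$age[idx],
    stringsAsFactors = FALSE)
  rownames(meta) <- sprintf("N%06d", seq_len(n))
  p_other <- max(0, 1 - config$frac_capillary - config$frac_microglia)
  meta$cell_type <- sample(c("capillary EC", "microglia", "other"), n,
                           replace = TRUE,
                           prob = c(config$frac_capillary,
                                    config$frac_microglia, p_other))
  diseased <- meta$disease_group %in% c("AD", "ALS", "FTD")
  p_rev1 <- ifelse(diseased, config$rev1_prob_disease,
                   config$rev1_prob_healthy)
  is_cap <- meta$cell_type == "capillary EC"
  meta$cluster <- meta$cell_type
  meta$cluster[is_cap] <- ifelse(stats::runif(sum(is_cap)) < p_rev1[is_cap],
                                 "REV1", "HC")
  high <- stats::runif(n) < config$frac_hashtag_high
  meta$hashtag_counts <- round(stats::rlnorm(
    n,
    meanlog = ifelse(high, config$hashtag_high_meanlog, config$hashtag_meanlog),
    sdlog = config$hashtag_sdlog))
  list(donors = donors, meta = meta)
}

#' Simulate latent nuclear protein levels and nuisance factors
#'
#' Draws the latent natural-log protein level `L` for every nucleus and
#' antibody (the quantity whose estimate is nCLR), donor random effects,
#' cluster/disease shifts for TDP-43, beta-catenin and p65 in the REV1
#' cluster, the per-nucleus capture-efficiency scalar shared across the
#' panel, the per-nucleus depth factor and the mitochondrial count
#' fraction. The reference antibody's latent level is constant across
#' nuclei up to `h3_sd` noise.
#'
#' @param meta nucleus metadata from [simulate_cohort()]
#' @param config a [sim_config()]
#' @return list of class `sim_truth` with `L`, `capture_eff`, `depth`,
#'   `mito_fraction`, `beta_true`
#' @export
simulate_latent_protein <- function(meta, config) {
  n <- nrow(meta)
  panel <- config$panel
  base <- stats::setNames(rep(log(100), length(panel)), panel)
  base[config$reference] <- log(300)
  L <- matrix(rep(base, each = n), n, length(panel),
              dimnames = list(rownames(meta), panel))
  donor_ids <- unique(meta$donor_id)
  for (p in setdiff(panel, config$reference)) {
    re <- stats::setNames(stats::rnorm(length(donor_ids), 0, config$donor_sd),
                          donor_ids)
    L[, p] <- L[, p] + re[meta$donor_id] + stats::rnorm(n, 0, config$latent_sd)
  }
  L[, config$reference] <- L[, config$reference] + stats::rnorm(n, 0, config$h3_sd)
  rev1 <- meta$cluster == "REV1"
  diseased <- meta$disease_group %in% c("AD", "ALS", "FTD")
  shift_if <- function(protein, mask, amount) {
    if (protein %in% panel && any(mask))
      L[mask, protein] <<- L[mask, protein] + amount
  }
  shift_if("TDP-43", rev1, config$tdp43_rev1_shift)
  shift_if("TDP-43", rev1 & diseased, config$tdp43_disease_shift)
  shift_if("beta-catenin", rev1, config$bcat_rev1_shift)
  shift_if("p65", rev1, config$p65_rev1_shift)

  genes <- sim_gene_names(config)
  beta_true <- matrix(0, length(genes), length(panel),
                      dimnames = list(genes, panel))
  et <- config$effect_table
  if (nrow(et)) {
    bad <- !(et$gene %in% genes) | !(et$protein %in% panel)
    if (any(bad))
      stop("effect_table refers to unknown gene or protein: ",
           paste(et$gene[bad], collapse = ", "))
    beta_true[cbind(et$gene, et$protein)] <- et$beta
  }
  high <- stats::runif(n) < config$frac_mito_high
  ab <- ifelse(high, config$mito_high_beta[1], config$mito_beta[1])
  bb <- ifelse(high, config$mito_high_beta[2], config$mito_beta[2])
  structure(list(
    L = L,
    capture_eff = exp(stats::rnorm(n, 0, config$capture_efficiency_sd)),
    depth = stats::rlnorm(n, log(config$depth_mean) - config$depth_sdlog^2 / 2,
                          config$depth_sdlog),
    mito_fraction = stats::rbeta(n, ab, bb),
    beta_true = beta_true), class = "sim_truth")
}

rcounts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate antibody-capture counts
#'
#' `A[i, p] ~ NegBin(mean = c_i * exp(L[i, p]), size = ab_dispersion)`,
#' with `c_i` the per-nucleus capture-efficiency scalar shared by the whole
#' panel including the reference. Because the scalar multiplies every
#' antibody of a nucleus, it cancels exactly under reference normalization
#' - the nuisance this generator exists to create.
#'
#' @param truth a `sim_truth` from [simulate_latent_protein()]
#' @param config a [sim_config()]
#' @param noise if `FALSE`, return the rounded expected counts (no
#'   sampling), for limit-case checks
#' @return nuclei-by-antibodies integer count matrix
#' @export
simulate_antibody_counts <- function(truth, config, noise = TRUE) {
  mu <- truth$capture_eff * exp(truth$L)
  A <- if (noise) {
    matrix(rcounts(length(mu), as.vector(mu), config$ab_dispersion),
           nrow(mu), ncol(mu))
  } else round(mu)
  dimnames(A) <- dimnames(truth$L)
  A
}

#' Simulate gene-expression counts
#'
#' `X[i, g] ~ NegBin(mean = s_i * pi_g(i), size = gene_dispersion)`, where
#' the relative expression `pi` follows
#' `exp(alpha_g + batch_g[b(i)] + sum_p beta_true[g, p] * L[i, p])`
#' normalized within each nucleus, `s_i` is the per-nucleus depth factor,
#' and the mitochondrial gene block receives the nucleus's simulated
#' mitochondrial fraction. Genes named in the effect table are given
#' elevated baselines so planted effects are observable.
#'
#' @param truth a `sim_truth` from [simulate_latent_protein()]
#' @param meta nucleus metadata from [simulate_cohort()]
#' @param config a [sim_config()]
#' @return nuclei-by-genes sparse count matrix
#' @export
simulate_gene_counts <- function(truth, meta, config) {
  genes <- sim_gene_names(config)
  n <- nrow(meta)
  n_reg <- config$n_genes - config$n_mito
  reg <- genes[seq_len(n_reg)]
  alpha <- stats::rnorm(n_reg, 0, 1)
  names(alpha) <- reg
  planted <- intersect(config$effect_table$gene, reg)
  alpha[planted] <- pmax(alpha[planted], 1)
  batches <- sort(unique(meta$batch))
  batch_eff <- matrix(stats::rnorm(n_reg * length(batches), 0,
                                   config$batch_effect_sd),
                      n_reg, length(batches),
                      dimnames = list(reg, batches))
  eta <- matrix(alpha, n, n_reg, byrow = TRUE) +
    t(batch_eff[, meta$batch, drop = FALSE]) +
    truth$L %*% t(truth$beta_true[reg, , drop = FALSE])
  pi_reg <- exp(eta)
  pi_reg <- pi_reg / rowSums(pi_reg) * (1 - truth$mito_fraction)
  w_mito <- exp(stats::rnorm(config$n_mito, 0, 0.5))
  w_mito <- w_mito / sum(w_mito)
  pi_mito <- outer(truth$mito_fraction, w_mito)
  mu <- cbind(pi_reg, pi_mito) * truth$depth
  X <- matrix(rcounts(length(mu), as.vector(mu), config$gene_dispersion),
              n, config$n_genes, dimnames = list(rownames(meta), genes))
  methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
}

#' Simulate a complete synthetic inCITE-seq cohort
#'
#' Orchestrates [simulate_cohort()], [simulate_latent_protein()],
#' [simulate_antibody_counts()] and [simulate_gene_counts()] under the
#' config seed and assembles the result into a [nucleus_dataset()]. The
#' returned truth carries the latent protein matrix and the true
#' gene-protein effect matrix for recovery and calibration tests.
#'
#' @param config a [sim_config()]
#' @return list with `dataset` (a `nucleus_dataset`), `truth` (a
#'   `sim_truth`) and `donors`
#' @examples
#' sim <- simulate_incite(sim_config(n_donors_per_group = 1,
#'                                   groups = c("young", "AD"),
#'                                   nuclei_per_donor_mean = 60,
#'                                   n_genes = 50, seed = 7))
#' sim$dataset
#' @export
simulate_incite <- function(config = sim_config()) {
  set.seed(config$seed)
  cohort <- simulate_cohort(config)
  truth <- simulate_latent_protein(cohort$meta, config)
  A <- simulate_antibody_counts(truth, config)
  X <- simulate_gene_counts(truth, cohort$meta, config)
  ds <- nucleus_dataset(X, A, cohort$meta, reference = config$reference)
  list(dataset = ds, truth = truth, donors = cohort$donors)
}

#' Write a simulated cohort to disk as standard bundles
#'
#' Writes `expr/` and `adt/` MatrixMarket bundles, `meta.csv` and
#' `truth.csv` (columns gene, protein, beta_true for nonzero effects) under
#' `out_dir`, in the formats [assemble_dataset()] reads back.
#'
#' @param sim result of [simulate_incite()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_simulated_cohort <- function(sim, out_dir) {
  ds <- sim$dataset
  write_matrix_bundle(ds$X, file.path(out_dir, "expr"))
  write_matrix_bundle(ds$A, file.path(out_dir, "adt"))
  meta <- cbind(barcode = rownames(ds$meta), ds$meta)
  utils::write.csv(meta, file.path(out_dir, "meta.csv"), row.names = FALSE)
  bt <- sim$truth$beta_true
  nz <- which(bt != 0, arr.ind = TRUE)
  utils::write.csv(data.frame(gene = rownames(bt)[nz[, 1]],
                              protein = colnames(bt)[nz[, 2]],
                              beta_true = bt[nz]),
                   file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(out_dir)
}
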