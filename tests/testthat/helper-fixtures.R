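# Small deterministic fixtures built in code.

# a fully valid tiny dataset: n nuclei, g genes (last two mitochondrial),
# 3 antibodies incl. H3, two donors / groups / batches
tiny_dataset <- function(n = 12L, g = 8L, seed = 1L) {
  set.seed(seed)
  genes <- c(sprintf("G%03d", seq_len(g - 2L)), "MT-ND1", "MT-CO1")
  X <- matrix(rpois(n * g, 8) + 4, n, g,
              dimnames = list(sprintf("bc%02d", seq_len(n)), genes))
  # mitochondrial counts kept tiny so the mito fraction stays below 5%,
  # but detected in enough nuclei to survive the gene filter
  X[, (g - 1L):g] <- 0
  X[seq_len(min(n, 8L)), (g - 1L):g] <- 1
  A <- matrix(rpois(n * 3, 50) + 1, n, 3,
              dimnames = list(rownames(X), c("H3", "TDP-43", "p65")))
  meta <- data.frame(
    donor_id = rep(c("D1", "D2"), length.out = n),
    disease_group = rep(c("young", "AD"), length.out = n),
    batch = rep(c("B1", "B2"), each = n / 2),
    hashtag_counts = rpois(n, 300),
    cell_type = "capillary EC",
    cluster = rep(c("HC", "REV1"), length.out = n),
    row.names = rownames(X))
  nucleus_dataset(Matrix::Matrix(X, sparse = TRUE), A, meta)
}

# small simulated cohort used by several suites
small_sim <- function(seed = 11L, ...) {
  simulate_incite(sim_config(n_donors_per_group = 2,
                             groups = c("young", "aged", "AD"),
                             nuclei_per_donor_mean = 80,
                             n_genes = 60, n_batches = 2, seed = seed, ...))
}

# dataset with boundary nuclei around every QC rule, built in code:
# 30 filler nuclei expressing all genes, plus one nucleus per boundary
qc_boundary_dataset <- function() {
  set.seed(9)
  n_genes <- 60L
  genes <- c(sprintf("G%03d", seq_len(n_genes - 2L)), "MT-ND1", "MT-CO1")
  fill <- matrix(rpois(30 * n_genes, 4) + 1, 30, n_genes)
  special <- rbind(
    genes49  = c(rep(2, 49), rep(0, n_genes - 49)),
    genes50  = c(rep(2, 50), rep(0, n_genes - 50)),
    mito6pct = c(rep(2, 46), 1, 1, rep(0, n_genes - 50), 3, 3),  # 6/100 mito, 50 genes
    mito4pct = c(rep(2, 48), rep(0, n_genes - 50), 2, 2),  # 4/100 mito
    hash4001 = rep(2, n_genes),
    hash4000 = rep(2, n_genes),
    tdp3001  = rep(2, n_genes),
    tdp3000  = rep(2, n_genes))
  X <- rbind(fill, special)
  rownames(X) <- c(sprintf("fill%02d", 1:30), rownames(special))
  colnames(X) <- genes
  A <- matrix(100, nrow(X), 3,
              dimnames = list(rownames(X), c("H3", "TDP-43", "p65")))
  A["tdp3001", "TDP-43"] <- 3001
  A["tdp3000", "TDP-43"] <- 3000
  meta <- data.frame(donor_id = rep("D1", nrow(X)), disease_group = "AD",
                     batch = "B1", hashtag_counts = 300,
                     cell_type = "capillary EC", row.names = rownames(X))
  meta["hash4001", "hashtag_counts"] <- 4001
  meta["hash4000", "hashtag_counts"] <- 4000
  nucleus_dataset(Matrix::Matrix(X, sparse = TRUE), A, meta)
}

# cohort with controlled unit sizes: donor A has 9 cells, donor B has 10
# low-count cells, donor C has 12 cells summing to 799 counts
pseudobulk_fixture <- function() {
  set.seed(26)
  build <- function(donor, n, per_cell) {
    X <- matrix(per_cell, n, 4)
    list(X = X, donor = rep(donor, n))
  }
  a <- build("A", 9, 100)      # 9 cells: dropped on cell count
  b <- build("B", 10, 25)      # 10 cells x 100 counts = 1000: kept
  cc <- build("C", 12, 0)      # filled below to total 799
  cc$X[] <- 16                 # 12*4*16 = 768
  cc$X[1, 1:3] <- 16 + 10      # + 30 -> 798
  cc$X[2, 1] <- 17             # 799 total: dropped on counts
  d <- build("D", 15, 30)      # kept
  X <- do.call(rbind, list(a$X, b$X, cc$X, d$X))
  colnames(X) <- paste0("g", 1:4)
  rownames(X) <- paste0("n", seq_len(nrow(X)))
  meta <- data.frame(
    donor_id = c(a$donor, b$donor, cc$donor, d$donor),
    disease_group = "AD", batch = "B1", hashtag_counts = 10,
    cell_type = "capillary EC", row.names = rownames(X))
  A <- matrix(5, nrow(X), 2, dimnames = list(rownames(X), c("H3", "TDP-43")))
  nucleus_dataset(Matrix::Matrix(X, sparse = TRUE), A, meta)
}

# null-cohort config: no planted effects, ~2,000 nuclei, 500 genes
null_cohort_config <- function(seed, n_genes = 500) {
  sim_config(n_donors_per_group = 2, nuclei_per_donor_mean = 200,
             n_genes = n_genes,
             effect_table = data.frame(gene = character(),
                                       protein = character(),
                                       beta = numeric()),
             seed = seed)
}

# independent brute-force CLR oracle: explicit per-antibody product / nth
# root over the cohort, elementwise logs
clr_oracle <- function(n_p, cohort_mask = rep(TRUE, nrow(n_p))) {
  out <- n_p
  for (p in seq_len(ncol(n_p))) {
    v <- n_p[cohort_mask, p]
    gm <- prod(v)^(1 / length(v))
    out[, p] <- log(n_p[, p] / gm)
  }
  out
}

# independent BH step-up: sort p ascending, q_i = min_{j >= i} m*p_j/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q)[order(o)]
}
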