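test_that("cohort layout: donors per group, mixed batches, NB nucleus totals", {
  cfg <- sim_config(n_donors_per_group = 2,
                    groups = c("young", "aged", "AD", "ALS"),
                    nuclei_per_donor_mean = 500, nuclei_per_donor_size = 8,
                    n_batches = 2, seed = 5)
  set.seed(cfg$seed)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$donors), 8)
  expect_equal(as.integer(table(cohort$donors$disease_group)), rep(2L, 4))
  # every batch pools several disease groups
  mix <- tapply(cohort$donors$disease_group, cohort$donors$batch,
                function(g) length(unique(g)))
  expect_true(all(mix >= 2))
  # total nuclei within 3 SD of 8 * 500 under the stated NB draw
  mu <- 500; size <- 8; ndon <- 8
  sd_tot <- sqrt(ndon * (mu + mu^2 / size))
  expect_lt(abs(nrow(cohort$meta) - ndon * mu), 3 * sd_tot)
  expect_error(sim_config(groups = character()), "group")
})

test_that("a fixed seed reproduces the cohort exactly", {
  a <- small_sim(seed = 21)
  b <- small_sim(seed = 21)
  expect_identical(as.matrix(a$dataset$X), as.matrix(b$dataset$X))
  expect_identical(a$dataset$A, b$dataset$A)
  expect_identical(a$dataset$meta, b$dataset$meta)
  expect_identical(a$truth$L, b$truth$L)
})

test_that("antibody counts follow capture efficiency times exp(latent)", {
  cfg <- sim_config(capture_efficiency_sd = 0, seed = 2)
  set.seed(2)
  cohort <- simulate_cohort(sim_config(n_donors_per_group = 1,
                                       groups = c("young", "AD"),
                                       nuclei_per_donor_mean = 30, seed = 2))
  truth <- simulate_latent_protein(cohort$meta, cfg)
  # noise off, unit capture: counts exactly round(exp(L))
  A <- simulate_antibody_counts(truth, cfg, noise = FALSE)
  expect_equal(A, round(truth$capture_eff * exp(truth$L)))
  expect_true(all(truth$capture_eff == 1))

  # doubling every capture-efficiency scalar doubles expected counts of
  # every antibody including the reference, and leaves reference-normalized
  # means unchanged
  cfg2 <- sim_config(n_donors_per_group = 1, groups = "young",
                     nuclei_per_donor_mean = 1000, seed = 3)
  set.seed(3)
  cohort2 <- simulate_cohort(cfg2)
  truth2 <- simulate_latent_protein(cohort2$meta, cfg2)
  set.seed(7); A1 <- simulate_antibody_counts(truth2, cfg2)
  truth2x <- truth2; truth2x$capture_eff <- 2 * truth2$capture_eff
  set.seed(7); A2 <- simulate_antibody_counts(truth2x, cfg2)
  expect_equal(colMeans(A2) / colMeans(A1), rep(2, ncol(A1)),
               tolerance = 0.05, ignore_attr = TRUE)
  r1 <- colMeans(normalize_to_reference(A1, pseudocount = 0))
  r2 <- colMeans(normalize_to_reference(A2, pseudocount = 0))
  expect_equal(r1, r2, tolerance = 0.05)

  # a panel of one antibody plus the reference still works
  cfg1 <- sim_config(panel = c("H3", "TDP-43"),
                     effect_table = data.frame(gene = character(),
                                               protein = character(),
                                               beta = numeric()), seed = 4)
  sim1 <- simulate_incite(cfg1)
  expect_equal(ncol(sim1$dataset$A), 2)
})

test_that("depth factor scales totals but not normalized expression", {
  base <- sim_config(n_donors_per_group = 1, groups = "young",
                     nuclei_per_donor_mean = 400, n_genes = 80, seed = 6)
  dbl <- base; dbl$depth_mean <- 2 * base$depth_mean
  s1 <- simulate_incite(base)
  s2 <- simulate_incite(dbl)
  expect_equal(mean(s2$dataset$meta$total_counts) /
                 mean(s1$dataset$meta$total_counts), 2, tolerance = 0.05)
  m1 <- colMeans(as.matrix(normalize_expression(s1$dataset$X)))
  m2 <- colMeans(as.matrix(normalize_expression(s2$dataset$X)))
  expect_gt(cor(m1, m2), 0.99)
})

test_that("with no planted effects, residuals are uncorrelated with latent protein", {
  cfg <- sim_config(n_donors_per_group = 2, groups = c("young", "AD"),
                    nuclei_per_donor_mean = 300, n_genes = 80,
                    effect_table = data.frame(gene = character(),
                                              protein = character(),
                                              beta = numeric()), seed = 8)
  sim <- simulate_incite(cfg)
  res <- residualize_expression(normalize_expression(sim$dataset$X),
                                sim$dataset$meta)
  cors <- cor(res, sim$truth$L[, "TDP-43"])
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("an emitted bundle passes assemble_dataset unchanged", {
  sim <- small_sim(seed = 31)
  dir <- withr::local_tempdir()
  write_simulated_cohort(sim, dir)
  ds <- suppressMessages(assemble_dataset(file.path(dir, "expr"),
                                          file.path(dir, "adt"),
                                          file.path(dir, "meta.csv")))
  expect_equal(nrow(ds$X), nrow(sim$dataset$X))
  expect_equal(as.matrix(ds$X), as.matrix(sim$dataset$X)[rownames(ds$X), ])
  truth <- read.csv(file.path(dir, "truth.csv"))
  planted <- rownames(sim$truth$beta_true)[
    rowSums(sim$truth$beta_true != 0) > 0]
  expect_setequal(truth$gene, planted)
})
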