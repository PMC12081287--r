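# small aligned residual/nclr problem with known structure
make_assoc_fixture <- function(n = 200, g = 12, seed = 18) {
  set.seed(seed)
  meta <- data.frame(
    total_counts = rpois(n, 2000) + 500,
    hashtag_counts = rpois(n, 300),
    batch = sample(c("B1", "B2", "B3"), n, replace = TRUE),
    row.names = paste0("n", 1:n))
  counts <- matrix(rpois(n * g, 5), n, g,
                   dimnames = list(rownames(meta), sprintf("g%02d", 1:g)))
  norm_X <- normalize_expression(Matrix::Matrix(counts, sparse = TRUE))
  nclr <- matrix(rnorm(n * 2), n, 2,
                 dimnames = list(rownames(meta), c("TDP-43", "p65")))
  list(meta = meta, norm_X = norm_X, nclr = nclr)
}

test_that("step-1 residuals are orthogonal to every covariate column", {
  fx <- make_assoc_fixture()
  res <- residualize_expression(fx$norm_X, fx$meta, min_nuclei = 5)
  D <- attr(res, "design")
  dots <- crossprod(D, res)
  expect_lt(max(abs(dots)), 1e-8)
  # intercept-only covariates: residuals are mean-centered expression
  res0 <- residualize_expression(fx$norm_X, fx$meta,
                                 covariates = character(), min_nuclei = 5)
  expect_equal(res0, scale(as.matrix(fx$norm_X), scale = FALSE),
               ignore_attr = TRUE)
})

test_that("genes below the 25-nucleus detection floor are skipped", {
  fx <- make_assoc_fixture()
  M <- as.matrix(fx$norm_X)
  M[, "g01"] <- 0; M[1:24, "g01"] <- 1    # detected in 24 nuclei
  M[, "g02"] <- 0; M[1:25, "g02"] <- 1    # detected in 25
  res <- residualize_expression(Matrix::Matrix(M, sparse = TRUE), fx$meta)
  expect_false("g01" %in% colnames(res))
  expect_true("g02" %in% colnames(res))
  expect_true(all(attr(res, "n_detected") >= 25))
})

test_that("collinear design columns are dropped with a warning", {
  fx <- make_assoc_fixture()
  meta1 <- fx$meta
  meta1$batch <- "B1"  # single batch: its indicator is collinear
  expect_warning(res <- residualize_expression(fx$norm_X, meta1,
                                               min_nuclei = 5),
                 "collinear")
  expect_lt(max(abs(crossprod(attr(res, "design"), res))), 1e-8)
})

test_that("BH adjustment matches the hand example and a step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(19)
  for (rep in 1:10) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
  # q values reported by the fitter are BH over all gene x protein tests
  fx <- make_assoc_fixture()
  res <- residualize_expression(fx$norm_X, fx$meta, min_nuclei = 5)
  fit <- fit_protein_associations(res, fx$nclr)
  expect_equal(fit$table$q_value, bh_oracle(fit$table$p_value))
  expect_true(all(fit$table$q_value >= fit$table$p_value))
})

test_that("two-step coefficients equal the joint regression (FWL)", {
  fx <- make_assoc_fixture(n = 200)
  res <- residualize_expression(fx$norm_X, fx$meta, min_nuclei = 5)
  fit <- fit_protein_associations(res, fx$nclr, residualize_protein = TRUE)
  D <- attr(res, "design")
  for (gene in colnames(res)[c(1, 5, 9)]) {
    y <- as.matrix(fx$norm_X)[, gene]
    joint <- lm(y ~ D - 1 + fx$nclr)
    jc <- coef(joint)
    for (p in colnames(fx$nclr)) {
      got <- fit$table$coefficient[fit$table$gene == gene &
                                     fit$table$protein == p]
      expect_equal(got, unname(jc[paste0("fx$nclr", p)]), tolerance = 1e-8)
      # matching t statistics too, given the two-stage degrees of freedom
      jt <- summary(joint)$coefficients[paste0("fx$nclr", p), "t value"]
      gt <- fit$table$t_stat[fit$table$gene == gene &
                               fit$table$protein == p]
      expect_equal(gt, unname(jt), tolerance = 1e-6)
    }
  }
})

test_that("coefficients are invariant to constant shifts of a protein", {
  fx <- make_assoc_fixture()
  res <- residualize_expression(fx$norm_X, fx$meta, min_nuclei = 5)
  f1 <- fit_protein_associations(res, fx$nclr)
  shifted <- fx$nclr
  shifted[, "TDP-43"] <- shifted[, "TDP-43"] + 5
  f2 <- fit_protein_associations(res, shifted)
  expect_equal(f1$table$coefficient, f2$table$coefficient, tolerance = 1e-10)
  # constant protein column errors
  cst <- fx$nclr; cst[, "p65"] <- 2
  expect_error(fit_protein_associations(res, cst,
                                        residualize_protein = FALSE),
               "constant")
  # single mode returns one row per gene per protein as well
  fs <- fit_protein_associations(res, fx$nclr, mode = "single")
  expect_equal(nrow(fs$table), nrow(f1$table))
  expect_equal(dim(coef(f1)), c(ncol(res), 2))
})

test_that("Fisher overlap enrichment reproduces the cross-product table", {
  universe <- paste0("g", 1:30)
  assoc <- paste0("g", 1:15)
  target <- paste0("g", c(1:10, 16:20))
  out <- overlap_enrichment(assoc, target, universe)
  expect_equal(unname(as.vector(t(out$table))), c(10, 5, 5, 10))
  expect_equal(out$odds_ratio, 4.0)
  # p equals exhaustive hypergeometric enumeration of tables at fixed
  # margins (two-sided by point-probability rule)
  hyper_p <- function(a, m_assoc, m_target, N) {
    av <- max(0, m_assoc + m_target - N):min(m_assoc, m_target)
    pr <- dhyper(av, m_target, N - m_target, m_assoc)
    sum(pr[pr <= dhyper(a, m_target, N - m_target, m_assoc) * (1 + 1e-7)])
  }
  expect_equal(out$p_value, hyper_p(10, 15, 15, 30), tolerance = 1e-12)
  # zero overlap with nonzero margins: odds ratio 0, exact p
  out0 <- overlap_enrichment(paste0("g", 1:5), paste0("g", 6:10), universe)
  expect_equal(out0$odds_ratio, 0)
  expect_equal(out0$p_value, hyper_p(0, 5, 5, 30), tolerance = 1e-12)
  # perfect overlap of half the universe
  outp <- overlap_enrichment(paste0("g", 1:15), paste0("g", 1:15), universe)
  expect_equal(outp$p_value, hyper_p(15, 15, 15, 30), tolerance = 1e-12)
  expect_error(overlap_enrichment(assoc, target, character()), "empty")
})

test_that("percentage overlap follows intersection over union", {
  expect_equal(gene_set_overlap_pct(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_equal(gene_set_overlap_pct(c("a", "b"), c("a", "b")), 100)
  expect_equal(gene_set_overlap_pct(c("a"), c("b")), 0)
  expect_error(gene_set_overlap_pct(character(), character()), "empty")
})

test_that("the dataset-level wrapper runs the whole two-step model", {
  sim <- small_sim(seed = 51)
  ds <- qc_filter(sim$dataset)$dataset
  fit <- protein_assoc(ds, min_nuclei = 10)
  expect_s3_class(fit, "protein_assoc")
  expect_setequal(fit$proteins, setdiff(colnames(ds$A), "H3"))
  s <- summary(fit)
  expect_setequal(s$protein, fit$proteins)
  expect_output(print(fit), "protein_assoc")
  sg <- significant_genes(fit, "TDP-43", "positive")
  expect_true(all(sg %in% fit$table$gene))
})
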