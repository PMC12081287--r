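test_that("QC removes nuclei exactly at the documented thresholds", {
  out <- qc_filter(qc_boundary_dataset())
  kept <- rownames(out$dataset$X)
  expect_false("genes49" %in% kept)   # 49 genes: removed
  expect_true("genes50" %in% kept)    # 50 genes: kept
  expect_false("mito6pct" %in% kept)  # 6% mitochondrial: removed
  expect_true("mito4pct" %in% kept)
  expect_false("hash4001" %in% kept)  # hashtag 4,001: removed
  expect_true("hash4000" %in% kept)
  expect_false("tdp3001" %in% kept)   # TDP-43 antibody 3,001: removed
  expect_true("tdp3000" %in% kept)
  rep <- out$report
  expect_equal(rep$n_removed[rep$rule == "min_genes_per_nucleus"], 1)
  expect_equal(rep$n_removed[rep$rule == "max_hashtag_counts"], 1)
  expect_equal(rep$n_removed[rep$rule == "max_tdp43_ab_counts"], 1)
})

test_that("genes detected in too few nuclei are dropped; QC is idempotent", {
  ds <- tiny_dataset(n = 20, g = 10)
  X <- as.matrix(ds$X)
  X[, "G001"] <- 0
  X[1:4, "G001"] <- 5    # detected in 4 < 5 nuclei
  X[1:5, "G002"] <- 5    # G002 detected everywhere anyway
  ds <- nucleus_dataset(Matrix::Matrix(X, sparse = TRUE), ds$A, ds$meta)
  thr <- qc_thresholds(min_genes_per_nucleus = 3)
  out <- qc_filter(ds, thr)
  expect_false("G001" %in% colnames(out$dataset$X))

  sim <- small_sim(seed = 41)
  once <- qc_filter(sim$dataset)
  twice <- qc_filter(once$dataset)
  expect_equal(dim(twice$dataset$X), dim(once$dataset$X))
  expect_equal(sum(twice$report$n_removed), 0)

  empty <- tiny_dataset(n = 6, g = 8)
  expect_error(qc_filter(empty, qc_thresholds(min_genes_per_nucleus = 100)),
               "per-rule|removed all")
})

test_that("normalization hits the target sum, preserves zeros, ignores depth", {
  X <- Matrix::Matrix(matrix(c(10, 30, 0, 5, 10, 25), 3, 2, byrow = FALSE),
                      sparse = TRUE)
  rownames(X) <- c("n1", "n2", "n3"); colnames(X) <- c("g1", "g2")
  # nucleus with depth equal to the target: values pass through the log
  X1 <- Matrix::Matrix(matrix(c(10, 30), 1, 2), sparse = TRUE)
  out1 <- normalize_expression(X1, target_sum = 40)
  expect_equal(as.numeric(out1), c(log(11), log(31)))
  # zeros stay zero; pre-log sums equal the target
  out <- normalize_expression(X, target_sum = 100)
  expect_equal(as.matrix(out) == 0, as.matrix(X) == 0)
  expect_equal(unname(rowSums(expm1(as.matrix(out)))), rep(100, 3))
  # doubling a nucleus's depth leaves its normalized vector unchanged
  out2 <- normalize_expression(2 * X, target_sum = 100)
  expect_equal(as.matrix(out2), as.matrix(out))
  X0 <- X; X0[2, ] <- 0
  expect_error(normalize_expression(X0), "zero total")
})

test_that("variable-gene selection applies mean window and dispersion cut", {
  set.seed(12)
  n <- 400
  # Poisson genes with means inside the window; one overdispersed gene;
  # one constant gene; one high-mean gene
  lam <- runif(40, 0.05, 0.6)
  X <- sapply(lam, function(l) rpois(n, l))
  od <- rnbinom(n, mu = 0.3, size = 0.1)      # planted high dispersion
  hi <- rpois(n, 60)                          # mean far above max_mean
  cst <- rep(1, n)
  M <- cbind(X, od = od, hi = hi, cst = cst)
  colnames(M) <- c(sprintf("g%02d", seq_along(lam)), "od", "hi", "cst")
  rownames(M) <- paste0("n", 1:n)
  # ln(x+1) values directly: the back-transformed per-gene means then equal
  # the raw count means, which the window bounds refer to
  norm_X <- Matrix::Matrix(log1p(M), sparse = TRUE)
  hv <- select_variable_genes(norm_X, hvg_params(max_mean = 50))
  st <- attr(hv, "stats")
  expect_false("cst" %in% hv)                  # zero variance
  expect_false("hi" %in% hv)                   # mean above max_mean
  expect_true("od" %in% hv)                    # planted dispersion
  # agree with a direct dispersion computation on the same scale
  E <- expm1(as.matrix(norm_X))
  expect_equal(st$dispersion[st$gene == "od"],
               var(E[, "od"]) / mean(E[, "od"]))
  # selection is independent of gene ordering
  perm <- sample(ncol(norm_X))
  hv2 <- select_variable_genes(norm_X[, perm], hvg_params(max_mean = 50))
  expect_setequal(hv, hv2)
  expect_error(select_variable_genes(norm_X,
                                     hvg_params(min_mean = 100,
                                                max_mean = 101)),
               "fewer than 2")
})

test_that("clustering separates well-separated blobs into pure clusters", {
  set.seed(13)
  n <- 300
  g <- 20
  blob <- rbind(matrix(rnorm(n * g), n, g),
                matrix(rnorm(n * g, mean = 10), n, g))
  dimnames(blob) <- list(paste0("c", 1:(2 * n)), paste0("g", 1:g))
  truthv <- rep(1:2, each = n)
  ec <- embed_and_cluster(blob, n_pcs = 10, k = 10, resolution = 0.8)
  # every Leiden community is fully contained in one blob (the algorithm
  # may legitimately subdivide a dense blob), so majority-mapped agreement
  # is >= 99%
  tab <- table(ec$clusters, truthv)
  agreement <- sum(apply(tab, 1, max)) / (2 * n)
  expect_gte(agreement, 0.99)
  # the two blobs are never merged into one community
  expect_true(all(rowSums(tab > 0) == 1))
  # duplicated nuclei land in the same community
  dup <- blob[c(1, 1, 1, 2:50), ]
  rownames(dup) <- paste0("d", seq_len(nrow(dup)))
  ecd <- embed_and_cluster(dup, n_pcs = 5, k = 3, resolution = 0.8)
  expect_equal(ecd$clusters[[1]], ecd$clusters[[2]])
  expect_equal(ecd$clusters[[1]], ecd$clusters[[3]])
  expect_warning(embed_and_cluster(blob[1:30, ], n_pcs = 40, k = 5),
                 "clamped")
  expect_error(embed_and_cluster(blob[1:10, ], k = 10), "smaller")
})
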