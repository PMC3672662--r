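# Moderated t, filters and z-scoring.

test_that("zscore_rows standardizes every row", {
  expect_equal(unname(zscore_rows(rbind(a = c(1, 2, 3)))[1, ]), c(-1, 0, 1))
  set.seed(5)
  m <- matrix(rnorm(50 * 8, sd = runif(50, 0.1, 4)), 50, 8,
              dimnames = list(paste0("g", 1:50), NULL))
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
})

test_that("constant rows z-score to zero with a warning", {
  m <- rbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(unname(z["a", ]), c(0, 0, 0))
})

test_that("moderated t with prior_df = 0 equals the ordinary pooled t", {
  sim <- simulate_expression_dataset(simulation_config(seed = 2, n_genes = 100))
  de <- moderated_t(sim$dataset, prior_df = 0)
  x <- sim$dataset$expr
  cond <- sim$dataset$condition
  for (i in c(1, 17, 50, 100)) {
    tt <- t.test(x[i, cond == "parous"], x[i, cond == "virgin"],
                 var.equal = TRUE)
    expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t with infinite prior pools all variances", {
  sim <- simulate_expression_dataset(simulation_config(seed = 3, n_genes = 200))
  de <- moderated_t(sim$dataset, prior_df = Inf)
  expect_true(attr(de, "fully_pooled"))
  # with one shared variance, |t| ordering equals |log2 fc| ordering
  expect_identical(order(-abs(de$t_mod)), order(-abs(de$log2_fc)))
})

test_that("moderated t matches a direct-formula oracle", {
  sim <- simulate_expression_dataset(simulation_config(seed = 4, n_genes = 200))
  de <- moderated_t(sim$dataset)
  x <- sim$dataset$expr
  cond <- sim$dataset$condition
  a <- x[, cond == "virgin"]; b <- x[, cond == "parous"]
  na <- ncol(a); nb <- ncol(b); dfr <- na + nb - 2
  s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / dfr
  d0 <- attr(de, "prior_df"); s0 <- attr(de, "prior_var")
  t_oracle <- (rowMeans(b) - rowMeans(a)) /
    sqrt(((d0 * s0 + dfr * s2) / (d0 + dfr)) * (1 / na + 1 / nb))
  expect_equal(de$t_mod, unname(t_oracle), tolerance = 1e-10)
})

test_that("moderated t agrees with limma on the same contrast", {
  sim <- simulate_expression_dataset(simulation_config(seed = 6, n_genes = 500))
  de <- moderated_t(sim$dataset)
  design <- model.matrix(~ sim$dataset$condition)
  fit <- limma::eBayes(limma::lmFit(sim$dataset$expr, design))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 0.05)
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("variance prior recovery matches the generative parameters", {
  cfg <- simulation_config(seed = 10, n_genes = 8000,
                           n_samples_per_condition = 4,
                           variance_prior_df = 5, variance_prior_scale = 0.08,
                           de_fraction = 0)
  de <- moderated_t(simulate_expression_dataset(cfg)$dataset)
  expect_equal(attr(de, "prior_df"), 5, tolerance = 0.25)
  expect_equal(attr(de, "prior_var"), 0.08, tolerance = 0.1)
})

test_that("BH adjustment is the standard step-up transform", {
  sim <- simulate_expression_dataset(simulation_config(seed = 7, n_genes = 300))
  de <- moderated_t(sim$dataset)
  expect_equal(de$p_adj, p.adjust(de$p, "BH"))
  expect_true(all(de$p_adj >= de$p))
  # permuting gene order leaves every adjusted p unchanged
  perm <- sample(nrow(sim$dataset$expr))
  de2 <- moderated_t(expression_dataset(sim$dataset$expr[perm, ],
                                        sim$dataset$condition))
  expect_equal(de2$p_adj[match(de$gene, de2$gene)], de$p_adj)
})

test_that("filters retain exactly the genes passing all three rules", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2_fc = log2(c(1.6, 1.4, 3, 2)),
                    ave_linear_expr = c(5, 10, 2, 8),
                    t_mod = 1, df_total = 4,
                    p = c(0.001, 0.0001, 0.001, 0.2),
                    p_adj = c(0.01, 0.001, 0.01, 0.4))
  class(res) <- c("de_result", "data.frame")
  kept <- apply_filters(res, filter_criteria(1.5, 0.05, 4))
  expect_identical(kept$gene, "a")  # b fails FC, c fails ave, d fails p_adj
  # downregulation passes through the absolute fold change
  res$log2_fc[1] <- -log2(1.6)
  expect_identical(apply_filters(res, filter_criteria(1.5, 0.05, 4))$gene, "a")
})

test_that("top_genes ranks by absolute fold change within strict criteria", {
  sim <- simulate_expression_dataset(
    simulation_config(seed = 12, n_genes = 500, de_fraction = 0.02,
                      de_log2_effect = 1.2))
  x <- sim$dataset$expr
  # plant one 16-fold gene on top of the simulated background
  x["gene_00001", sim$dataset$condition == "parous"] <-
    x["gene_00001", sim$dataset$condition == "virgin"] + 4
  de <- moderated_t(expression_dataset(x, sim$dataset$condition))
  top <- top_genes(de, n = 5)
  expect_identical(top$up$gene[1], "gene_00001")
  # empty result gives empty lists
  empty <- de[0, ]
  class(empty) <- c("de_result", "data.frame")
  expect_identical(nrow(top_genes(empty)$up), 0L)
})

test_that("expression TSV round-trips", {
  sim <- simulate_expression_dataset(simulation_config(seed = 18, n_genes = 40))
  tmp <- tempfile(fileext = ".tsv")
  write_expression_tsv(sim$dataset$expr, tmp)
  back <- read_expression_tsv(tmp)
  expect_equal(back, sim$dataset$expr, tolerance = 1e-10)
})
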