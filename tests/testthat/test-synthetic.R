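# Seeded generators: determinism, moment recovery, truth-record structure.

test_that("zero frequency forces all-negative outcomes", {
  a <- simulate_dilution_assay(0, std_doses, std_n, seed = 1)
  expect_true(all(a$n_positive == 0))
})

test_that("simulated positivity matches the single-hit closed form", {
  # dose 1000 at f = 1/500: P(pos) = 1 - exp(-2)
  a <- simulate_dilution_assay(1 / 500, 1000, 20000, seed = 3)
  p_true <- -expm1(-2)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(a$n_positive / 20000 - p_true), 3 * se)
})

test_that("generators are byte-identical under the same seed", {
  cfg <- simulation_config(seed = 9, n_genes = 300, n_motifs = 10,
                           image_size = c(32, 32))
  expect_identical(simulate_dilution_assay(1 / 500, std_doses, std_n, seed = 5),
                   simulate_dilution_assay(1 / 500, std_doses, std_n, seed = 5))
  expect_identical(simulate_expression_dataset(cfg),
                   simulate_expression_dataset(cfg))
  expect_identical(simulate_motif_dataset(cfg), simulate_motif_dataset(cfg))
  expect_identical(simulate_ihc_image(cfg), simulate_ihc_image(cfg))
})

test_that("generator substreams are independent of one another", {
  cfg <- simulation_config(seed = 9, n_genes = 100, n_motifs = 5)
  e1 <- simulate_expression_dataset(cfg)
  invisible(simulate_motif_dataset(cfg))  # interleaved call, other stream
  e2 <- simulate_expression_dataset(cfg)
  expect_identical(e1, e2)
})

test_that("planted genes shift by the configured log2 effect", {
  cfg <- simulation_config(seed = 21, n_genes = 4000, de_fraction = 0.1,
                           de_log2_effect = 1.5, n_samples_per_condition = 10)
  sim <- simulate_expression_dataset(cfg)
  x <- sim$dataset$expr
  cond <- sim$dataset$condition
  diff <- rowMeans(x[, cond == "parous"]) - rowMeans(x[, cond == "virgin"])
  planted <- sim$truth
  expect_gt(nrow(planted), 0)
  obs <- diff[planted$gene] * planted$sign
  expect_lt(abs(mean(obs) - 1.5), 3 * sd(obs) / sqrt(length(obs)))
  # non-planted genes centered at zero
  null_diff <- diff[setdiff(rownames(x), planted$gene)]
  expect_lt(abs(mean(null_diff)), 3 * sd(null_diff) / sqrt(length(null_diff)))
})

test_that("gene variances follow the scaled inverse-chi-square prior", {
  cfg <- simulation_config(seed = 33, n_genes = 20000,
                           variance_prior_df = 6, variance_prior_scale = 0.1)
  sim <- simulate_expression_dataset(cfg)
  v <- attr(sim$truth, "gene_variances")
  # mean of scaled-inv-chi2(df, s2) is df*s2/(df-2)
  expect_equal(mean(v), 6 * 0.1 / 4, tolerance = 0.05)
})

test_that("too small a DE fraction warns and plants nothing", {
  cfg <- simulation_config(seed = 2, n_genes = 10, de_fraction = 0.05)
  expect_warning(sim <- simulate_expression_dataset(cfg), "no genes planted")
  expect_identical(nrow(sim$truth), 0L)
})

test_that("motif dataset obeys E = N A + baseline + noise structure", {
  cfg <- simulation_config(seed = 13, n_genes = 800, n_motifs = 10,
                           expression_noise_sd = 1e-8)
  sim <- simulate_motif_dataset(cfg)
  e <- sim$dataset$expr
  recon <- sim$sites %*% sim$truth$activities
  # after removing the per-gene baseline, expression is exactly N A
  resid <- sweep(e - recon, 1, rowMeans(e - recon))
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("planted motif shifts are recorded with their signs", {
  cfg <- simulation_config(seed = 14, n_genes = 500, n_motifs = 8)
  sim <- simulate_motif_dataset(cfg, c(motif_002 = -1.0, motif_005 = 0.5))
  expect_identical(unname(sim$truth$shifts["motif_002"]), -1.0)
  expect_identical(unname(sim$truth$shifts["motif_005"]), 0.5)
  expect_true(all(sim$truth$shifts[c("motif_001", "motif_003")] == 0))
  expect_error(simulate_motif_dataset(cfg, c(bogus = 1)), "unknown motif")
})

test_that("all-zero site columns are flagged in the truth record", {
  cfg <- simulation_config(seed = 15, n_genes = 50, n_motifs = 6,
                           motif_site_rate = 0.01)
  sim <- simulate_motif_dataset(cfg)
  expect_identical(sim$truth$zero_site_motifs,
                   colnames(sim$sites)[colSums(sim$sites) == 0])
})

test_that("ihc image has exactly the configured positive-pixel count", {
  cfg <- simulation_config(seed = 8, image_size = c(40, 50),
                           positive_fraction = 0.3)
  sim <- simulate_ihc_image(cfg)
  expect_identical(sum(sim$mask), as.integer(floor(0.3 * 40 * 50)))
  expect_identical(dim(sim$image), c(40L, 50L, 3L))
  zero <- simulate_ihc_image(simulation_config(seed = 8, image_size = c(10, 10),
                                               positive_fraction = 0))
  expect_false(any(zero$mask))
})

test_that("ihc simulation validates its color inputs", {
  cfg <- simulation_config(seed = 8, image_size = c(10, 10))
  expect_error(simulate_ihc_image(cfg, positive_color_mean = c(300, 0, 0)),
               "\\[0, 255\\]")
  bad_cov <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(simulate_ihc_image(cfg, color_cov = bad_cov),
               "positive-definite")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0))
  expect_error(simulation_config(de_fraction = 1.5))
  expect_error(simulation_config(variance_prior_scale = -1))
})

test_that("png round trip preserves the image", {
  cfg <- simulation_config(seed = 77, image_size = c(16, 16))
  sim <- simulate_ihc_image(cfg)
  tmp <- tempfile(fileext = ".png")
  write_rgb_png(sim$image, tmp)
  back <- read_rgb_png(tmp)
  expect_equal(back, sim$image, tolerance = 0.51)  # 8-bit quantization
})
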