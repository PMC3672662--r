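# Single-hit Poisson limiting-dilution inference.

test_that("single dose group recovers the closed-form frequency", {
  # one group: f = -log(1 - r/n) / d
  a <- dilution_assay(100, 10, 5)
  fit <- fit_single_hit(a)
  expect_equal(fit$f_hat, log(2) / 100, tolerance = 1e-6)
})

test_that("MLE matches the independent grid-search oracle on random tables", {
  set.seed(42)
  for (i in 1:30) {
    a <- random_assay()
    fit <- fit_single_hit(a)
    phi_grid <- grid_search_logf(a$dose, a$n_injected, a$n_positive)
    expect_lt(abs(log(fit$f_hat) - phi_grid), 1e-6)
  }
})

test_that("MLE agrees with complementary log-log binomial regression", {
  # glm with cloglog link and offset log(dose) is the standard equivalent
  # formulation: P(pos) = 1 - exp(-exp(log f + log d)).
  tabs <- parity_transplant_tables()
  for (g in names(tabs)) {
    a <- tabs[[g]]
    fit <- fit_single_hit(a)
    gfit <- suppressWarnings(stats::glm(
      cbind(n_positive, n_injected - n_positive) ~ 1 + offset(log(dose)),
      family = stats::binomial(link = "cloglog"), data = a))
    expect_equal(log(fit$f_hat), unname(stats::coef(gfit)), tolerance = 1e-5)
    # observed vs expected information: a few percent apart at these counts
    expect_equal(fit$log_f_se,
                 unname(sqrt(stats::vcov(gfit)[1, 1])), tolerance = 0.05)
  }
})

test_that("dose rescaling divides the frequency exactly", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_assay()
    f1 <- fit_single_hit(a)$f_hat
    b <- dilution_assay(a$dose * 10, a$n_injected, a$n_positive)
    expect_equal(fit_single_hit(b)$f_hat, f1 / 10, tolerance = 1e-6)
  }
})

test_that("increasing positives never decreases the frequency estimate", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_assay()
    f1 <- fit_single_hit(a)$f_hat
    bump <- which(a$n_positive < a$n_injected)
    if (!length(bump)) next
    j <- bump[sample.int(length(bump), 1)]
    r2 <- a$n_positive
    r2[j] <- r2[j] + 1L
    if (all(r2 == a$n_injected)) next
    b <- dilution_assay(a$dose, a$n_injected, r2)
    expect_gte(fit_single_hit(b)$f_hat, f1 - 1e-12)
  }
})

test_that("boundary tables are flagged rather than fitted", {
  zero <- make_assay(c(0, 0, 0, 0, 0))
  fit0 <- fit_single_hit(zero)
  expect_identical(fit0$boundary, "zero")
  expect_identical(fit0$f_hat, 0)
  full <- make_assay(std_n)
  expect_identical(fit_single_hit(full)$boundary, "infinite")
})

test_that("profile-likelihood interval contains the MLE and differs from Wald", {
  a <- make_assay(c(8, 8, 2, 0, 0))
  wald <- fit_single_hit(a, ci = "wald")
  prof <- fit_single_hit(a, ci = "profile")
  expect_lt(prof$ci_low, prof$f_hat)
  expect_gt(prof$ci_high, prof$f_hat)
  # same order of magnitude but a genuinely different construction
  expect_false(isTRUE(all.equal(prof$ci_low, wald$ci_low, tolerance = 1e-8)))
})

test_that("identical groups give chi2 = 0 and p = 1", {
  a <- make_assay(c(8, 8, 2, 0, 0))
  cmp <- compare_frequencies(a, a)
  expect_equal(cmp$chi2, 0, tolerance = 1e-6)
  expect_equal(cmp$p_value, 1, tolerance = 1e-4)
})

test_that("comparison p decreases as tables diverge", {
  a <- make_assay(c(8, 8, 2, 0, 0))
  near <- make_assay(c(7, 8, 2, 0, 0))
  far <- make_assay(c(2, 1, 0, 0, 0))
  expect_gt(compare_frequencies(a, near)$p_value,
            compare_frequencies(a, far)$p_value)
})

test_that("goodness-of-fit p is roughly uniform under the single-hit model", {
  ps <- vapply(1:300, function(i) {
    a <- simulate_dilution_assay(1 / 400, std_doses, std_n * 3, seed = i)
    fit <- fit_single_hit(a)
    if (fit$boundary != "none") return(NA_real_)
    goodness_of_fit(a, fit)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  # discrete data make the deviance only approximately chi-square; check the
  # gross shape: sub-uniform tail mass at both ends
  expect_gt(mean(ps > 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("goodness of fit detects non-single-hit dose response", {
  # two-hit-shaped data: positivity rises much more steeply with dose than
  # the single-hit model allows
  set.seed(99)
  rejected <- 0
  for (i in 1:40) {
    p2 <- 1 - exp(-(std_doses / 450)^2)  # quadratic in dose
    r <- rbinom(5, std_n * 3, p2)
    if (all(r == 0) || all(r == std_n * 3)) next
    a <- dilution_assay(std_doses, std_n * 3, r)
    gof <- goodness_of_fit(a)
    if (gof$p_value < 0.05) rejected <- rejected + 1
  }
  expect_gt(rejected, 20)
})

test_that("goodness of fit requires at least two dose groups", {
  expect_error(goodness_of_fit(dilution_assay(100, 10, 5)), "two dose groups")
})

test_that("outgrowth classification counts fill fractions at threshold", {
  expect_identical(classify_outgrowths(c(0.02, 0.05, 0.30), 0.03), 2L)
  expect_identical(classify_outgrowths(c(0.02, 0.05, 0.30), 0.10), 1L)
  expect_identical(classify_outgrowths(numeric(0), 0.25), 0L)
  expect_error(classify_outgrowths(c(0.5, 1.2), 0.1), "\\[0, 1\\]")
})

test_that("assay construction rejects invalid tables", {
  expect_error(dilution_assay(c(100, 100), c(5, 5), c(1, 1)), "unique")
  expect_error(dilution_assay(c(-10, 50), c(5, 5), c(1, 1)), "positive")
  expect_error(dilution_assay(100, 5, 6), "n_positive")
})

test_that("dilution CSV round-trips through read_dilution_csv", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(group = rep(c("a", "b"), each = 2),
                   dose = c(100, 50, 100, 50),
                   n_injected = c(6, 6, 6, 6), n_positive = c(3, 1, 5, 2))
  write.csv(df, tmp, row.names = FALSE)
  tabs <- read_dilution_csv(tmp)
  expect_named(tabs, c("a", "b"))
  expect_equal(tabs$a$n_positive, c(3L, 1L))
})
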