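# Single-hit Poisson limiting-dilution analysis of mammary repopulating
# frequency from cleared-fat-pad transplantation dose-response tables.
#
# Model: a graft is negative iff it receives zero repopulating cells, so
# P(negative | dose d) = exp(-f * d) where f is the repopulating-unit
# frequency (units: repopulating units per injected cell). The number of
# positive outgrowths r_i among n_i injections at dose d_i is binomial with
# success probability 1 - exp(-f * d_i).

#' Construct a limiting-dilution assay table
#'
#' Bundles the dose-response rows of a single transplantation group: for each
#' cell dose, the number of injections performed and the number that produced
#' a positive outgrowth.
#'
#' @param dose numeric vector of cells injected per cleared fat pad; all > 0.
#' @param n_injected integer vector, number of injections per dose group.
#' @param n_positive integer vector, number of positive outgrowths
#'   (`0 <= n_positive <= n_injected`).
#' @param group optional single character label for the donor group.
#' @return A `dilution_assay`: a data frame with columns `dose`, `n_injected`,
#'   `n_positive` and attribute `group`.
#' @examples
#' dilution_assay(c(1000, 500, 250, 100, 50), c(9, 11, 6, 6, 7),
#'                c(8, 8, 2, 0, 0), group = "virgin")
#' @export
dilution_assay <- function(dose, n_injected, n_positive, group = "group") {
  stopifnot(length(dose) >= 1L,
            length(dose) == length(n_injected),
            length(dose) == length(n_positive))
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("all doses must be positive and finite")
  }
  if (any(n_injected < 1) || any(n_positive < 0) || any(n_positive > n_injected)) {
    stop("need 0 <= n_positive <= n_injected with n_injected >= 1")
  }
  if (anyDuplicated(dose)) stop("dose groups must be unique within an assay")
  out <- data.frame(dose = as.numeric(dose),
                    n_injected = as.integer(n_injected),
                    n_positive = as.integer(n_positive))
  out <- out[order(-out$dose), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group") <- as.character(group)[1L]
  class(out) <- c("dilution_assay", "data.frame")
  out
}

#' @export
print.dilution_assay <- function(x, ...) {
  cat("Limiting-dilution assay:", attr(x, "group"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

## Log-likelihood of the single-hit model at log-frequency phi = log(f).
single_hit_loglik <- function(phi, dose, n, r) {
  a <- exp(phi) * dose
  # log(1 - exp(-a)) computed stably for small a
  lp <- ifelse(a < 1e-8, log(a) + log1p(-a / 2), log1p(-exp(-a)))
  sum(r * lp - (n - r) * a)
}

## Score (d loglik / d phi) at phi = log f; a * e^-a / (1 - e^-a) -> 1 as
## a -> 0, handled explicitly for numerical safety.
single_hit_score <- function(phi, dose, n, r) {
  a <- exp(phi) * dose
  hit <- ifelse(a < 1e-10, 1 - a / 2, a * exp(-a) / (1 - exp(-a)))
  sum(r * hit - (n - r) * a)
}

## Maximize the single-hit log-likelihood over phi = log f. The likelihood
## is unimodal in phi; golden-section search brackets the maximum and a few
## Newton steps on the score polish it to machine precision.
single_hit_mle <- function(dose, n, r, interval = c(-30, 5)) {
  opt <- stats::optimize(single_hit_loglik, interval = interval,
                         dose = dose, n = n, r = r,
                         maximum = TRUE, tol = 1e-10)
  phi <- opt$maximum
  if (phi < interval[1] + 0.5 || phi > interval[2] - 0.5) {
    stop("single-hit MLE did not converge inside the search interval; ",
         "log f at boundary ", format(phi))
  }
  h <- 1e-6
  for (it in 1:50) {
    g <- single_hit_score(phi, dose, n, r)
    curv <- (single_hit_score(phi + h, dose, n, r) -
             single_hit_score(phi - h, dose, n, r)) / (2 * h)
    if (!is.finite(curv) || curv >= 0) break
    step <- g / curv
    phi <- phi - step
    if (abs(step) < 1e-13) break
  }
  list(maximum = phi, objective = single_hit_loglik(phi, dose, n, r))
}

#' Fit the single-hit Poisson model to a limiting-dilution assay
#'
#' Maximum-likelihood estimation of the repopulating-unit frequency `f` under
#' the single-hit model `P(negative | dose d) = exp(-f d)`, with a Wald 95%
#' confidence interval on the natural-log scale (the construction used by
#' standard limiting-dilution software). A profile-likelihood interval is
#' available via `ci = "profile"`.
#'
#' All-negative tables are flagged `boundary = "zero"` (the MLE is f = 0) and
#' all-positive tables `boundary = "infinite"`; in either case no finite
#' interval exists and `f_hat`/`ci` are reported as the boundary values.
#'
#' @param assay a [dilution_assay()].
#' @param conf_level confidence level for the interval (default 0.95).
#' @param ci `"wald"` (default) for a normal interval on log f, or
#'   `"profile"` for a likelihood-ratio-inverted interval.
#' @return A `frequency_estimate` list: `f_hat`, `denominator`
#'   (`round(1/f_hat)`, the "1 repopulating unit per N cells" display form),
#'   `log_f_se`, `ci_low`, `ci_high` (frequency scale), `ci_denominator`
#'   (denominators of the interval, upper bound first as conventionally
#'   printed), `log_likelihood`, `boundary` and the input `assay`.
#' @examples
#' a <- dilution_assay(c(1000, 500, 250, 100, 50), c(9, 11, 6, 6, 7),
#'                     c(8, 8, 2, 0, 0), group = "virgin")
#' fit_single_hit(a)
#' @seealso [compare_frequencies()], [goodness_of_fit()]
#' @export
fit_single_hit <- function(assay, conf_level = 0.95, ci = c("wald", "profile")) {
  stopifnot(inherits(assay, "dilution_assay"))
  ci <- match.arg(ci)
  d <- assay$dose; n <- assay$n_injected; r <- assay$n_positive

  boundary <- "none"
  if (all(r == 0)) boundary <- "zero"
  if (all(r == n)) boundary <- "infinite"
  if (boundary != "none") {
    est <- list(f_hat = if (boundary == "zero") 0 else Inf,
                denominator = if (boundary == "zero") Inf else 0,
                log_f_se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ci_denominator = c(NA_real_, NA_real_),
                log_likelihood = 0, boundary = boundary,
                conf_level = conf_level, assay = assay)
    class(est) <- "frequency_estimate"
    return(est)
  }

  opt <- single_hit_mle(d, n, r)
  phi <- opt$maximum
  ll <- opt$objective

  # observed information on the log-frequency scale by central difference
  h <- 1e-5
  info <- -(single_hit_loglik(phi + h, d, n, r) -
            2 * ll +
            single_hit_loglik(phi - h, d, n, r)) / h^2
  se <- sqrt(1 / info)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (ci == "wald") {
    lo <- exp(phi - zq * se)
    hi <- exp(phi + zq * se)
  } else {
    # invert the likelihood-ratio test: phi with 2*(ll_max - ll) <= chi2_1
    crit <- stats::qchisq(conf_level, df = 1) / 2
    drop_fun <- function(p) ll - single_hit_loglik(p, d, n, r) - crit
    lo <- exp(stats::uniroot(drop_fun, c(phi - 20, phi), tol = 1e-10)$root)
    hi_root <- tryCatch(
      stats::uniroot(drop_fun, c(phi, phi + 20), tol = 1e-10)$root,
      error = function(e) Inf)
    hi <- exp(hi_root)
  }

  est <- list(f_hat = exp(phi),
              denominator = round(1 / exp(phi)),
              log_f_se = se,
              ci_low = lo, ci_high = hi,
              ci_denominator = c(round(1 / lo), round(1 / hi)),
              log_likelihood = ll,
              boundary = "none",
              conf_level = conf_level,
              assay = assay)
  class(est) <- "frequency_estimate"
  est
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat("Single-hit repopulating frequency:", attr(x$assay, "group"), "\n")
  if (x$boundary != "none") {
    cat("  boundary table (", x$boundary, "): f_hat = ", x$f_hat, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  1/%d  (%.0f%% CI 1/%d - 1/%d)\n",
              x$denominator, 100 * x$conf_level,
              x$ci_denominator[1], x$ci_denominator[2]))
  cat(sprintf("  f_hat = %.3e, SE(log f) = %.4f, logLik = %.3f\n",
              x$f_hat, x$log_f_se, x$log_likelihood))
  invisible(x)
}

#' Likelihood-ratio comparison of repopulating frequencies between two groups
#'
#' Tests whether two dose-response tables share a common repopulating
#' frequency: `chi2 = 2 (ll_a + ll_b - ll_pooled)` where the pooled
#' log-likelihood fits one frequency to the concatenated rows; p from a
#' chi-square distribution with 1 df.
#'
#' A group at the zero boundary (no positive outgrowths at all) contributes
#' its boundary log-likelihood of 0; the comparison is still defined as long
#' as the pooled table is non-boundary, and such cases are flagged.
#'
#' @param assay_a,assay_b [dilution_assay()] tables for the two groups.
#' @return A `frequency_comparison` list: `chi2`, `df` (1), `p_value`,
#'   per-group `frequency_estimate`s and a `boundary` flag.
#' @examples
#' va <- dilution_assay(c(1000, 500, 250, 100, 50), c(9, 11, 6, 6, 7),
#'                      c(8, 8, 2, 0, 0), "virgin")
#' pa <- dilution_assay(c(1000, 500, 250, 100, 50), c(9, 11, 6, 6, 7),
#'                      c(3, 2, 0, 0, 1), "parous")
#' compare_frequencies(va, pa)
#' @export
compare_frequencies <- function(assay_a, assay_b) {
  stopifnot(inherits(assay_a, "dilution_assay"), inherits(assay_b, "dilution_assay"))
  fa <- fit_single_hit(assay_a)
  fb <- fit_single_hit(assay_b)
  boundary <- fa$boundary != "none" || fb$boundary != "none"

  d <- c(assay_a$dose, assay_b$dose)
  n <- c(assay_a$n_injected, assay_b$n_injected)
  r <- c(assay_a$n_positive, assay_b$n_positive)
  if (all(r == 0) || all(r == n)) {
    stop("pooled table is at the likelihood boundary; frequencies cannot be compared")
  }
  ll_pooled <- single_hit_mle(d, n, r)$objective

  chi2 <- max(0, 2 * (fa$log_likelihood + fb$log_likelihood - ll_pooled))
  out <- list(chi2 = chi2, df = 1L,
              p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              fit_a = fa, fit_b = fb, boundary = boundary)
  class(out) <- "frequency_comparison"
  out
}

#' @export
print.frequency_comparison <- function(x, ...) {
  cat(sprintf("Frequency comparison (%s vs %s): chi2 = %.3f, df = 1, p = %.4g\n",
              attr(x$fit_a$assay, "group"), attr(x$fit_b$assay, "group"),
              x$chi2, x$p_value))
  if (x$boundary) cat("  note: a group was at the likelihood boundary\n")
  invisible(x)
}

#' Goodness of fit of the single-hit model
#'
#' Residual deviance of the fitted single-hit binomial model against the
#' saturated model (one free positivity probability per dose group), referred
#' to a chi-square distribution with (number of dose groups - 1) df. Small
#' p-values indicate departure from single-hit kinetics, e.g. multi-hit
#' behaviour or cell-dose-dependent take rates.
#'
#' @param assay a [dilution_assay()] with at least two dose groups.
#' @param estimate optional pre-computed [fit_single_hit()] result.
#' @return list with `deviance`, `df` and `p_value`.
#' @export
goodness_of_fit <- function(assay, estimate = NULL) {
  stopifnot(inherits(assay, "dilution_assay"))
  if (nrow(assay) < 2L) {
    stop("goodness of fit requires at least two dose groups")
  }
  if (is.null(estimate)) estimate <- fit_single_hit(assay)
  if (estimate$boundary != "none") {
    stop("goodness of fit undefined for a boundary table")
  }
  d <- assay$dose; n <- assay$n_injected; r <- assay$n_positive
  # saturated log-likelihood: p_i = r_i / n_i
  ll_sat <- sum(ifelse(r > 0, r * log(r / n), 0) +
                ifelse(r < n, (n - r) * log(1 - r / n), 0))
  dev <- max(0, 2 * (ll_sat - estimate$log_likelihood))
  df <- nrow(assay) - 1L
  list(deviance = dev, df = df,
       p_value = stats::pchisq(dev, df = df, lower.tail = FALSE))
}

#' Count positive outgrowths at a fill-fraction threshold
#'
#' Transplants are scored positive when the epithelial outgrowth fills at
#' least a given fraction of the cleared fat pad. Different thresholds define
#' different scoring stringencies: rudimentary outgrowths at 3%, large
#' outgrowths at 10% or 25%.
#'
#' @param fill_fractions numeric vector of fat-pad fill fractions in \[0, 1\].
#' @param threshold scoring threshold in (0, 1).
#' @return integer count of transplants scoring positive.
#' @examples
#' classify_outgrowths(c(0.02, 0.05, 0.30), 0.03)  # 2
#' classify_outgrowths(c(0.02, 0.05, 0.30), 0.10)  # 1
#' @export
classify_outgrowths <- function(fill_fractions, threshold) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  if (length(fill_fractions) == 0L) return(0L)
  if (any(fill_fractions < 0 | fill_fractions > 1)) {
    stop("fill fractions must lie in [0, 1]")
  }
  sum(fill_fractions >= threshold)
}

#' Read limiting-dilution assays from CSV
#'
#' Expects columns `group`, `dose`, `n_injected`, `n_positive` (header
#' required) and returns one [dilution_assay()] per group.
#'
#' @param path CSV file path.
#' @return named list of `dilution_assay` objects.
#' @export
read_dilution_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "dose", "n_injected", "n_positive")
  if (!all(need %in% names(tab))) {
    stop("dilution CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tab, tab$group), function(g) {
    dilution_assay(g$dose, g$n_injected, g$n_positive, group = g$group[1])
  })
  out[unique(tab$group)]
}

#' Packaged cleared-fat-pad transplantation tables
#'
#' Dose-response tables for basal stem/progenitor cells transplanted from
#' age-matched virgin and parous donors, under three outgrowth-scoring
#' stringencies: variant c (>= 25% of fat pad filled), variant d (>= 10%)
#' and variant e (rudimentary, >= 3%). For virgin donors the d and e
#' scorings coincide, so a single `virgin_d` table serves both variants and
#' the variant-e comparison pairs `parous_e` against `virgin_d`.
#'
#' @return named list of five [dilution_assay()] objects: `virgin_c`,
#'   `parous_c`, `virgin_d`, `parous_d`, `parous_e`.
#' @examples
#' tabs <- parity_transplant_tables()
#' fit_single_hit(tabs$virgin_c)
#' @export
parity_transplant_tables <- function() {
  path <- system.file("extdata", "parity_transplants.csv",
                      package = "paritykit", mustWork = TRUE)
  read_dilution_csv(path)
}
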