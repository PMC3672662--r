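# Motif activity response analysis: log-expression of every gene is modeled
# as a linear combination of transcription-factor motif activities, with
# coefficients given by the number of binding sites in the proximal promoter.
# Per sample s: E[, s] ~ N %*% A[, s], solved by ridge-regularized least
# squares after double-centering the expression matrix and column-centering
# the site counts. Condition-level activity changes are scored by z.

#' Infer motif activities from expression and promoter site counts
#'
#' Centers the expression matrix per gene row and per sample column, centers
#' each site-count column, and solves, for every sample `s`,
#' `A[, s] = argmin ||E[, s] - N A||^2 + lambda ||A||^2` in closed form.
#' Standard errors come from the per-sample residual variance times the
#' diagonal of `(N'N + lambda I)^-1`. With `lambda = "cv"` the penalty is
#' selected by k-fold gene-wise cross-validation minimizing held-out squared
#' error on a logarithmic grid scaled to the site-count matrix.
#'
#' @param dataset an [expression_dataset()]; genes must overlap the site
#'   matrix rows.
#' @param sites genes x motifs nonnegative count matrix with rownames
#'   matching the expression genes.
#' @param lambda non-negative ridge penalty, or `"cv"` for cross-validated
#'   selection.
#' @param n_folds folds for cross-validation (default 5).
#' @return A `motif_activity_result` list: `activities` (motif x sample),
#'   `se` (same shape), `lambda`, `residual_variance` (per sample),
#'   `zero_site_motifs`, `cv` (grid and errors when CV was used) and the
#'   sample `condition` labels.
#' @examples
#' sim <- simulate_motif_dataset(simulation_config(seed = 3, n_genes = 400,
#'                                                 n_motifs = 10))
#' fit <- fit_activities(sim$dataset, sim$sites, lambda = 1)
#' @export
fit_activities <- function(dataset, sites, lambda = "cv", n_folds = 5L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sites <- as.matrix(sites)
  if (any(sites < 0)) stop("site counts must be non-negative")
  shared <- intersect(rownames(dataset$expr), rownames(sites))
  if (length(shared) == 0L) stop("no shared genes between expression and site matrices")
  if (ncol(dataset$expr) < 2L) stop("need at least two samples")
  e <- dataset$expr[shared, , drop = FALSE]
  n <- sites[shared, , drop = FALSE]
  zero_motifs <- colnames(n)[colSums(n) == 0]

  # double-center expression (gene rows, then sample columns); center sites
  e <- e - rowMeans(e)
  e <- sweep(e, 2, colMeans(e))
  nc <- sweep(n, 2, colMeans(n))

  ntn <- crossprod(nc)
  if (identical(lambda, "cv")) {
    cv <- cv_ridge_lambda(e, nc, n_folds = n_folds)
    lambda <- cv$lambda
  } else {
    cv <- NULL
    if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0 or \"cv\"")
    if (lambda == 0) {
      ev <- eigen(ntn, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10 * max(ev)) {
        stop("site-count cross-product is singular; use lambda > 0 (or \"cv\")")
      }
    }
  }

  reg <- ntn + diag(lambda, ncol(nc))
  ch <- chol(reg)
  acts <- backsolve(ch, forwardsolve(t(ch), crossprod(nc, e)))
  dimnames(acts) <- list(colnames(n), colnames(e))

  resid <- e - nc %*% acts
  df_resid <- max(1, nrow(e) - ncol(n))
  rv <- colSums(resid^2) / df_resid
  inv_diag <- diag(chol2inv(ch))
  se <- sqrt(outer(inv_diag, rv))
  dimnames(se) <- dimnames(acts)

  structure(list(activities = acts, se = se, lambda = lambda,
                 residual_variance = rv, zero_site_motifs = zero_motifs,
                 cv = cv, condition = dataset$condition),
            class = "motif_activity_result")
}

## Gene-wise k-fold cross-validation of the ridge penalty on a log grid
## scaled by the mean diagonal of N'N (so the grid is invariant to the
## number of genes and the site density).
cv_ridge_lambda <- function(e, nc, n_folds = 5L,
                            ratios = 10^seq(-6, 1, length.out = 15)) {
  g <- nrow(e)
  stopifnot(g >= 2 * n_folds)
  grid <- ratios * mean(diag(crossprod(nc)))
  fold <- rep_len(seq_len(n_folds), g)[sample.int(g)]
  err <- matrix(0, length(grid), n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    ntn_tr <- crossprod(nc[tr, , drop = FALSE])
    nte_tr <- crossprod(nc[tr, , drop = FALSE], e[tr, , drop = FALSE])
    for (j in seq_along(grid)) {
      a <- solve(ntn_tr + diag(grid[j], ncol(nc)), nte_tr)
      pred <- nc[!tr, , drop = FALSE] %*% a
      err[j, k] <- mean((e[!tr, , drop = FALSE] - pred)^2)
    }
  }
  mean_err <- rowMeans(err)
  list(lambda = grid[which.min(mean_err)], grid = grid, cv_error = mean_err)
}

#' @export
print.motif_activity_result <- function(x, ...) {
  cat("Motif activities:", nrow(x$activities), "motifs x",
      ncol(x$activities), "samples; lambda =", format(x$lambda), "\n")
  if (length(x$zero_site_motifs)) {
    cat("  all-zero site columns:", paste(x$zero_site_motifs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score condition-level motif activity changes
#'
#' For each motif, `delta = mean(parous activities) - mean(virgin
#' activities)`. The standard error of `delta` is derived from the
#' within-condition spread of the recovered per-sample activities — which
#' already carries the activity-fitting uncertainty — with the per-motif
#' pooled variances moderated by the same empirical-Bayes squeeze used for
#' differential expression, so that small per-condition sample counts do not
#' produce heavy-tailed z. `z = delta / se`, two-sided normal p, motifs
#' ranked by `|z|`.
#'
#' @param result a [fit_activities()] result.
#' @param condition optional condition factor overriding the one stored in
#'   `result`.
#' @return A `motif_change_report` data frame sorted by decreasing `|z|`:
#'   `motif`, `delta_activity`, `se`, `z`, `p`.
#' @export
motif_change_z <- function(result, condition = NULL) {
  stopifnot(inherits(result, "motif_activity_result"))
  cond <- as.factor(condition %||% result$condition)
  if (nlevels(cond) != 2L) stop("exactly two conditions are required")
  a <- result$activities
  if (length(cond) != ncol(a)) stop("condition labels do not match samples")
  ia <- which(cond == levels(cond)[1L]); ib <- which(cond == levels(cond)[2L])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need at least two samples in each condition")
  }
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(a[, ia, drop = FALSE]); mb <- rowMeans(a[, ib, drop = FALSE])
  ss <- rowSums((a[, ia, drop = FALSE] - ma)^2) +
    rowSums((a[, ib, drop = FALSE] - mb)^2)
  df_resid <- na + nb - 2L
  s2 <- ss / df_resid
  prior <- fit_variance_prior(s2, df_resid)
  s2_post <- squeeze_variances(s2, df_resid, prior$prior_df, prior$prior_var)
  delta <- mb - ma
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  z <- delta / se
  out <- data.frame(motif = rownames(a), delta_activity = delta, se = se,
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_change_report", "data.frame")
  out
}

#' Read a site-count TSV (genes x motifs)
#' @param path TSV file; first column gene ids, remaining columns motifs.
#' @return integer matrix with gene rownames.
#' @export
read_sites_tsv <- function(path) {
  m <- read_expression_tsv(path)
  if (any(m < 0) || any(m != round(m))) stop("site counts must be non-negative integers")
  m
}
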