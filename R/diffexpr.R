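# Two-group moderated differential expression on log2 expression matrices,
# with the linear fold-change / adjusted-p / average-expression filters used
# for the parous-vs-virgin comparisons, and row z-scoring for heatmap display.

#' Construct an expression dataset
#'
#' A genes x samples matrix of log2 expression values together with a
#' two-level condition label per sample (reference first, e.g. virgin, then
#' the treatment condition, e.g. parous).
#'
#' @param expr numeric matrix, genes in rows (unique rownames required),
#'   samples in columns.
#' @param condition factor or character vector of length `ncol(expr)` with
#'   exactly two levels; the first level is the reference.
#' @return An `expression_dataset` list with elements `expr` and `condition`.
#' @export
expression_dataset <- function(expr, condition) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression matrix")
  if (!all(is.finite(expr))) stop("expression values must be finite")
  condition <- as.factor(condition)
  if (length(condition) != ncol(expr)) {
    stop("condition labels must match the number of samples")
  }
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0(as.character(condition), "_", seq_len(ncol(expr)))
  }
  structure(list(expr = expr, condition = condition),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$expr), "genes x", ncol(x$expr), "samples (",
      paste(levels(x$condition), table(x$condition), sep = ":", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Row-wise z-score standardization
#'
#' Standardizes each gene row to mean 0 and sample standard deviation 1,
#' Z = (x - mean) / sd, the normalization used to display expression heatmaps.
#' Constant rows (sd = 0) are mapped to all zeros with a warning.
#'
#' @param x numeric matrix with at least two columns.
#' @return matrix of the same shape with standardized rows.
#' @examples
#' zscore_rows(rbind(a = c(1, 2, 3)))  # -1 0 1
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("z-scoring requires at least two samples per row")
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to all-zero z-scores")
    sd[const] <- 1
  }
  (x - mu) / sd
}

## Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0).
## Convex decreasing on (0, Inf); converges in a handful of iterations.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

## Method-of-moments fit of the scaled-F prior for gene-wise variances,
## working on z = log(s^2). Returns prior df d0 (possibly Inf) and prior
## variance s0^2. Matches the empirical-Bayes model s^2 ~ s0^2 * F(df, d0).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) stop("too few positive variances to estimate a prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  list(prior_df = d0, prior_var = s0_2)
}

## Shrink gene-wise variances toward the prior:
## s2_post = (d0 * s0^2 + df * s2) / (d0 + df).
squeeze_variances <- function(s2, df, prior_df, prior_var) {
  if (is.infinite(prior_df)) rep(prior_var, length(s2))
  else (prior_df * prior_var + df * s2) / (prior_df + df)
}

#' Empirical-Bayes moderated t differential expression
#'
#' Two-group comparison (second condition level minus the first, e.g.
#' parous - virgin) with gene-wise residual variances shrunk toward a prior
#' estimated from all genes. The prior `(d0, s0^2)` is fitted by method of
#' moments on `log s_g^2` under the scaled-F sampling model; posterior
#' variances are `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the moderated t
#' is referred to a t distribution with `d0 + d_g` degrees of freedom.
#' P-values are adjusted by Benjamini-Hochberg.
#'
#' @param dataset an [expression_dataset()] with >= 2 samples per condition.
#' @param prior_df override for the prior degrees of freedom: `NULL`
#'   (default) estimates it; `0` gives the ordinary pooled two-sample t;
#'   `Inf` fully pools all gene variances.
#' @return A `de_result` data frame with one row per gene: `gene`, `log2_fc`,
#'   `ave_linear_expr` (mean of `2^log2` values across all samples), `t_mod`,
#'   `df_total`, `p`, `p_adj`; attributes `prior_df`, `prior_var`,
#'   `fully_pooled`.
#' @examples
#' sim <- simulate_expression_dataset(simulation_config(seed = 1, n_genes = 200))
#' de <- moderated_t(sim$dataset)
#' head(de[order(de$p), ])
#' @export
moderated_t <- function(dataset, prior_df = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  cond <- dataset$condition
  ia <- which(cond == levels(cond)[1L])
  ib <- which(cond == levels(cond)[2L])
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L) stop("need at least two samples per condition")
  x <- dataset$expr
  df_resid <- na + nb - 2L
  if (df_resid < 1L) stop("zero residual degrees of freedom")

  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, ib, drop = FALSE])
  ssa <- rowSums((x[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, ib, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / df_resid

  fully_pooled <- FALSE
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df_resid)
    d0 <- prior$prior_df; s0_2 <- prior$prior_var
    fully_pooled <- is.infinite(d0)
  } else {
    d0 <- prior_df
    s0_2 <- if (d0 > 0) {
      if (is.infinite(d0)) exp(mean(log(s2[s2 > 0]))) else
        fit_variance_prior(s2, df_resid)$prior_var
    } else 0
    fully_pooled <- is.infinite(d0)
  }

  s2_post <- if (d0 == 0) s2 else squeeze_variances(s2, df_resid, d0, s0_2)
  log2_fc <- mb - ma
  t_mod <- log2_fc / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(gene = rownames(x),
                    log2_fc = log2_fc,
                    ave_linear_expr = rowMeans(2^x),
                    t_mod = t_mod,
                    df_total = df_total,
                    p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0_2
  attr(out, "fully_pooled") <- fully_pooled
  class(out) <- c("de_result", "data.frame")
  out
}

#' Differential-expression filter criteria
#'
#' The retention rules applied to a moderated-t table: linear fold change
#' above `min_linear_fc`, BH-adjusted p below `max_p_adj`, and average
#' linear-scale expression across conditions above `min_ave_linear_expr`.
#' The defaults (1.5, 0.05, 4) are the general-analysis cutoffs; the
#' shortlist cutoffs (2.0, 0.001, 4) are available via [top_genes()].
#'
#' @param min_linear_fc minimum linear fold change (> 1).
#' @param max_p_adj maximum adjusted p-value, in (0, 1).
#' @param min_ave_linear_expr minimum average linear expression (> 0).
#' @return a `filter_criteria` list.
#' @export
filter_criteria <- function(min_linear_fc = 1.5, max_p_adj = 0.05,
                            min_ave_linear_expr = 4) {
  stopifnot(min_linear_fc > 1, max_p_adj > 0, max_p_adj < 1,
            min_ave_linear_expr > 0)
  structure(list(min_linear_fc = min_linear_fc, max_p_adj = max_p_adj,
                 min_ave_linear_expr = min_ave_linear_expr),
            class = "filter_criteria")
}

#' Apply fold-change / significance / expression filters
#'
#' @param result a `de_result` from [moderated_t()].
#' @param criteria a [filter_criteria()].
#' @return the retained rows of `result`, original order preserved.
#' @export
apply_filters <- function(result, criteria = filter_criteria()) {
  stopifnot(inherits(result, "de_result"), inherits(criteria, "filter_criteria"))
  keep <- 2^abs(result$log2_fc) > criteria$min_linear_fc &
    result$p_adj < criteria$max_p_adj &
    result$ave_linear_expr > criteria$min_ave_linear_expr
  result[keep, , drop = FALSE]
}

#' Top up- and downregulated genes under strict criteria
#'
#' Genes passing the strict criteria (default: linear fold change > 2,
#' adjusted p < 0.001, average linear expression > 4) are ranked by absolute
#' log2 fold change (ties broken by adjusted p), and the top `n` up- and
#' downregulated genes are reported separately.
#'
#' @param result a `de_result` from [moderated_t()].
#' @param n number of genes per direction.
#' @param strict a [filter_criteria()]; defaults to the shortlist cutoffs.
#' @return list with data frames `up` and `down`.
#' @export
top_genes <- function(result, n = 10,
                      strict = filter_criteria(2.0, 0.001, 4)) {
  passing <- apply_filters(result, strict)
  rank_dir <- function(rows) {
    rows <- rows[order(-abs(rows$log2_fc), rows$p_adj), , drop = FALSE]
    utils::head(rows, n)
  }
  list(up = rank_dir(passing[passing$log2_fc > 0, , drop = FALSE]),
       down = rank_dir(passing[passing$log2_fc < 0, , drop = FALSE]))
}

#' Read an expression TSV (genes in rows, sample ids in the header)
#'
#' @param path TSV file; first column gene ids.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#' @param x numeric matrix with gene rownames.
#' @param path output path.
#' @param id_col name of the gene-id column.
#' @export
write_expression_tsv <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
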