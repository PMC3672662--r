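# Gene-set enrichment on a ranked gene list with a gene-set permutation
# null: the classic weighted Kolmogorov-Smirnov running sum gives the
# enrichment score (ES); random same-size gene sets give the null from which
# nominal p, the normalized enrichment score (NES), FDR q and FWER are
# derived. Gene-set (not phenotype) permutation is used throughout, which
# remains valid with as few as three arrays per condition.

#' Rank genes by mean expression difference
#'
#' Scores each shared gene by `mean(parous samples) - mean(virgin samples)`
#' and returns the list sorted by decreasing score, ties broken by gene id
#' for determinism.
#'
#' @param expr_parous,expr_virgin numeric matrices (genes x samples) with
#'   gene rownames; the shared gene universe is used.
#' @return named numeric vector of scores, sorted descending; class
#'   `ranked_list`.
#' @export
rank_by_difference <- function(expr_parous, expr_virgin) {
  shared <- intersect(rownames(expr_parous), rownames(expr_virgin))
  if (length(shared) == 0L) stop("no shared genes between the two matrices")
  score <- rowMeans(as.matrix(expr_parous)[shared, , drop = FALSE]) -
    rowMeans(as.matrix(expr_virgin)[shared, , drop = FALSE])
  score <- score[order(-score, names(score), method = "radix")]
  class(score) <- "ranked_list"
  score
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list; at each in-set gene ("hit") the running sum
#' increments by `|score|^p` normalized over the in-set total, at each
#' out-of-set gene it decrements by `1/(N - k)`. The enrichment score is the
#' running-sum value of largest magnitude (signed). `p = 1` weights hits by
#' their ranking scores (the conventional default); `p = 0` gives the
#' classic unweighted Kolmogorov-Smirnov form.
#'
#' @param ranked a [rank_by_difference()] result, or any named numeric
#'   vector sorted in decreasing score order.
#' @param set character vector of gene ids; must intersect the ranked list.
#' @param p weight exponent (>= 0), default 1.
#' @return list with `es` and the running-sum `profile` (length N, starting
#'   and ending at 0 up to rounding).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  scores <- unclass(ranked)
  if (is.null(names(scores))) stop("ranked list must be named by gene id")
  hit <- names(scores) %in% set
  if (!any(hit)) stop("gene set does not intersect the ranked list")
  es_running(scores, hit, p)
}

## Core running sum over a logical hit indicator aligned to the ranked list.
es_running <- function(scores, hit, p) {
  n <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^p
  hit_w <- w * hit
  denom <- sum(hit_w)
  if (denom == 0) {
    # all in-set scores are exactly zero (possible with p > 0): fall back to
    # equal hit weights so the profile remains defined
    hit_w <- as.numeric(hit)
    denom <- k
  }
  step <- hit_w / denom - (!hit) / (n - k)
  profile <- cumsum(step)
  es <- unname(profile[which.max(abs(profile))])
  list(es = es, profile = unname(profile))
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then member gene ids.
#' Duplicated members within a set are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `description` attribute
#'   per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    members <- unique(f[-(1:2)])
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Permutation-based enrichment statistics for a gene-set collection
#'
#' For every set, null enrichment scores are computed from `n_perm` random
#' gene sets of the same size drawn from the ranked universe. Nominal p is
#' the fraction of same-sign null ES at least as extreme as the observed ES;
#' NES divides the observed ES by the mean magnitude of same-sign null ES;
#' FDR q uses the tail-ratio construction on the pooled normalized null
#' (fraction of pooled null NES as extreme, divided by the fraction of
#' observed NES as extreme, capped at 1); FWER is the fraction of
#' permutations whose most extreme same-sign null NES exceeds the observed
#' NES.
#'
#' Sets outside `size_range` are flagged (`in_size_range = FALSE`) but still
#' scored, not silently dropped.
#'
#' @param ranked a [rank_by_difference()] result (named scores, descending).
#' @param collection named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm number of permutations (>= 10; >= 100 recommended).
#' @param seed integer seed for the permutation stream.
#' @param p weight exponent passed to [enrichment_score()].
#' @param size_range acceptable set sizes (after intersection with the
#'   universe).
#' @return An `enrichment_result` data frame: `set`, `size`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `fwer`, `in_size_range`, with attributes `n_perm`
#'   and `seed`.
#' @export
permute_and_score <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                              p = 1, size_range = c(5L, 500L)) {
  scores <- unclass(ranked)
  n <- length(scores)
  if (n_perm < 10L) stop("n_perm must be at least 10")
  if (!length(collection)) stop("empty gene-set collection")
  if (is.null(names(collection))) stop("gene-set collection must be named")

  hits <- lapply(collection, function(s) which(names(scores) %in% s))
  sizes <- lengths(hits)
  if (any(sizes == 0L)) {
    stop("sets with empty intersection: ",
         paste(names(collection)[sizes == 0L], collapse = ", "))
  }
  if (any(sizes > n / 2)) {
    warning("set(s) larger than half the universe: ",
            paste(names(collection)[sizes > n / 2], collapse = ", "))
  }

  obs_es <- vapply(hits, function(idx) {
    hit <- logical(n); hit[idx] <- TRUE
    es_running(scores, hit, p)$es
  }, numeric(1))

  # null ES per set x permutation from random same-size sets; sets of equal
  # size share one null block
  null_es <- matrix(NA_real_, length(hits), n_perm,
                    dimnames = list(names(hits), NULL))
  with_seed(stream_seed(seed, "gsea-permutation"), {
    for (k in unique(sizes)) {
      rows <- which(sizes == k)
      block <- vapply(seq_len(n_perm), function(i) {
        hit <- logical(n); hit[sample.int(n, k)] <- TRUE
        es_running(scores, hit, p)$es
      }, numeric(1))
      for (rw in rows) null_es[rw, ] <- block
    }
  })

  stat <- t(vapply(seq_along(hits), function(i) {
    nul <- null_es[i, ]
    same <- if (obs_es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    p_nom <- if (length(same)) mean(abs(same) >= abs(obs_es[i])) else 0
    norm <- if (length(same)) mean(abs(same)) else NA_real_
    c(p_nominal = p_nom, nes = obs_es[i] / norm)
  }, c(p_nominal = 0, nes = 0)))

  nes <- stat[, "nes"]
  # normalize the null the same way to get the pooled null NES distribution
  null_nes <- null_es
  for (i in seq_along(hits)) {
    pos <- null_es[i, ] >= 0
    mpos <- mean(null_es[i, pos]); mneg <- mean(abs(null_es[i, !pos]))
    null_nes[i, pos] <- null_es[i, pos] / mpos
    null_nes[i, !pos] <- null_es[i, !pos] / mneg
  }

  pool <- as.vector(null_nes)
  fdr_q <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- mean(pool[pool >= 0] >= x)
      den <- mean(nes[nes >= 0] >= x)
    } else {
      num <- mean(pool[pool < 0] <= x)
      den <- mean(nes[nes < 0] <= x)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  max_pos <- apply(null_nes, 2, function(col) max(c(col[col >= 0], 0)))
  min_neg <- apply(null_nes, 2, function(col) min(c(col[col < 0], 0)))
  fwer <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) mean(max_pos >= x) else mean(min_neg <= x)
  }, numeric(1))

  out <- data.frame(set = names(hits), size = as.integer(sizes),
                    es = obs_es, nes = nes,
                    p_nominal = stat[, "p_nominal"],
                    fdr_q = fdr_q, fwer = fwer,
                    in_size_range = sizes >= size_range[1] & sizes <= size_range[2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
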