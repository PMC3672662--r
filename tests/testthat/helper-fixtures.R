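# Shared fixtures and independent oracles used across the test files.

# Table of cleared-fat-pad doses and injection counts used throughout:
# five dose groups, 9/11/6/6/7 injections.
std_doses <- c(1000, 500, 250, 100, 50)
std_n <- c(9, 11, 6, 6, 7)

make_assay <- function(r, group = "g", doses = std_doses, n = std_n) {
  dilution_assay(doses, n, r, group = group)
}

# Independent oracle for the single-hit MLE: iteratively refined dense grid
# search over log f. No derivative or optimizer machinery shared with the
# implementation under test.
grid_search_logf <- function(dose, n, r, lo = -20, hi = 2,
                             n_points = 2001L, passes = 4L) {
  ll <- function(phi) {
    a <- exp(phi) * dose
    sum(r * log1p(-exp(-a)) - (n - r) * a)
  }
  for (pass in seq_len(passes)) {
    grid <- seq(lo, hi, length.out = n_points)
    vals <- vapply(grid, ll, numeric(1))
    best <- which.max(vals)
    width <- grid[2] - grid[1]
    lo <- grid[max(1L, best - 2L)]
    hi <- grid[min(n_points, best + 2L)]
  }
  grid[best]
}

# Random non-boundary dilution table for property-based suites.
random_assay <- function() {
  repeat {
    k <- sample(2:5, 1)
    doses <- sort(sample(c(25, 50, 100, 250, 500, 1000, 2000), k), decreasing = TRUE)
    n <- sample(4:12, k, replace = TRUE)
    f <- 1 / exp(stats::runif(1, log(50), log(3000)))
    r <- stats::rbinom(k, n, -expm1(-f * doses))
    if (any(r > 0) && any(r < n)) {
      return(dilution_assay(doses, n, r, group = "random"))
    }
  }
}

# Brute-force running-sum enrichment score: direct loop over list positions.
brute_force_es <- function(scores, set_positions, p = 0) {
  n <- length(scores)
  w <- unname(abs(scores)^p)
  inset <- seq_len(n) %in% set_positions
  denom <- sum(w[inset])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (inset[i]) w[i] / denom else -1 / (n - sum(inset))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
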