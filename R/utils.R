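# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a global seed and a stream name.
#'
#' Each generator draws from its own substream so that adding or removing a
#' generator never perturbs the draws of the others. The substream seed is a
#' deterministic hash of (seed, name) folded into the 32-bit signed range.
#'
#' @param seed integer global seed.
#' @param name character stream label.
#' @return integer seed below 2^31.
#' @keywords internal
#' @noRd
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 7919 + h + 1) %% 2147483629)
}

#' Evaluate an expression under a local RNG state.
#'
#' Saves and restores .Random.seed so seeded generators do not disturb the
#' caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Draw n samples from a multivariate normal via Cholesky factorization.
#' @keywords internal
#' @noRd
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

#' MD5 hash of an R object through its canonical JSON serialization.
#'
#' Used to fingerprint pipeline configurations; identical configurations give
#' identical hashes across sessions.
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
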