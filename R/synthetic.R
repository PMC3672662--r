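# Seeded generators producing every input the analysis stages consume, with
# the statistical structure each stage assumes: binomial transplant outcomes
# under the single-hit model, log2 expression with scaled-inverse-chi-square
# gene variances and planted condition effects, expression built as promoter
# site counts x planted motif activities plus noise, and two-population RGB
# images with a known stained fraction.
#
# One global seed is expanded into per-generator substreams, so adding a
# generator never perturbs the draws of the others.

#' Simulation configuration
#'
#' Parameters of all synthetic-data generators. Defaults emulate a small
#' two-condition (virgin vs parous) microarray study: three arrays per
#' condition, a few thousand genes, moderate planted effects.
#'
#' @param seed integer global seed; expanded into per-generator substreams.
#' @param n_genes number of genes.
#' @param n_samples_per_condition arrays per condition.
#' @param n_motifs number of transcription-factor binding motifs.
#' @param de_fraction fraction of genes receiving a planted condition effect.
#' @param de_log2_effect absolute planted shift in log2 units.
#' @param variance_prior_df,variance_prior_scale degrees of freedom and scale
#'   of the scaled-inverse-chi-square distribution of gene-wise variances, so
#'   the moderated-t shrinkage prior is exactly the generative family.
#' @param motif_site_rate mean promoter binding-site count per motif
#'   (Poisson), keeping the site-count matrix sparse.
#' @param motif_activity_sd per-sample spread of motif activities around the
#'   condition means.
#' @param expression_noise_sd residual log2 noise.
#' @param image_size integer (height, width) of synthetic micrographs.
#' @param positive_fraction fraction of stained pixels in synthetic images.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 5000L,
                              n_samples_per_condition = 3L,
                              n_motifs = 50L,
                              de_fraction = 0.05,
                              de_log2_effect = 1.0,
                              variance_prior_df = 4,
                              variance_prior_scale = 0.05,
                              motif_site_rate = 0.5,
                              motif_activity_sd = 1.0,
                              expression_noise_sd = 0.5,
                              image_size = c(128L, 128L),
                              positive_fraction = 0.25) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_motifs = as.integer(n_motifs), de_fraction = de_fraction,
              de_log2_effect = de_log2_effect,
              variance_prior_df = variance_prior_df,
              variance_prior_scale = variance_prior_scale,
              motif_site_rate = motif_site_rate,
              motif_activity_sd = motif_activity_sd,
              expression_noise_sd = expression_noise_sd,
              image_size = as.integer(image_size),
              positive_fraction = positive_fraction)
  with(cfg, {
    stopifnot(n_genes > 0, n_samples_per_condition > 0, n_motifs > 0,
              de_fraction >= 0, de_fraction <= 1,
              variance_prior_df > 0, variance_prior_scale > 0,
              motif_site_rate >= 0, motif_activity_sd > 0,
              expression_noise_sd >= 0,
              length(image_size) == 2L, all(image_size > 0),
              positive_fraction >= 0, positive_fraction <= 1)
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a limiting-dilution transplantation assay
#'
#' Draws binomial outcomes under the single-hit Poisson model: each injection
#' at dose `d` is positive independently with probability `1 - exp(-f d)`.
#'
#' @param frequency true repopulating frequency (units per cell), >= 0.
#' @param doses cells injected per fat pad, one entry per dose group.
#' @param n_per_dose injections per dose group.
#' @param seed integer seed.
#' @param group label for the simulated group.
#' @return a [dilution_assay()].
#' @examples
#' simulate_dilution_assay(1 / 500, c(1000, 500, 250, 100, 50),
#'                         c(9, 11, 6, 6, 7), seed = 1)
#' @export
simulate_dilution_assay <- function(frequency, doses, n_per_dose, seed,
                                    group = "simulated") {
  if (frequency < 0) stop("frequency must be non-negative")
  if (any(doses <= 0)) stop("doses must be positive")
  stopifnot(length(doses) == length(n_per_dose))
  r <- with_seed(stream_seed(seed, "dilution"), {
    stats::rbinom(length(doses), size = n_per_dose,
                  prob = -expm1(-frequency * doses))
  })
  dilution_assay(doses, n_per_dose, r, group = group)
}

#' Simulate a two-condition expression dataset with planted effects
#'
#' Gene baselines are drawn wide (log2 N(7, 2)); gene-wise variances from a
#' scaled inverse-chi-square with (`variance_prior_df`,
#' `variance_prior_scale`), the exact generative family of the moderated-t
#' shrinkage prior; a `de_fraction` subset of genes receives a random-sign
#' shift of `de_log2_effect` in the second (parous) condition.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   data frame of planted differentially expressed genes (`gene`, `sign`,
#'   `effect`) plus attribute `gene_variances`.
#' @export
simulate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(stream_seed(config$seed, "expression"), {
    g <- config$n_genes; ns <- config$n_samples_per_condition
    genes <- sprintf("gene_%05d", seq_len(g))
    baseline <- stats::rnorm(g, mean = 7, sd = 2)
    # scaled inverse-chi-square: df * scale / chi2_df
    v <- config$variance_prior_df * config$variance_prior_scale /
      stats::rchisq(g, df = config$variance_prior_df)

    n_de <- floor(config$de_fraction * g)
    if (config$de_fraction > 0 && n_de < 1L) {
      warning("de_fraction * n_genes < 1: no genes planted")
    }
    de_idx <- if (n_de >= 1L) sort(sample.int(g, n_de)) else integer(0)
    sign <- if (n_de >= 1L) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
    shift <- numeric(g)
    shift[de_idx] <- sign * config$de_log2_effect

    mu <- cbind(matrix(baseline, g, ns),
                matrix(baseline + shift, g, ns))
    expr <- mu + matrix(stats::rnorm(g * 2 * ns, sd = rep(sqrt(v), 2 * ns)),
                        g, 2 * ns)
    rownames(expr) <- genes
    colnames(expr) <- c(paste0("virgin_", seq_len(ns)),
                        paste0("parous_", seq_len(ns)))
    cond <- factor(rep(c("virgin", "parous"), each = ns),
                   levels = c("virgin", "parous"))
    truth <- data.frame(gene = genes[de_idx], sign = sign,
                        effect = sign * config$de_log2_effect,
                        stringsAsFactors = FALSE)
    attr(truth, "gene_variances") <- stats::setNames(v, genes)
    list(dataset = expression_dataset(expr, cond), truth = truth)
  })
}

#' Simulate paired expression and promoter site-count matrices
#'
#' Site counts `N[g, m]` are sparse Poisson draws; per-sample motif
#' activities are drawn around condition means that differ by the planted
#' shifts; expression is `N %*% A` plus Gaussian noise plus gene baselines.
#' Motifs whose site-count column is all zero are generated as-is and flagged
#' in the truth record (they are unidentifiable downstream).
#'
#' @param config a [simulation_config()].
#' @param planted_activity_changes named numeric vector mapping motif ids
#'   (`motif_001`, ...) to parous-minus-virgin activity shifts; unnamed
#'   motifs get shift 0.
#' @return list with `dataset` (an [expression_dataset()]), `sites` (genes x
#'   motifs integer matrix) and `truth` (list: `activities` motif x sample
#'   matrix, `shifts`, `zero_site_motifs`).
#' @export
simulate_motif_dataset <- function(config, planted_activity_changes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_motifs >= config$n_genes) {
    stop("need n_motifs much smaller than n_genes for an over-determined fit")
  }
  with_seed(stream_seed(config$seed, "motif"), {
    g <- config$n_genes; m <- config$n_motifs
    ns <- config$n_samples_per_condition
    genes <- sprintf("gene_%05d", seq_len(g))
    motifs <- sprintf("motif_%03d", seq_len(m))
    sites <- matrix(stats::rpois(g * m, lambda = config$motif_site_rate),
                    g, m, dimnames = list(genes, motifs))

    shifts <- stats::setNames(numeric(m), motifs)
    if (!is.null(planted_activity_changes)) {
      unknown <- setdiff(names(planted_activity_changes), motifs)
      if (length(unknown)) stop("unknown motif ids: ", paste(unknown, collapse = ", "))
      shifts[names(planted_activity_changes)] <- planted_activity_changes
    }
    cond_mean <- cbind(matrix(0, m, ns), matrix(shifts, m, ns))
    acts <- cond_mean + matrix(stats::rnorm(m * 2 * ns,
                                            sd = config$motif_activity_sd),
                               m, 2 * ns)
    samples <- c(paste0("virgin_", seq_len(ns)), paste0("parous_", seq_len(ns)))
    dimnames(acts) <- list(motifs, samples)

    baseline <- stats::rnorm(g, mean = 7, sd = 2)
    expr <- sites %*% acts + baseline +
      matrix(stats::rnorm(g * 2 * ns, sd = config$expression_noise_sd), g, 2 * ns)
    colnames(expr) <- samples
    cond <- factor(rep(c("virgin", "parous"), each = ns),
                   levels = c("virgin", "parous"))
    list(dataset = expression_dataset(expr, cond),
         sites = sites,
         truth = list(activities = acts, shifts = shifts,
                      zero_site_motifs = motifs[colSums(sites) == 0]))
  })
}

#' Simulate a two-population immunohistochemistry image
#'
#' Exactly `floor(positive_fraction * H * W)` pixels are drawn from the
#' positive (stained) color distribution and the remainder from the
#' background distribution, both multivariate normal with covariance
#' `color_cov`; pixel positions are randomized and a ground-truth mask
#' returned. Intensities are clipped to \[0, 255\].
#'
#' @param config a [simulation_config()] (uses `image_size`,
#'   `positive_fraction`, `seed`).
#' @param positive_color_mean,background_color_mean RGB 3-vectors in
#'   \[0, 255\].
#' @param color_cov 3x3 symmetric positive-definite covariance.
#' @return list with `image` (H x W x 3 array, 0-255) and `mask` (H x W
#'   logical truth mask).
#' @export
simulate_ihc_image <- function(config,
                               positive_color_mean = c(120, 70, 30),
                               background_color_mean = c(190, 160, 210),
                               color_cov = diag(25, 3)) {
  stopifnot(inherits(config, "simulation_config"),
            length(positive_color_mean) == 3L,
            length(background_color_mean) == 3L,
            all(dim(color_cov) == c(3L, 3L)))
  if (any(positive_color_mean < 0 | positive_color_mean > 255) ||
      any(background_color_mean < 0 | background_color_mean > 255)) {
    stop("color means must lie in [0, 255]")
  }
  if (max(abs(color_cov - t(color_cov))) > 1e-8 ||
      any(eigen(color_cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("color covariance must be symmetric positive-definite")
  }
  with_seed(stream_seed(config$seed, "ihc"), {
    h <- config$image_size[1]; w <- config$image_size[2]
    npix <- h * w
    npos <- floor(config$positive_fraction * npix)
    pos_idx <- if (npos > 0) sample.int(npix, npos) else integer(0)
    mask <- matrix(FALSE, h, w)
    mask[pos_idx] <- TRUE
    pix <- matrix(0, npix, 3)
    if (npos > 0) {
      pix[pos_idx, ] <- rmvnorm_chol(npos, positive_color_mean, color_cov)
    }
    if (npos < npix) {
      bg <- setdiff(seq_len(npix), pos_idx)
      pix[bg, ] <- rmvnorm_chol(length(bg), background_color_mean, color_cov)
    }
    pix <- pmin(pmax(pix, 0), 255)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- matrix(pix[, ch], h, w)
    list(image = img, mask = mask)
  })
}

#' Write a simulated 0-255 RGB array as PNG
#' @param image H x W x 3 array with values in \[0, 255\].
#' @param path output PNG path.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
}

#' Read a PNG as a 0-255 RGB array
#' @param path PNG path.
#' @return H x W x 3 array scaled to 0-255 (alpha dropped, gray replicated).
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}
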