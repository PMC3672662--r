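# Mahalanobis-distance color segmentation of immunohistochemistry
# micrographs: a reference RGB distribution (mean + covariance) is fitted
# from training pixels of the stain of interest, and image pixels whose
# squared Mahalanobis distance to that reference falls below a chi-square(3)
# quantile are called positive. The positive-pixel fraction quantifies
# staining (e.g. versican deposition) per image.

#' Fit a reference color distribution from training pixels
#'
#' Sample mean and covariance of RGB training pixels. A covariance that is
#' (near-)singular — e.g. from pixels lying on a color plane — is
#' regularized by inflating the diagonal and the result flagged.
#'
#' @param training_pixels numeric matrix or data frame with >= 10 rows and 3
#'   columns (R, G, B in 0-255).
#' @return A `color_reference` list: `mu`, `sigma`, `n_training_pixels`,
#'   `regularized`.
#' @export
fit_color_reference <- function(training_pixels) {
  px <- as.matrix(training_pixels)
  if (ncol(px) != 3L) stop("training pixels must have 3 columns (R, G, B)")
  if (nrow(px) < 10L) stop("need at least 10 training pixels")
  mu <- colMeans(px)
  sigma <- stats::cov(px)
  regularized <- FALSE
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * max(max(ev), 1)) {
    sigma <- sigma + diag(max(1e-6 * max(ev), 1e-3), 3)
    regularized <- TRUE
  }
  structure(list(mu = mu, sigma = sigma,
                 n_training_pixels = nrow(px), regularized = regularized),
            class = "color_reference")
}

#' @export
print.color_reference <- function(x, ...) {
  cat(sprintf("Color reference: mu = (%.1f, %.1f, %.1f), n = %d%s\n",
              x$mu[1], x$mu[2], x$mu[3], x$n_training_pixels,
              if (x$regularized) " (covariance regularized)" else ""))
  invisible(x)
}

#' Segment an RGB image by Mahalanobis distance to a color reference
#'
#' A pixel is positive iff its squared Mahalanobis distance to the reference
#' distribution is at most the chi-square(3) quantile `qchisq(quantile, 3)`,
#' so on pixels drawn exactly from the reference Gaussian the positive rate
#' equals `quantile`. The positive fraction is computed over an optional
#' tissue mask (e.g. to exclude white background).
#'
#' @param image H x W x 3 numeric array, intensities 0-255 (see
#'   [read_rgb_png()]).
#' @param reference a [fit_color_reference()] result.
#' @param quantile probability in (0, 1) defining the distance cutoff
#'   (default 0.99).
#' @param tissue_mask optional H x W logical matrix restricting the analyzed
#'   region.
#' @return A `segmentation_result` list: `mask` (H x W logical),
#'   `positive_fraction` (over the analyzed region), `threshold` (squared
#'   distance cutoff), `quantile`, `n_analyzed`.
#' @examples
#' cfg <- simulation_config(seed = 5, image_size = c(64, 64))
#' sim <- simulate_ihc_image(cfg)
#' ref <- fit_color_reference(matrix(rnorm(300, c(120, 70, 30), 5),
#'                                   ncol = 3, byrow = TRUE))
#' seg <- segment_by_mahalanobis(sim$image, ref)
#' seg$positive_fraction
#' @export
segment_by_mahalanobis <- function(image, reference, quantile = 0.99,
                                   tissue_mask = NULL) {
  stopifnot(inherits(reference, "color_reference"))
  if (!(is.numeric(quantile) && length(quantile) == 1L &&
        quantile > 0 && quantile < 1)) {
    stop("quantile must lie strictly between 0 and 1")
  }
  dm <- dim(image)
  if (length(dm) != 3L || dm[3] != 3L) stop("image must be an H x W x 3 array")
  pix <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  d2 <- stats::mahalanobis(pix, reference$mu, reference$sigma)
  cutoff <- stats::qchisq(quantile, df = 3)
  mask <- matrix(d2 <= cutoff, dm[1], dm[2])
  if (!is.null(tissue_mask)) {
    stopifnot(identical(dim(tissue_mask), dm[1:2]))
    analyzed <- which(tissue_mask)
  } else {
    analyzed <- seq_len(dm[1] * dm[2])
  }
  frac <- mean(mask[analyzed])
  structure(list(mask = mask & (if (is.null(tissue_mask)) TRUE else tissue_mask),
                 positive_fraction = frac, threshold = cutoff,
                 quantile = quantile, n_analyzed = length(analyzed)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Mahalanobis segmentation: %.2f%% positive (d2 <= %.2f, quantile %.3f, %d pixels)\n",
              100 * x$positive_fraction, x$threshold, x$quantile, x$n_analyzed))
  invisible(x)
}

#' Luminance-based tissue mask
#'
#' Marks pixels darker than a luminance cutoff as tissue, excluding bright
#' (near-white) background from quantification.
#'
#' @param image H x W x 3 array, 0-255.
#' @param max_luminance pixels with mean RGB above this are background.
#' @return H x W logical matrix (TRUE = tissue).
#' @export
tissue_mask_by_luminance <- function(image, max_luminance = 240) {
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3 <= max_luminance
}
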