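# Model-independent rank analysis of temperature-series spectra.

#' Singular-value decomposition of a spectra matrix
#'
#' Decomposes a wavelength x temperature ellipticity matrix; the number of
#' significant components estimates how many spectroscopically
#' distinguishable species are populated across the series.  Raw spectra
#' are decomposed by default (no mean-centering).
#'
#' @param spectra numeric matrix, wavelengths x temperatures, no missing
#'   cells, at least 3 columns.
#' @param center if `TRUE`, subtract the row means before decomposing.
#' @return An object of class `svd_result` with `singularValues`
#'   (non-increasing), `leftVectors` (wavelength basis), `rightVectors`
#'   (temperature amplitudes), and the matrix dimensions.
#' @export
svd_decompose <- function(spectra, center = FALSE) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 3) stop("need at least 3 temperature columns", call. = FALSE)
  if (anyNA(spectra)) stop("spectra matrix contains missing cells", call. = FALSE)
  if (all(spectra == 0)) stop("degenerate all-zero spectra matrix", call. = FALSE)
  if (center) spectra <- spectra - rowMeans(spectra)
  s <- svd(spectra)
  structure(list(singularValues = s$d, leftVectors = s$u, rightVectors = s$v,
                 dims = dim(spectra)),
            class = "svd_result")
}

#' Estimate the number of significant spectral components
#'
#' Two criteria are available: `threshold` counts singular values
#' exceeding a fraction `f` of the largest (default `f = 0.05`, the
#' headline criterion), and `autocorrelation` counts components whose
#' temperature-amplitude vector has lag-1 autocorrelation above `cutoff`
#' (default 0.8), i.e. varies smoothly with temperature rather than like
#' noise.
#'
#' @param result an [svd_decompose()] result.
#' @param method `"threshold"` or `"autocorrelation"`.
#' @param f significance fraction for the threshold criterion.
#' @param cutoff lag-1 autocorrelation cutoff.
#' @return Integer count of significant components.
#' @export
estimate_rank <- function(result, method = c("threshold", "autocorrelation"),
                          f = 0.05, cutoff = 0.8) {
  method <- match.arg(method)
  d <- result$singularValues
  if (method == "threshold") {
    return(sum(d > f * d[1]))
  }
  lag1 <- function(v) {
    v <- v - mean(v)
    denom <- sum(v^2)
    if (denom == 0) return(0)
    sum(v[-1] * v[-length(v)]) / denom
  }
  sum(apply(result$rightVectors, 2, lag1) > cutoff)
}
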