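#' Log-transform counts
#'
#' `log(count + pseudocount)`. Natural log by default; the base is
#' irrelevant to downstream interaction calls because min-max scaling
#' removes any positive affine transformation (see
#' [call_valid_interactions()]), but is exposed for verification.
#'
#' @param counts non-negative numeric vector
#' @param pseudocount positive offset added before the log (default 1,
#'   so zero counts map to 0)
#' @param base logarithm base (default natural)
#' @return numeric vector of transformed values
#' @export
log_transform <- function(counts, pseudocount = 1, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  stopifnot(pseudocount > 0)
  log(counts + pseudocount, base = base)
}

#' Min-max scale values to the 8-bit interval
#'
#' `s_i = round(255 * (v_i - vmin) / (vmax - vmin))` with half-up
#' rounding: the minimum maps to 0, the maximum to 255, mimicking the
#' 8-bit image representation that Otsu thresholding operates on. The
#' result is invariant under any positive affine transform of the
#' input.
#'
#' @param values numeric vector, at least 2 elements
#' @return integer vector in `0..255` with attributes `vmin`, `vmax`
#' @export
scale_to_8bit <- function(values) {
  stopifnot(length(values) >= 2L)
  vmin <- min(values)
  vmax <- max(values)
  if (vmax <= vmin)
    stop(errorCondition(
      "constant profile: all values identical, cannot scale to 8 bits",
      class = c("degenerate_profile", "error", "condition")))
  s <- as.integer(floor(255 * (values - vmin) / (vmax - vmin) + 0.5))
  s <- pmin(pmax(s, 0L), 255L)
  structure(s, vmin = vmin, vmax = vmax)
}

#' Otsu threshold of a 256-bin histogram
#'
#' For each candidate cut `k` in `0..254`, splits the histogram into a
#' low class (bins `<= k`) and a high class (bins `> k`) and computes
#' the between-class variance
#' `sigma_b^2(k) = w0 * w1 * (mu0 - mu1)^2`; the threshold is the
#' smallest `k` maximising it. Applied to 8-bit-scaled log counts this
#' separates background noise from genuine viewpoint-interaction
#' signal.
#'
#' @param histogram non-negative integer vector of length 256 (bin `i`
#'   holds the count of scaled value `i - 1`); see [hist_256()]
#' @return object of class `otsu_result`: list with `histogram`,
#'   `threshold` (0-based bin, `NA` when degenerate),
#'   `between_class_variance` (length 256, entry `k+1` for cut `k`;
#'   the final entry is 0 by convention) and `degenerate` flag (fewer
#'   than 2 non-empty bins)
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256L, all(histogram >= 0))
  n <- sum(histogram)
  if (n < 2 || sum(histogram > 0) < 2L) {
    return(structure(list(histogram = histogram, threshold = NA_integer_,
                          between_class_variance = numeric(256L),
                          degenerate = TRUE),
                     class = "otsu_result"))
  }
  p <- histogram / n
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * 0:255)
  mu_t <- mu_cum[256L]
  sigma <- (mu_t * w0 - mu_cum)^2 / (w0 * (1 - w0))
  sigma[!is.finite(sigma)] <- 0
  sigma[256L] <- 0
  structure(list(histogram = histogram,
                 threshold = which.max(sigma[1:255]) - 1L,
                 between_class_variance = sigma,
                 degenerate = FALSE),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  if (x$degenerate) cat("Otsu result: degenerate histogram (<2 non-empty bins)\n")
  else cat(sprintf("Otsu threshold: %d (between-class variance %.4g; n = %d)\n",
                   x$threshold, x$between_class_variance[x$threshold + 1L],
                   sum(x$histogram)))
  invisible(x)
}

#' Tabulate 8-bit values into a 256-bin histogram
#'
#' @param scaled integer vector in `0..255`
#' @return integer vector of length 256
#' @export
hist_256 <- function(scaled) {
  stopifnot(all(scaled >= 0L & scaled <= 255L))
  tabulate(scaled + 1L, nbins = 256L)
}
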