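#' Binomial multiplicative cascade
#'
#' Generates a deterministic binomial cascade on `2^depth` dyadic bins: the
#' unit interval is halved `depth` times, the left half of each subinterval
#' receiving weight fraction `p` and the right half `1 - p`. The result is a
#' 1D probability measure with an analytically known multifractal spectrum
#' (see [cascade_true_spectrum()]), used as the ground-truth input when
#' validating the spectrum estimators.
#'
#' @param p Weight fraction assigned to the left half at each level,
#'   `0 < p < 1`. `p = 0.5` gives the uniform (monofractal) measure.
#' @param depth Number of dyadic levels, `depth >= 1`; the measure has
#'   `2^depth` bins.
#' @param shuffle_seed Optional integer; when set, the bins are permuted with
#'   a seeded random shuffle. Shuffling preserves the multifractal spectrum of
#'   the bin-value distribution while destroying the spatial nesting, which is
#'   useful for probing what the estimators actually respond to.
#' @return Numeric vector of `2^depth` nonnegative weights summing to 1.
#' @examples
#' generate_binomial_cascade(0.7, 2)  # 0.49 0.21 0.21 0.09
#' @export
generate_binomial_cascade <- function(p, depth, shuffle_seed = NULL) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p >= 1) {
    stop("p must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 ||
      depth != round(depth)) {
    stop("depth must be an integer >= 1", call. = FALSE)
  }
  w <- 1
  for (k in seq_len(depth)) {
    w <- as.vector(rbind(w * p, w * (1 - p)))
  }
  if (!is.null(shuffle_seed)) {
    w <- with_local_seed(shuffle_seed, sample(w))
  }
  w
}

#' Closed-form multifractal spectrum of the binomial cascade
#'
#' Exact generalized dimension, singularity strength, and singularity spectrum
#' of the binomial cascade with weight `p`, evaluated at moment order(s) `q`.
#' Serves as the independent oracle against which the regression-based
#' estimators are checked. In base-2 logarithms:
#' \deqn{D_q = -\log_2(p^q + (1-p)^q)/(q - 1), \quad q \ne 1}
#' \deqn{D_1 = -(p \log_2 p + (1-p)\log_2(1-p))}
#' \deqn{\alpha_q = -\frac{p^q \log_2 p + (1-p)^q \log_2(1-p)}{p^q + (1-p)^q}}
#' \deqn{f_q = q\,\alpha_q - (q - 1) D_q}
#'
#' @param p Weight fraction in (0, 1).
#' @param q Numeric vector of moment orders.
#' @return A data frame with columns `q`, `D`, `alpha`, `f`.
#' @examples
#' cascade_true_spectrum(0.7, c(0, 1, 2))
#' @export
cascade_true_spectrum <- function(p, q) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("p must be a single number in (0, 1)", call. = FALSE)
  }
  lp <- log2(p)
  lq <- log2(1 - p)
  D <- vapply(q, function(qi) {
    if (abs(qi - 1) < .Machine$double.eps^0.5) {
      -(p * lp + (1 - p) * lq)
    } else {
      -log2(p^qi + (1 - p)^qi) / (qi - 1)
    }
  }, numeric(1))
  Z <- p^q + (1 - p)^q
  alpha <- -(p^q * lp + (1 - p)^q * lq) / Z
  f <- q * alpha - (q - 1) * D
  data.frame(q = q, D = D, alpha = alpha, f = f)
}
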