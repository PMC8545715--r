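# Multifractal analysis of 1D measures by the direct (Chhabra-Jensen) method:
# dyadic partitioning of the support, moment sums over bins, and ordinary
# least-squares regression of the relevant statistic against log epsilon.

curve_counts <- function(curve) {
  if (inherits(curve, "frequency_curve")) curve$counts
  else if (is.numeric(curve)) curve
  else stop("curve must be a frequency_curve or numeric vector", call. = FALSE)
}

#' Dyadic partition of a frequency curve into a normalized measure
#'
#' Splits the curve into `2^k` contiguous equal-length bins and normalizes
#' the per-bin count sums to a probability measure. The relative bin size is
#' `epsilon = 2^-k`; absolute bin length is `L / 2^k` slices.
#'
#' @param curve A `frequency_curve` or numeric vector of counts.
#' @param k Dyadic level, `2^k <= length(curve)`; the length must be
#'   divisible by `2^k`.
#' @return A `dyadic_partition`: list with `k`, `n_bins`, `epsilon`, and
#'   normalized bin measures `mu` (summing to 1).
#' @export
dyadic_measures <- function(curve, k) {
  counts <- curve_counts(curve)
  L <- length(counts)
  if (k < 1 || k != round(k)) stop("k must be an integer >= 1", call. = FALSE)
  n_bins <- 2^k
  if (n_bins > L) stop("2^k exceeds curve length", call. = FALSE)
  if (L %% n_bins != 0) {
    stop("curve length must be divisible by 2^k; truncate first", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero curve: no measure to partition", call. = FALSE)
  bin <- rep(seq_len(n_bins), each = L / n_bins)
  mu <- as.numeric(tapply(counts, bin, sum)) / total
  structure(list(k = k, n_bins = n_bins, epsilon = 2^-k, mu = mu),
            class = "dyadic_partition")
}

#' Moment partition sum
#'
#' \eqn{Z(q, \epsilon) = \sum_i \mu_i^q} over non-empty bins; `q = 0` counts
#' the non-empty bins.
#'
#' @param partition A `dyadic_partition`.
#' @param q Moment order.
#' @return The partition sum.
#' @export
partition_sum <- function(partition, q) {
  stopifnot(inherits(partition, "dyadic_partition"))
  mu <- partition$mu[partition$mu > 0]
  sum(mu^q)
}

#' Chhabra-Jensen normalized weights
#'
#' \eqn{\mu_i(q) = \mu_i^q / \sum_j \mu_j^q} over non-empty bins; empty bins
#' keep weight 0. `q = 1` returns the measure unchanged; `q = 0` is uniform
#' over the non-empty bins.
#'
#' @param partition A `dyadic_partition`.
#' @param q Moment order.
#' @return Numeric weights of length `n_bins`, summing to 1.
#' @export
chhabra_weights <- function(partition, q) {
  stopifnot(inherits(partition, "dyadic_partition"))
  mu <- partition$mu
  w <- numeric(length(mu))
  nz <- mu > 0
  w[nz] <- mu[nz]^q
  w / sum(w)
}

# OLS of y on x, returning slope, its standard error, and R^2. Computed
# directly (not via lm) so that numerically exact fits on ideal scaling data
# give R^2 = 1 and SE = 0 without perfect-fit warnings.
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - (my + slope * (x - mx))
  rss <- sum(res^2)
  tss <- sum((y - my)^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NaN
  r2 <- if (tss > 0) 1 - rss / tss else if (rss < 1e-20) 1 else 0
  list(slope = slope, se = se, r2 = r2)
}

# Precompute partitions once per curve for a set of levels.
mf_partitions <- function(counts, k_range) {
  lapply(k_range, function(k) dyadic_measures(counts, k))
}

# Levels usable at moment order q: for q < 0 a level with any empty bin is
# dropped entirely (mu^q diverges as mu -> 0); for q >= 0 empty bins are
# simply excluded from the sums.
usable_levels <- function(partitions, q) {
  if (q >= 0) return(seq_along(partitions))
  which(vapply(partitions, function(p) all(p$mu > 0), logical(1)))
}

#' Estimate singularity strength and spectrum value at one moment order
#'
#' Direct-method estimates: \eqn{\alpha_q} is the OLS slope of
#' \eqn{\sum_i \mu_i(q) \log \mu_i(\epsilon)} against \eqn{\log \epsilon},
#' and \eqn{f_q} the slope of \eqn{\sum_i \mu_i(q) \log \mu_i(q)} against
#' \eqn{\log \epsilon}, over the dyadic levels in `k_range`, where
#' \eqn{\mu_i(q)} are the [chhabra_weights()]. The estimate is accepted when
#' both regressions reach `r2_threshold`.
#'
#' @param curve A `frequency_curve` or numeric counts (length a power of 2).
#' @param q Moment order.
#' @param k_range Dyadic levels used for the regression (default
#'   `1:min(10, log2(L))`).
#' @param r2_threshold Acceptance threshold on the coefficient of
#'   determination (default 0.9).
#' @return List with `alpha`, `se_alpha`, `r2_alpha`, `f`, `se_f`, `r2_f`,
#'   `accepted`, and `n_levels` used.
#' @export
estimate_alpha_f <- function(curve, q, k_range = NULL, r2_threshold = 0.9) {
  counts <- curve_counts(curve)
  k_range <- default_k_range(length(counts), k_range)
  parts <- mf_partitions(counts, k_range)
  est_alpha_f_q(parts, k_range, q, r2_threshold)
}

est_alpha_f_q <- function(parts, k_range, q, r2_threshold) {
  use <- usable_levels(parts, q)
  if (length(use) < 3) {
    stop("fewer than 3 usable dyadic levels at q = ", q, call. = FALSE)
  }
  x <- log(2^-k_range[use])
  y_alpha <- vapply(use, function(i) {
    p <- parts[[i]]
    w <- chhabra_weights(p, q)
    nz <- p$mu > 0
    sum(w[nz] * log(p$mu[nz]))
  }, numeric(1))
  y_f <- vapply(use, function(i) {
    p <- parts[[i]]
    w <- chhabra_weights(p, q)
    nz <- w > 0
    sum(w[nz] * log(w[nz]))
  }, numeric(1))
  fa <- ols_slope(x, y_alpha)
  ff <- ols_slope(x, y_f)
  list(alpha = fa$slope, se_alpha = fa$se, r2_alpha = fa$r2,
       f = ff$slope, se_f = ff$se, r2_f = ff$r2,
       accepted = fa$r2 >= r2_threshold && ff$r2 >= r2_threshold,
       n_levels = length(use))
}

#' Estimate the generalized (Renyi) dimension at one moment order
#'
#' For `q != 1`, \eqn{D_q} is the OLS slope of \eqn{\log \sum_i \mu_i^q}
#' against \eqn{\log \epsilon}, divided by `q - 1`; the slope standard error
#' is scaled by `1 / |q - 1|`. For `q = 1` the entropy (L'Hopital) form is
#' used: the slope of \eqn{\sum_i \mu_i \log \mu_i} against
#' \eqn{\log \epsilon}.
#'
#' @inheritParams estimate_alpha_f
#' @return List with `D`, `se_D`, `r2_D`, `accepted`, `n_levels`.
#' @export
estimate_Dq <- function(curve, q, k_range = NULL, r2_threshold = 0.9) {
  counts <- curve_counts(curve)
  k_range <- default_k_range(length(counts), k_range)
  parts <- mf_partitions(counts, k_range)
  est_Dq_q(parts, k_range, q, r2_threshold)
}

est_Dq_q <- function(parts, k_range, q, r2_threshold) {
  use <- usable_levels(parts, q)
  if (length(use) < 3) {
    stop("fewer than 3 usable dyadic levels at q = ", q, call. = FALSE)
  }
  x <- log(2^-k_range[use])
  if (abs(q - 1) < .Machine$double.eps^0.5) {
    y <- vapply(use, function(i) {
      mu <- parts[[i]]$mu
      mu <- mu[mu > 0]
      sum(mu * log(mu))
    }, numeric(1))
    fit <- ols_slope(x, y)
    D <- fit$slope; se <- fit$se
  } else {
    y <- vapply(use, function(i) log(partition_sum(parts[[i]], q)), numeric(1))
    fit <- ols_slope(x, y)
    D <- fit$slope / (q - 1)
    se <- fit$se / abs(q - 1)
  }
  list(D = D, se_D = se, r2_D = fit$r2,
       accepted = fit$r2 >= r2_threshold, n_levels = length(use))
}

default_k_range <- function(L, k_range = NULL) {
  k_max <- floor(log2(L))
  if (is.null(k_range)) k_range <- seq_len(min(10, k_max))
  k_range <- as.integer(k_range)
  if (any(k_range < 1) || any(k_range > k_max)) {
    stop("k_range must lie within [1, log2(L)]", call. = FALSE)
  }
  k_range
}

# Truncate a curve to the largest centered power-of-two length.
truncate_pow2 <- function(counts) {
  L <- length(counts)
  m <- floor(log2(L))
  L2 <- 2^m
  if (L2 == L) return(counts)
  warning(sprintf("curve length %d is not a power of 2; using the centered %d slices",
                  L, L2), call. = FALSE)
  start <- floor((L - L2) / 2) + 1
  counts[start:(start + L2 - 1)]
}

#' Full multifractal spectrum of a frequency curve
#'
#' Runs the singularity-spectrum and generalized-dimension estimators over a
#' grid of moment orders (default q = -9..9 in steps of 1) and dyadic levels
#' k (default 1..10, capped at log2 of the curve length), flags each
#' estimate by the R-squared acceptance rule, and attaches shape
#' descriptors. Curves whose length is not a power of two are truncated to
#' the largest centered power-of-two window, with a warning.
#'
#' @param curve A `frequency_curve` or numeric counts.
#' @param q_grid Moment orders (default `-9:9`).
#' @param k_range Dyadic levels (default `1:min(10, log2(L))`).
#' @param r2_threshold Acceptance threshold on R-squared (default 0.9).
#' @return A `multifractal_spectrum`: list with `table` (one row per q:
#'   alpha, f, D, standard errors, R-squared values, accepted flag),
#'   `descriptors` (see [spectrum_descriptors()]), and the analysis
#'   parameters.
#' @examples
#' sp <- run_multifractal(generate_binomial_cascade(0.7, 10) * 1e6)
#' sp$descriptors$D0  # ~1 by construction of the dyadic support
#' @export
run_multifractal <- function(curve, q_grid = -9:9, k_range = NULL,
                             r2_threshold = 0.9) {
  counts <- truncate_pow2(curve_counts(curve))
  k_range <- default_k_range(length(counts), k_range)
  if (length(k_range) < 3) stop("need at least 3 dyadic levels", call. = FALSE)
  parts <- mf_partitions(counts, k_range)
  rows <- lapply(q_grid, function(q) {
    af <- tryCatch(est_alpha_f_q(parts, k_range, q, r2_threshold),
                   error = function(e) NULL)
    dq <- tryCatch(est_Dq_q(parts, k_range, q, r2_threshold),
                   error = function(e) NULL)
    data.frame(
      q = q,
      alpha = if (is.null(af)) NA_real_ else af$alpha,
      se_alpha = if (is.null(af)) NA_real_ else af$se_alpha,
      r2_alpha = if (is.null(af)) NA_real_ else af$r2_alpha,
      f = if (is.null(af)) NA_real_ else af$f,
      se_f = if (is.null(af)) NA_real_ else af$se_f,
      r2_f = if (is.null(af)) NA_real_ else af$r2_f,
      D = if (is.null(dq)) NA_real_ else dq$D,
      se_D = if (is.null(dq)) NA_real_ else dq$se_D,
      r2_D = if (is.null(dq)) NA_real_ else dq$r2_D,
      n_levels = if (is.null(af)) 0L else af$n_levels,
      accepted = !is.null(af) && !is.null(dq) && af$accepted && dq$accepted
    )
  })
  table <- do.call(rbind, rows)
  spectrum <- structure(list(table = table, q_grid = q_grid,
                             k_range = k_range, r2_threshold = r2_threshold,
                             L = length(counts)),
                        class = "multifractal_spectrum")
  spectrum$descriptors <- tryCatch(spectrum_descriptors(spectrum),
                                   error = function(e) NULL)
  spectrum
}

#' Shape descriptors of a multifractal spectrum
#'
#' Summarizes the spectrum by its singularity-strength extremes and
#' asymmetry and by differences of generalized dimensions: `alpha0`,
#' `alpha_min`, `alpha_max`, width `delta_alpha = alpha_max - alpha_min`,
#' asymmetry `A = (alpha0 - alpha_min) / (alpha_max - alpha0)` (`NaN` when
#' the denominator vanishes, i.e. a degenerate point spectrum), `D0`, `D1`,
#' `D2`, `D0_D2`, and `Dqmin_Dqmax` (D at the smallest minus D at the
#' largest accepted q). Only accepted q values feed the extremes; the list
#' also records which q were rejected.
#'
#' @param spectrum A `multifractal_spectrum`.
#' @return Named list of descriptors.
#' @export
spectrum_descriptors <- function(spectrum) {
  stopifnot(inherits(spectrum, "multifractal_spectrum"))
  tb <- spectrum$table
  row0 <- tb[tb$q == 0, ]
  if (nrow(row0) != 1 || !row0$accepted) {
    stop("q = 0 estimate rejected: spectrum descriptors undefined",
         call. = FALSE)
  }
  acc <- tb[tb$accepted, ]
  alpha0 <- row0$alpha
  alpha_min <- min(acc$alpha)
  alpha_max <- max(acc$alpha)
  A <- if (alpha_max - alpha0 < 1e-9) NaN else
    (alpha0 - alpha_min) / (alpha_max - alpha0)
  getD <- function(qv) {
    r <- tb[tb$q == qv, ]
    if (nrow(r) == 1 && r$accepted) r$D else NA_real_
  }
  D0 <- getD(0); D1 <- getD(1); D2 <- getD(2)
  list(alpha0 = alpha0, alpha_min = alpha_min, alpha_max = alpha_max,
       delta_alpha = alpha_max - alpha_min, A = A,
       f_alpha0 = row0$f,
       D0 = D0, D1 = D1, D2 = D2,
       D0_D2 = D0 - D2,
       Dqmin_Dqmax = acc$D[which.min(acc$q)] - acc$D[which.max(acc$q)],
       q_accepted = acc$q,
       q_rejected = tb$q[!tb$accepted])
}

#' @export
print.multifractal_spectrum <- function(x, ...) {
  cat(sprintf("multifractal_spectrum: L = %d, q in [%g, %g], k in [%d, %d], R2 >= %g\n",
              x$L, min(x$q_grid), max(x$q_grid), min(x$k_range),
              max(x$k_range), x$r2_threshold))
  cat(sprintf("  accepted %d / %d q values\n", sum(x$table$accepted),
              nrow(x$table)))
  d <- x$descriptors
  if (!is.null(d)) {
    cat(sprintf("  alpha0 = %.4f, delta_alpha = %.4f, A = %.3f\n",
                d$alpha0, d$delta_alpha, d$A))
    cat(sprintf("  D0 = %.4f, D1 = %.4f, D2 = %.4f, D0 - D2 = %.4f\n",
                d$D0, d$D1, d$D2, d$D0_D2))
  }
  invisible(x)
}

#' Write a spectrum table as CSV
#'
#' One row per moment order with the estimates, standard errors, R-squared
#' values and acceptance flags.
#'
#' @param spectrum A `multifractal_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "multifractal_spectrum"))
  utils::write.csv(spectrum$table, path, row.names = FALSE)
  invisible(path)
}
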