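#' Squared exponential covariance
#'
#' \eqn{k(t_p, t_q) = \theta_1 \exp(-\tfrac12 \theta_2 |t_p - t_q|^2)}.
#' `theta1` is the signal variance (squared-count units); `theta2` the
#' inverse squared length-scale (1/h^2), so large `theta2` means wiggly
#' trajectories and small `theta2` smooth ones.
#'
#' @param tp,tq Times in hours (vectorized with recycling).
#' @param theta1 Signal variance, > 0.
#' @param theta2 Inverse squared length-scale, > 0.
#' @return Covariance value(s).
#' @export
se_kernel <- function(tp, tq, theta1, theta2) {
  if (any(theta1 <= 0) || any(theta2 <= 0))
    stop("theta1 and theta2 must be positive")
  theta1 * exp(-0.5 * theta2 * (tp - tq)^2)
}

#' Gaussian-process covariance matrix over a time grid
#'
#' Pairwise [se_kernel()] values plus a small diagonal jitter proportional
#' to `theta1`. The jitter keeps the matrix positive definite when
#' evaluation times coincide, which happens by construction when several
#' replicates share (scaled) timepoints.
#'
#' @param times Vector of evaluation times in hours (>= 1).
#' @param theta1,theta2 Kernel hyperparameters, see [se_kernel()].
#' @param jitter_rel Relative diagonal jitter; absolute jitter is
#'   `jitter_rel * theta1` (default 1e-6).
#' @return Symmetric positive-definite matrix.
#' @export
gp_covariance <- function(times, theta1, theta2, jitter_rel = 1e-6) {
  if (length(times) < 1L) stop("need at least one timepoint")
  d2 <- outer(times, times, "-")^2
  K <- se_kernel_d2(d2, theta1, theta2)
  K + diag(jitter_rel * theta1, length(times))
}

## kernel from a precomputed squared-distance matrix (hot path)
se_kernel_d2 <- function(d2, theta1, theta2) {
  theta1 * exp(-0.5 * theta2 * d2)
}

#' Negative binomial parameters from mean and variance
#'
#' Solves the textbook (r, p) parameterization from the first two moments:
#' `p = (sigma2 - mu) / sigma2`, `r = mu^2 / (sigma2 - mu)`. Defined only
#' for overdispersed inputs `sigma2 > mu`; callers floor the variance via
#' [variance_at()] before converting.
#'
#' @param mu Mean, > 0.
#' @param sigma2 Variance, > `mu`.
#' @return List with components `r` and `p`.
#' @export
nb_params_from_moments <- function(mu, sigma2) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(sigma2 <= mu))
    stop("sigma2 must exceed mu (overdispersion); floor the variance first")
  list(r = mu^2 / (sigma2 - mu), p = (sigma2 - mu) / sigma2)
}

#' Negative binomial log pmf in mean/variance form
#'
#' Log probability of observing `y` reads under NB(mu, sigma2), evaluated
#' through base R's `dnbinom` with `size = mu^2/(sigma2 - mu)`; as
#' `sigma2` approaches `mu` this converges to the Poisson log pmf.
#'
#' @param y Non-negative integer count(s).
#' @param mu Mean(s), > 0.
#' @param sigma2 Variance(s), > `mu`.
#' @return Log probability (vectorized).
#' @export
nb_log_pmf <- function(y, mu, sigma2) {
  if (any(!is.finite(y) | y < 0 | y %% 1 != 0))
    stop("y must be non-negative integers")
  par <- nb_params_from_moments(mu, sigma2)
  stats::dnbinom(y, size = par$r, mu = mu, log = TRUE)
}

#' Rescale a time grid by a differentiation-efficiency factor
#'
#' Under the default convention the effective time of a replicate with
#' scaling factor k is `t' = k * t`, so the time difference at the last
#' design timepoint T is `T * (k - 1)`: k < 1 decelerates (delays) the
#' replicate, k > 1 accelerates it. The `"divide"` convention interprets k
#' as a divisor, `t' = t / k`.
#'
#' @param times Vector of nominal times in hours.
#' @param k Positive scaling factor.
#' @param convention `"multiply"` (default) or `"divide"`.
#' @return Effective time vector in hours.
#' @export
scaled_times <- function(times, k, convention = c("multiply", "divide")) {
  convention <- match.arg(convention)
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (convention == "multiply") k * times else times / k
}

#' Discrete grid of time-scaling factors
#'
#' The scaling factors are constrained to a discrete grid defined by the
#' time differences they induce at the end of the series: `delta` runs from
#' `-max_shift` to `+max_shift` in steps of `step` hours, and
#' `k = 1 + delta / t_end`. With the defaults (t_end = 72, max_shift = 32,
#' step = 4) this gives 17 grid points with extreme factors 5/9 and 13/9.
#'
#' @param t_end Last design timepoint in hours.
#' @param max_shift Maximal absolute time difference at `t_end`, hours.
#' @param step Grid step in hours; must divide `max_shift`.
#' @return A data frame with columns `delta` (h) and `k`, containing
#'   `delta = 0`, `k = 1` exactly; attributes `t_end` and `step`.
#' @export
timescale_grid <- function(t_end = 72, max_shift = 32, step = 4) {
  if (step <= 0 || max_shift %% step != 0)
    stop("step must be positive and divide max_shift")
  if (t_end <= max_shift)
    stop("t_end must exceed max_shift")
  delta <- seq(-max_shift, max_shift, by = step)
  grid <- data.frame(delta = delta, k = 1 + delta / t_end)
  attr(grid, "t_end") <- t_end
  attr(grid, "step") <- step
  grid
}

#' Joint negative binomial log-likelihood of a replicated time course
#'
#' Sums the NB log pmf over replicates and timepoints for one gene. Row j,
#' column i of `f` is the latent trajectory evaluated at replicate j's
#' scaled time for design timepoint i; the observation mean is the
#' size-factor scaled latent value `sf * f` (the scaling acts on the GP
#' sample, not on the discrete counts), and the variance comes from the
#' pooled mean-variance function evaluated at that mean. Under the identity
#' link the latent trajectory must be strictly positive wherever it is
#' evaluated; any non-positive value yields `-Inf` (the sampler rejects
#' such proposals rather than clamping them).
#'
#' @param y Count matrix, replicates x timepoints (or vector).
#' @param f Latent trajectory values, same shape as `y`.
#' @param sf Size factors, recycled to the shape of `y`.
#' @param vf Mean-variance function (`dynb_varfun`).
#' @return Scalar log-likelihood; `-Inf` if any latent value is <= 0.
#' @export
joint_log_likelihood <- function(y, f, sf, vf) {
  if (length(y) != length(f))
    stop("y and f must have the same length/shape")
  y <- as.vector(y); f <- as.vector(f)
  sf <- rep_len(as.vector(sf), length(y))
  if (any(f <= 0)) return(-Inf)
  mu <- sf * f
  v <- variance_at(vf, mu)
  sum(stats::dnbinom(y, size = mu^2 / (v - mu), mu = mu, log = TRUE))
}

#' Gene-specific default priors
#'
#' Encodes the default prior specification. The kernel signal variance is
#' fixed per gene at `theta1 = 10 * max(sd(y), 1)` (the floor guards
#' constant genes, for which the sampler would otherwise have a degenerate
#' proposal); `theta2` gets a uniform prior on `[0.5, 1]`, favouring smooth
#' trajectories. The GP prior mean is the mid-range `m = (max(y) +
#' min(y)) / 2` at every timepoint, with prior covariance built from
#' `sigma2 = 0.75` and a signal variance
#' `sigma1 = max(500 * m, ((max(y) - min(y)) / 2)^2)`: the `500 * m` rule
#' is well-scaled for weakly expressed genes, while the range-based term
#' guarantees the prior sd covers half the gene's count swing, so strongly
#' induced genes are not pushed tens of prior sds outside their own prior
#' (which would overwhelm the likelihood and pin the time-scaling
#' posterior at the identity). The time-scaling prior is a pmf over
#' the discrete delta grid: by default a discretized normal centered at
#' zero delay (symmetric around identity scaling); `"uniform"` is also
#' available, and a nonzero `k_prior_mode` gives an informative delay
#' prior.
#'
#' @param y Observed counts of the gene (all samples entering the fit).
#' @param grid Scaling grid from [timescale_grid()].
#' @param k_prior `"gaussian"` (default) or `"uniform"`.
#' @param k_prior_mode Mode of the Gaussian variant, hours (0, the
#'   default, gives the symmetric centered prior; a nonzero mode is an
#'   informative delay prior).
#' @param k_prior_sd Standard deviation of the Gaussian variant, hours
#'   (default 12, placing ~99% of the prior mass inside the default
#'   +/-32 h grid).
#' @param sigma1_mult Multiplier linking `sigma1` to the mid-range
#'   (default 500).
#' @param sigma2 Prior inverse squared length-scale (default 0.75).
#' @param theta2_range Support of the uniform `theta2` prior.
#' @return An object of class `dynb_priors`: list with `theta1`, `m`,
#'   `sigma1`, `sigma2`, `theta2_range`, and `k_log_prior` (named log-pmf
#'   over the grid deltas).
#' @export
default_priors <- function(y, grid = timescale_grid(),
                           k_prior = c("gaussian", "uniform"),
                           k_prior_mode = 0, k_prior_sd = 12,
                           sigma1_mult = 500, sigma2 = 0.75,
                           theta2_range = c(0.5, 1)) {
  if (length(y) == 0L) stop("y is empty")
  k_prior <- match.arg(k_prior)
  y <- as.numeric(y)
  theta1 <- 10 * max(stats::sd(y), 1)
  if (!is.finite(theta1)) theta1 <- 10  # single observation
  m <- (max(y) + min(y)) / 2
  sigma1 <- max(sigma1_mult * m, ((max(y) - min(y)) / 2)^2)
  if (sigma1 <= 0) sigma1 <- sigma1_mult  # all-zero gene safeguard
  pk <- switch(k_prior,
               uniform = rep(1, nrow(grid)),
               gaussian = stats::dnorm(grid$delta, k_prior_mode, k_prior_sd))
  pk <- pk / sum(pk)
  structure(list(theta1 = theta1, m = m, sigma1 = sigma1, sigma2 = sigma2,
                 theta2_range = theta2_range,
                 k_prior = stats::setNames(pk, grid$delta),
                 k_log_prior = stats::setNames(log(pk), grid$delta)),
            class = "dynb_priors")
}

#' @export
print.dynb_priors <- function(x, ...) {
  cat(sprintf("dynb priors: theta1 = %.4g, m = %.4g, sigma1 = %.4g, sigma2 = %.3g\n",
              x$theta1, x$m, x$sigma1, x$sigma2))
  cat(sprintf("theta2 ~ U[%g, %g]; k prior over %d grid deltas\n",
              x$theta2_range[1], x$theta2_range[2], length(x$k_prior)))
  invisible(x)
}
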