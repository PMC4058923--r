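#' Harmonic-mean log marginal likelihood
#'
#' Estimates the log marginal likelihood (model evidence) from posterior
#' samples as the harmonic mean of their likelihoods: with post-burn-in
#' per-sample log-likelihoods \eqn{\ell_i}, the estimate is
#' \eqn{-\log(\tfrac1m \sum_i e^{-\ell_i})}, computed via log-sum-exp so
#' it never overflows even when the likelihood spread exceeds hundreds of
#' nats. The harmonic-mean estimator is known to be noisy; see
#' [logml_bootstrap_sd()] for a resampling-based spread.
#'
#' @param x A `dynb_chain`, a `dynb_fit` (chains pooled), or a numeric
#'   vector of log-likelihoods.
#' @return Scalar log marginal likelihood estimate.
#' @export
log_marginal_likelihood <- function(x) {
  ll <- chain_logliks(x)
  if (any(ll == -Inf)) {
    warning("excluding ", sum(ll == -Inf),
            " -Inf log-likelihood sample(s) from the harmonic mean")
    ll <- ll[ll > -Inf]
  }
  if (length(ll) == 0L) stop("no finite log-likelihood samples")
  -(logsumexp(-ll) - log(length(ll)))
}

chain_logliks <- function(x) {
  if (inherits(x, "dynb_chain")) return(x$loglik[post_burn(x)])
  if (inherits(x, "dynb_fit"))
    return(unlist(lapply(x$chains, function(ch) ch$loglik[post_burn(ch)])))
  if (is.numeric(x)) return(x)
  stop("cannot extract log-likelihoods from this object")
}

#' Bootstrap spread of the harmonic-mean evidence estimate
#'
#' Resamples the post-burn-in log-likelihoods with replacement and reports
#' the standard deviation of the harmonic-mean estimate, giving users a
#' handle on the estimator's instability.
#'
#' @param x As in [log_marginal_likelihood()].
#' @param n_boot Number of bootstrap resamples.
#' @return Standard deviation of the bootstrap estimates.
#' @export
logml_bootstrap_sd <- function(x, n_boot = 50L) {
  ll <- chain_logliks(x)
  ll <- ll[is.finite(ll)]
  n <- length(ll)
  est <- vapply(seq_len(n_boot), function(b) {
    s <- ll[sample.int(n, n, replace = TRUE)]
    -(logsumexp(-s) - log(n))
  }, numeric(1))
  stats::sd(est)
}

#' Bayes factor between condition-specific and shared dynamics
#'
#' Compares the alternative model M1, in which each condition has its own
#' latent dynamics (two independent fits), against the null model M0, a
#' single fit pooling both conditions' replicates. With equal prior model
#' probabilities the evidence for M1 is
#' `BF = p(y | M1) / p(y | M0) = exp(logML(c1) + logML(c2) - logML(pooled))`.
#' A BF of 10 or more is conventionally read as strong evidence for
#' condition-specific dynamics.
#'
#' @param fit_c1,fit_c2 `dynb_fit` objects for the two conditions (M1).
#' @param fit_pooled `dynb_fit` of the pooled model (M0).
#' @return The Bayes factor (positive, possibly `Inf` when the log Bayes
#'   factor is very large); attribute `"log10"` carries log10(BF), which is
#'   always finite.
#' @export
bayes_factor <- function(fit_c1, fit_c2, fit_pooled) {
  if (missing(fit_c1) || missing(fit_c2) || missing(fit_pooled))
    stop("bayes_factor needs the two condition fits and the pooled fit")
  lbf <- log_marginal_likelihood(fit_c1) + log_marginal_likelihood(fit_c2) -
    log_marginal_likelihood(fit_pooled)
  structure(exp(lbf), log10 = lbf / log(10))
}

#' Posterior latent trajectory with credible band
#'
#' Interpolates each stored posterior sample of the latent trajectory to a
#' dense time grid through the Gaussian-process conditional mean (using
#' that sample's kernel hyperparameters and scaled evaluation times), then
#' summarizes pointwise: posterior mean and 2.5%/97.5% sample quantiles.
#' Trajectories are on the size-factor-normalized count scale.
#'
#' @param fit A `dynb_fit`.
#' @param grid Dense time vector (hours); default 101 points spanning the
#'   design range.
#' @param ndraws Number of (thinned) posterior samples to interpolate.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `time`, `mean`, `lower`, `upper`.
#' @export
posterior_trajectory <- function(fit, grid = NULL, ndraws = 200L,
                                 level = 0.95) {
  times <- fit$data$times
  if (is.null(grid))
    grid <- seq(min(times), max(times), length.out = 101L)
  t_end <- attr(fit$grid, "t_end") %||% max(times)
  pri <- fit$priors
  draws <- pooled_draws(fit, ndraws)
  kmax <- 1 + max(abs(fit$grid$delta)) / t_end
  if (any(grid < 0) || any(grid > max(times) * kmax))
    warning("trajectory grid extends beyond the observed (scaled) range; ",
            "extrapolating")
  tu <- fit$control$time_unit_h %||% 24
  jit <- fit$control$jitter_rel %||% 1e-6
  ## replicate nugget on the observation coordinates, as used in the fit
  yv <- as.vector(fit$data$y); sfv <- as.vector(fit$data$sf)
  nugvec <- (fit$control$nugget %||% 0.5) *
    variance_at(fit$vf, pmax(yv, sfv)) / sfv^2
  out <- matrix(NA_real_, length(grid), length(draws$idx))
  for (s in seq_along(draws$idx)) {
    delta <- draws$delta[s, ]
    st <- as.vector((1 + delta / t_end) %o% times) / tu
    fv <- draws$f[s, ]
    Kss <- gp_covariance(st, pri$sigma1, pri$sigma2, jitter_rel = jit) +
      diag(nugvec)
    Kgs <- se_kernel_d2(outer(grid / tu, st, "-")^2, pri$sigma1,
                        pri$sigma2)
    out[, s] <- pri$m + Kgs %*% solve(Kss, fv - pri$m)
  }
  alpha <- (1 - level) / 2
  data.frame(time = grid,
             mean = rowMeans(out),
             lower = apply(out, 1L, stats::quantile, probs = alpha),
             upper = apply(out, 1L, stats::quantile, probs = 1 - alpha))
}

## evenly thinned post-burn-in draws pooled across chains
pooled_draws <- function(fit, ndraws = 200L) {
  per <- max(1L, ceiling(ndraws / length(fit$chains)))
  f <- th <- de <- NULL
  for (ch in fit$chains) {
    idx <- post_burn(ch)
    take <- idx[unique(round(seq(1L, length(idx), length.out = per)))]
    f <- rbind(f, ch$f[take, , drop = FALSE])
    th <- c(th, ch$theta2[take])
    de <- rbind(de, ch$delta[take, , drop = FALSE])
  }
  list(f = f, theta2 = th, delta = de, idx = seq_along(th))
}

#' Posterior of a replicate's time difference
#'
#' Empirical posterior probability mass of the time difference at the last
#' design timepoint for one replicate, tabulated over the discrete grid
#' from the post-burn-in samples.
#'
#' @param fit A `dynb_fit` (time scaling must have been enabled).
#' @param replicate Replicate group: index or group label.
#' @return Data frame with columns `delta` (hours) and `prob` (sums to 1).
#' @export
timescale_posterior <- function(fit, replicate) {
  if (!fit$timescale)
    stop("time scaling was disabled in this fit")
  j <- replicate_index(fit, replicate)
  d <- unlist(lapply(fit$chains,
                     function(ch) ch$delta[post_burn(ch), j]))
  tab <- table(factor(d, levels = fit$grid$delta))
  data.frame(delta = fit$grid$delta,
             prob = as.vector(tab) / length(d))
}

replicate_index <- function(fit, replicate) {
  groups <- fit$data$groups
  if (is.numeric(replicate)) {
    j <- as.integer(replicate)
    if (j < 1L || j > nrow(groups)) stop("replicate index out of range")
    return(j)
  }
  j <- which(groups$replicate == replicate |
               paste(groups$condition, groups$replicate, sep = ":") ==
               replicate)
  if (length(j) != 1L)
    stop("replicate '", replicate, "' does not identify a unique group")
  j
}

#' Per-timepoint fold change between two condition fits
#'
#' Ratio of pseudocounted posterior-mean trajectories at the design
#' timepoints, folded to be >= 1:
#' `max(ratio, 1/ratio)` with `ratio = (mean_c1 + 1) / (mean_c2 + 1)`.
#' Both fits must be on the common size-factor-normalized scale (they are,
#' when size factors were estimated from the full matrix).
#'
#' @param fit_c1,fit_c2 `dynb_fit` objects for the two conditions.
#' @param times Timepoints at which to evaluate; defaults to the design
#'   timepoints.
#' @param ndraws Posterior draws used for the trajectory means.
#' @return Named vector of fold changes (>= 1), one per timepoint.
#' @export
fold_change <- function(fit_c1, fit_c2, times = NULL, ndraws = 200L) {
  times <- times %||% fit_c1$data$times
  m1 <- posterior_trajectory(fit_c1, grid = times, ndraws = ndraws)$mean
  m2 <- posterior_trajectory(fit_c2, grid = times, ndraws = ndraws)$mean
  ratio <- (pmax(m1, 0) + 1) / (pmax(m2, 0) + 1)
  stats::setNames(pmax(ratio, 1 / ratio), times)
}

#' Differential-dynamics decision rule
#'
#' A gene is called differential when the Bayes factor exceeds 10 (strong
#' evidence for condition-specific dynamics) and the fold change exceeds 2
#' in at least one timepoint.
#'
#' @param bf Bayes factor (positive scalar).
#' @param fcs Per-timepoint fold changes (>= 1).
#' @return Logical.
#' @export
call_differential <- function(bf, fcs) {
  isTRUE(bf > 10) && isTRUE(max(fcs) > 2)
}
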