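#' Propose a time-scaling move
#'
#' One step of the discrete random walk on the time-difference grid: with
#' probability 1/3 each, move `delta` by `+step`, `-step`, or stay. Moves
#' beyond the grid boundary are proposed here but carry zero prior mass, so
#' the sampler always rejects them; this preserves the 1/3-1/3-1/3
#' proposal without reflecting at the bounds.
#'
#' @param delta Current time difference(s) on the grid, hours.
#' @param step Grid step in hours (default 4).
#' @return Proposed time difference(s).
#' @export
k_move <- function(delta, step = 4) {
  delta + step * (sample.int(3L, length(delta), replace = TRUE) - 2L)
}

#' Metropolis-Hastings sampler for (f, theta2, k)
#'
#' Samples the joint posterior of the latent trajectory, the kernel
#' length-scale hyperparameter and the replicate time-scaling factors for
#' one gene. Each iteration jointly proposes: `theta2*` from a truncated
#' normal on `[0.5, 1]` centred at the current value; a `+step/-step/stay`
#' move of each non-reference replicate's time difference; and `f*` from a
#' GP-shaped random walk whose correlation structure is the squared
#' exponential kernel at `theta2*` on the proposed scaled times, and whose
#' per-coordinate amplitude is `min(sqrt(theta1), f_step * local
#' observation sd)`: the gene-level amplitude `theta1 = 10 sd(y)` caps the
#' step globally while the local scaling keeps moves acceptable at
#' low-count timepoints when a gene spans orders of magnitude (a single
#' scalar amplitude is rejected essentially always there).
#' The triple is accepted or rejected as a block,
#' entirely in log space, with prior, likelihood and proposal ratios
#' (including the truncated-normal normalizers, which do not cancel near
#' the bounds; the reverse trajectory-proposal density uses the current
#' hyperparameters and scaled times, making the kernel reversible).
#'
#' The latent state is one trajectory value per (replicate, timepoint)
#' coordinate; coordinates of different replicates that fall on (nearly)
#' the same scaled time are tied through the GP covariance, so the state is
#' a single coherent latent function evaluated on each replicate's scaled
#' grid.
#'
#' @param y Count matrix, replicates x timepoints.
#' @param times Nominal design times, hours (columns of `y`).
#' @param sf Size factors: scalar, per-replicate vector, or matrix shaped
#'   like `y`.
#' @param vf Mean-variance function (`dynb_varfun`).
#' @param priors `dynb_priors` from [default_priors()].
#' @param grid Scaling grid from [timescale_grid()].
#' @param n_iter Total iterations (stored samples).
#' @param burn_in Burn-in count, < `n_iter` (stored, discarded downstream).
#' @param theta2_sd Truncated-normal proposal standard deviation.
#' @param f_step Trajectory proposal scale relative to the local
#'   observation sd (default 0.4); ignored in `prior_only` mode, where the
#'   amplitude is `sqrt(theta1)` everywhere.
#' @param timescale Sample time-scaling factors? If `FALSE`, all k = 1.
#' @param reference Index of the reference replicate (k fixed at 1).
#' @param prior_only If `TRUE` the likelihood is constant (prior sampling;
#'   used for sampler validation).
#' @param nugget Replicate-variability term (default 0.5): each
#'   (replicate, timepoint) evaluation of the latent trajectory carries
#'   independent Gaussian noise with variance `nugget` times the local
#'   observation variance (on the trajectory scale). This models
#'   culture-level variability beyond counting noise, keeps the prior
#'   density smooth across neighbouring grid deltas, and is what couples
#'   replicates on the observation-noise scale so that time scaling is
#'   identified; 0 would tie coincident replicate coordinates exactly and
#'   pin the time-scaling chain at the identity.
#' @param jitter_rel Relative numerical jitter added to GP covariance
#'   diagonals (default 1e-6).
#' @param time_unit Hours per kernel time unit (default 24): kernel
#'   distances are computed on `times / time_unit`, so with the default
#'   the `theta2` prior support corresponds to length scales of roughly
#'   24-34 h — smooth trajectories over a multi-day course. Time
#'   differences and the scaling grid stay in hours.
#' @param seed Optional integer seed for this chain.
#' @param init Optional list with `theta2`, `delta`, `f` start values;
#'   the default trajectory start is the cross-replicate mean of
#'   normalized counts at each timepoint (positive and consistent across
#'   replicate-tied coordinates), which burns in far faster than the
#'   prior mean for strongly induced genes.
#' @return An object of class `dynb_chain`: matrices/vectors of the stored
#'   samples (`f`, `theta2`, `delta`, `loglik`, `accepted`) plus metadata.
#' @export
run_mh <- function(y, times, sf, vf, priors, grid = timescale_grid(),
                   n_iter = 10000L, burn_in = 2000L, theta2_sd = 0.01,
                   f_step = 0.4, timescale = TRUE, reference = 1L,
                   prior_only = FALSE, nugget = 0.5, jitter_rel = 1e-6,
                   time_unit = 24, seed = NULL, init = list()) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  M <- nrow(y); N <- ncol(y)
  if (length(times) != N) stop("times must match the columns of y")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (reference < 1L || reference > M) stop("invalid reference replicate")
  sfm <- if (is.matrix(sf)) sf else
    matrix(rep_len(as.vector(sf), M * N), M, N)
  if (!all(dim(sfm) == dim(y))) stop("sf shape does not match y")
  t_end <- attr(grid, "t_end") %||% max(times)
  step <- attr(grid, "step") %||% 4
  max_shift <- max(grid$delta)
  free <- if (timescale) setdiff(seq_len(M), reference) else integer(0)
  n_state <- M * N
  yv <- as.vector(y); sfv <- as.vector(sfm)
  th_lo <- priors$theta2_range[1]; th_hi <- priors$theta2_range[2]
  klp <- priors$k_log_prior
  klp_at <- function(d) {
    if (any(abs(d) > max_shift)) return(-Inf)
    sum(klp[as.character(d)])
  }
  jit2 <- jitter_rel * priors$sigma1
  mvec <- rep(priors$m, n_state)
  ## local observation scale at each coordinate (from the data, fixed for
  ## the whole run): drives the proposal amplitude and the replicate nugget
  muhat <- pmax(yv, sfv)
  ## in prior-only mode the nugget falls back to 1% of the prior signal
  ## variance: without it, coincident replicate coordinates make the prior
  ## singular and the independent proposal component is always rejected
  nugvec <- if (prior_only) rep(0.01 * priors$sigma1, n_state)
            else nugget * variance_at(vf, muhat) / sfv^2
  obsvar <- if (prior_only) nugvec else variance_at(vf, muhat)
  D <- if (prior_only) rep(sqrt(priors$theta1), n_state)
       else pmin(sqrt(priors$theta1),
                 f_step * sqrt(obsvar) / sfv)
  DDt <- tcrossprod(D)
  ## proposal covariance: D (0.7 R(theta2) + 0.3 I) D. The independent
  ## component bounds the condition number, so forward and reverse
  ## proposal densities stay commensurate when a k move (de)correlates
  ## coincident replicate coordinates; a pure kernel correlation is
  ## near-singular there and its reverse density underflows, freezing the
  ## time-scaling chain.
  prop_chol <- function(d2, th2) {
    C <- 0.7 * DDt * exp(-0.5 * th2 * d2)
    diag(C) <- diag(C) + 0.3 * D^2
    chol(C)
  }

  ## caches keyed by the delta configuration: squared distances of the
  ## flattened scaled-time vector, and the GP-prior Cholesky factor
  cache <- new.env(parent = emptyenv())
  get_d2 <- function(delta) {
    key <- paste0("d", paste(delta, collapse = ","))
    d2 <- cache[[key]]
    if (is.null(d2)) {
      st <- as.vector((1 + delta / t_end) %o% times) / time_unit
      d2 <- outer(st, st, "-")^2
      cache[[key]] <- d2
    }
    d2
  }
  get_prior_chol <- function(delta) {
    key <- paste0("p", paste(delta, collapse = ","))
    U <- cache[[key]]
    if (is.null(U)) {
      S <- se_kernel_d2(get_d2(delta), priors$sigma1, priors$sigma2)
      diag(S) <- diag(S) + jit2 + nugvec
      U <- chol(S)
      cache[[key]] <- U
    }
    U
  }

  loglik <- function(f) {
    if (prior_only) return(0)
    joint_log_likelihood(yv, f, sfv, vf)
  }

  ## initial state
  theta2 <- init$theta2 %||% 0.75
  delta <- rep(0, M)
  if (!is.null(init$delta)) delta <- rep_len(init$delta, M)
  delta[reference] <- 0
  f <- init$f %||% pmax(yv / sfv, 1)
  ll_c <- loglik(f)
  Uk_c <- prop_chol(get_d2(delta), theta2)
  lpf_c <- mvn_logpdf(f, mvec, get_prior_chol(delta))
  lpk_c <- klp_at(delta[free])

  f_store <- matrix(NA_real_, n_iter, n_state)
  th_store <- ll_store <- numeric(n_iter)
  d_store <- matrix(NA_real_, n_iter, M)
  acc <- logical(n_iter)

  for (it in seq_len(n_iter)) {
    th_s <- rtnorm1(theta2, theta2_sd, th_lo, th_hi)
    d_s <- delta
    if (length(free)) d_s[free] <- k_move(delta[free], step)
    lpk_s <- klp_at(d_s[free])
    if (is.finite(lpk_s)) {
      Uk_p <- prop_chol(get_d2(d_s), th_s)
      f_s <- mvn_draw(f, Uk_p)
      ll_s <- loglik(f_s)
      if (is.finite(ll_s)) {  # -Inf (non-positive latent) rejects outright
        lpf_s <- mvn_logpdf(f_s, mvec, get_prior_chol(d_s))
        lq_f_fwd <- mvn_logpdf(f_s, f, Uk_p)
        lq_f_rev <- mvn_logpdf(f, f_s, Uk_c)
        lq_t_fwd <- dtnorm_log(th_s, theta2, theta2_sd, th_lo, th_hi)
        lq_t_rev <- dtnorm_log(theta2, th_s, theta2_sd, th_lo, th_hi)
        logr <- (ll_s - ll_c) + (lpf_s - lpf_c) + (lpk_s - lpk_c) +
          (lq_f_rev - lq_f_fwd) + (lq_t_rev - lq_t_fwd)
        if (is.nan(logr))
          stop("NaN in MH log-ratio at iteration ", it,
               "; theta2* = ", th_s, ", delta* = ",
               paste(d_s, collapse = ","))
        if (log(stats::runif(1L)) < logr) {
          f <- f_s; theta2 <- th_s; delta <- d_s
          ll_c <- ll_s; lpf_c <- lpf_s; lpk_c <- lpk_s; Uk_c <- Uk_p
          acc[it] <- TRUE
        }
      }
    }
    f_store[it, ] <- f
    th_store[it] <- theta2
    d_store[it, ] <- delta
    ll_store[it] <- ll_c
  }

  if (!any(acc[(burn_in + 1L):n_iter]))
    warning("no accepted moves after burn-in (", n_iter - burn_in,
            " iterations); acceptance overall = ", mean(acc))

  structure(list(f = f_store, theta2 = th_store, delta = d_store,
                 loglik = ll_store, accepted = acc,
                 n_iter = n_iter, burn_in = burn_in,
                 M = M, N = N, times = times, reference = reference,
                 free = free, timescale = timescale, grid = grid,
                 priors = priors, sf = sfm, y = y, time_unit = time_unit,
                 nugget = nugget, prior_only = prior_only, seed = seed),
            class = "dynb_chain")
}

#' @export
print.dynb_chain <- function(x, ...) {
  cat(sprintf("dynb MH chain: %d iterations (%d burn-in), %d replicates x %d timepoints\n",
              x$n_iter, x$burn_in, x$M, x$N))
  cat(sprintf("acceptance rate %.3f; time scaling %s\n",
              mean(x$accepted), if (x$timescale) "on" else "off"))
  invisible(x)
}

## post-burn-in index range of a chain
post_burn <- function(chain) (chain$burn_in + 1L):chain$n_iter

#' Serialize an MCMC chain to a compressed columnar dump
#'
#' Writes the stored samples (trajectory coordinates, `theta2`, per-group
#' time differences, log-likelihood, acceptance flags) as gzip-compressed
#' TSV, one column per quantity, for post-hoc diagnostics outside R.
#'
#' @param chain A `dynb_chain` from [run_mh()].
#' @param path Output path (conventionally `.tsv.gz`).
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(iteration = seq_len(chain$n_iter),
                   theta2 = chain$theta2,
                   loglik = chain$loglik,
                   accepted = chain$accepted)
  colnames(chain$delta) <- paste0("delta_", seq_len(chain$M))
  colnames(chain$f) <- paste0("f_", rep(seq_len(chain$M), chain$N), "_",
                              rep(seq_len(chain$N), each = chain$M))
  df <- cbind(df, chain$delta, chain$f)
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a chain dump written by [write_chain()]
#' @param path Path to the `.tsv.gz` file.
#' @return A data frame with one row per iteration.
#' @export
read_chain <- function(path) {
  utils::read.table(gzfile(path), header = TRUE, sep = "\t")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the potential scale reduction factor from the between- and
#' within-chain variances of a scalar statistic: with m chains of length n,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the PSRF is `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1
#' indicate the chains have mixed; > 1.1 is the usual warning threshold.
#'
#' @param chains Either a numeric matrix (iterations x chains), or a list
#'   of `dynb_chain` objects (post-burn-in draws of `statistic` are used).
#' @param statistic For chain-object input: the name of a stored scalar
#'   series (`"theta2"` or `"loglik"`) or a function applied to the chain.
#' @return The PSRF (scalar, approximately >= 1).
#' @export
psrf <- function(chains, statistic = "theta2") {
  if (is.list(chains) && !is.data.frame(chains) && !is.matrix(chains)) {
    draws <- lapply(chains, function(ch) {
      idx <- post_burn(ch)
      if (is.function(statistic)) statistic(ch)
      else ch[[statistic]][idx]
    })
    n <- unique(lengths(draws))
    if (length(n) != 1L) stop("chains must have equal post-burn-in length")
    chains <- do.call(cbind, draws)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 2L) stop("chains too short")
  W <- mean(apply(chains, 2L, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}
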