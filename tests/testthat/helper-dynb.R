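# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as naive, literal computations so they stay
# independent of the implementation paths they check.

## standard two-condition design: 2 conditions x 3 replicates x 5 timepoints
make_design <- function(conditions = c("Th0", "Th17"), n_rep = 3,
                        times = c(0, 12, 24, 48, 72)) {
  d <- expand.grid(replicate = paste0("r", seq_len(n_rep)),
                   condition = conditions, time_h = times,
                   stringsAsFactors = FALSE)
  d$sample_id <- paste(d$condition, d$replicate, paste0("t", d$time_h),
                       sep = "_")
  d[, c("sample_id", "condition", "replicate", "time_h")]
}

## small sampler settings for unit tests
tiny_control <- function(...) {
  dynb_control(n_iter = 800, burn_in = 200, chains = 2, ...)
}

## ----- independent oracles ------------------------------------------------

## median-of-ratios, written as the textbook two-pass loop
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(g) exp(mean(log(g))))
  keep <- geo > 0
  raw <- apply(counts, 2, function(col)
    stats::median(col[keep] / geo[keep]))
  raw / exp(mean(log(raw)))
}

## NB log pmf via lgamma, from the (r, p) "number of failures" form
oracle_nb_log_pmf <- function(y, mu, sigma2) {
  r <- mu^2 / (sigma2 - mu)
  p <- (sigma2 - mu) / sigma2
  lgamma(y + r) - lgamma(r) - lgamma(y + 1) + r * log(1 - p) + y * log(p)
}

## joint likelihood as an explicit double loop over replicates/timepoints
oracle_joint_loglik <- function(y, f, sf, vf) {
  total <- 0
  for (j in seq_len(nrow(y))) {
    for (i in seq_len(ncol(y))) {
      if (f[j, i] <= 0) return(-Inf)
      mu <- sf[j, i] * f[j, i]
      v <- max(vf$coefficients[1] + vf$coefficients[2] * mu +
                 vf$coefficients[3] * mu^2, mu * (1 + vf$epsilon))
      total <- total + oracle_nb_log_pmf(y[j, i], mu, v)
    }
  }
  total
}

## Gelman-Rubin PSRF from the definition
oracle_psrf <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, function(x) sum((x - mean(x))^2) / (n - 1)))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## total variation distance between two pmfs on the same support
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

## Kolmogorov-Smirnov distance of draws against U[a, b]
ks_uniform <- function(x, a, b) {
  x <- sort((x - a) / (b - a))
  n <- length(x)
  max(abs(x - (seq_len(n) - 0.5) / n)) + 0.5 / n
}

## a degenerate fit object whose chains hold one constant trajectory;
## exercises trajectory/fold-change code without running the sampler
make_constant_fit <- function(values, times = c(0, 12, 24, 48, 72),
                              n_rep = 3, n_iter = 50) {
  M <- n_rep; N <- length(times)
  f <- matrix(rep(values, each = M), n_iter, M * N, byrow = TRUE)
  y <- matrix(as.integer(round(rep(values, each = M))), M, N)
  chain <- structure(list(f = f, theta2 = rep(0.75, n_iter),
                          delta = matrix(0, n_iter, M),
                          loglik = rep(-1, n_iter),
                          accepted = rep(TRUE, n_iter),
                          n_iter = n_iter, burn_in = 10L, M = M, N = N,
                          times = times, reference = 2L, free = integer(0),
                          timescale = FALSE, grid = timescale_grid(),
                          prior_only = FALSE, seed = 1L),
                     class = "dynb_chain")
  pri <- default_priors(as.vector(y))
  structure(list(chains = list(chain),
                 data = list(y = y, sf = matrix(1, M, N), times = times,
                             groups = data.frame(condition = "c",
                                                 replicate =
                                                   paste0("r", 1:M))),
                 priors = pri, grid = timescale_grid(),
                 vf = variance_function(c(0, 1, 0.05)),
                 control = dynb_control(), timescale = FALSE,
                 reference = 2L, gene = "const", conditions = "c"),
            class = "dynb_fit")
}
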