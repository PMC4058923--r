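# Internal numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## One draw from N_[a,b](mean, sd) via the inverse CDF.
rtnorm1 <- function(mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(1L, pa, pb), mean, sd)
}

## Log density of the truncated normal, normalizer included (it does not
## cancel in the MH ratio near the bounds).
dtnorm_log <- function(x, mean, sd, a, b) {
  z <- stats::pnorm(b, mean, sd) - stats::pnorm(a, mean, sd)
  stats::dnorm(x, mean, sd, log = TRUE) - log(z)
}

## Multivariate normal draw given the upper Cholesky factor U (K = U'U).
mvn_draw <- function(mu, U) {
  mu + drop(crossprod(U, stats::rnorm(length(mu))))
}

## Multivariate normal log density given the upper Cholesky factor.
mvn_logpdf <- function(x, mu, U) {
  v <- backsolve(U, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(v * v))
}

## Deterministic per-task seed derived from a master seed; stays inside the
## 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 8191) %%
               2147483587) + 1L
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x %% 1 == 0)
}
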