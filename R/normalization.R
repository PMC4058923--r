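#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample so that read counts from
#' libraries of different sequencing depth become comparable. For each sample
#' the factor is the median, over genes whose geometric mean across samples
#' is nonzero, of the ratio count / geometric mean. Factors are then rescaled
#' to have geometric mean 1 so that fits are comparable across runs.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' estimate_size_factors(m)  # s2 is double-depth
#' @export
estimate_size_factors <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  logc <- log(counts)
  lgm <- rowMeans(logc)
  use <- is.finite(lgm)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; consider a ",
         "pseudo-reference (e.g. add a pseudocount) before estimating ",
         "size factors")
  sf <- apply(logc[use, , drop = FALSE], 2L,
              function(col) exp(stats::median(col - lgm[use])))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Construct a quadratic mean-variance function
#'
#' The observation variance of the negative binomial is modelled as a
#' degree-2 polynomial of the (normalized) mean count,
#' \eqn{\sigma^2(\mu) = a_0 + a_1\mu + a_2\mu^2}, shared across genes. A
#' multiplicative overdispersion floor keeps \eqn{\sigma^2(\mu) \ge
#' \mu(1+\epsilon)} so the negative binomial stays well-defined
#' (it needs \eqn{\sigma^2 > \mu}).
#'
#' @param coefficients Numeric vector `c(a0, a1, a2)`.
#' @param epsilon Overdispersion floor (default 0.01, i.e. near-Poisson at
#'   the floor).
#' @return An object of class `dynb_varfun`.
#' @export
variance_function <- function(coefficients, epsilon = 0.01) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 3L || any(!is.finite(coefficients)))
    stop("coefficients must be finite c(a0, a1, a2)")
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be a small positive real")
  structure(list(coefficients = coefficients, epsilon = epsilon),
            class = "dynb_varfun")
}

#' @export
print.dynb_varfun <- function(x, ...) {
  a <- x$coefficients
  cat(sprintf("Mean-variance function: sigma^2(mu) = %.4g + %.4g*mu + %.4g*mu^2\n",
              a[1], a[2], a[3]))
  cat(sprintf("Overdispersion floor: sigma^2 >= mu*(1 + %.3g)\n", x$epsilon))
  invisible(x)
}

#' Evaluate the mean-variance function
#'
#' @param vf A `dynb_varfun` from [variance_function()] or
#'   [fit_variance_function()].
#' @param mu Positive mean count(s).
#' @return Variance(s), floored at `mu * (1 + epsilon)`.
#' @export
variance_at <- function(vf, mu) {
  if (any(!is.finite(mu) | mu <= 0)) stop("mu must be positive")
  a <- vf$coefficients
  pmax(a[1] + a[2] * mu + a[3] * mu^2, mu * (1 + vf$epsilon))
}

#' Fit the pooled mean-variance polynomial
#'
#' For every (gene, condition, timepoint) cell with at least two replicates,
#' computes the sample mean and unbiased sample variance of size-factor
#' normalized counts across replicates and pools all such (mean, variance)
#' pairs over genes, conditions and timepoints. The polynomial is then
#' fitted, by default, on the log scale: minimize
#' \eqn{\sum (\log s^2 + c_n - \log(a_0 + a_1\mu + a_2\mu^2))^2} with
#' coefficients constrained non-negative, where
#' \eqn{c_n = \log((n-1)/2) - \psi((n-1)/2)} corrects the downward bias of
#' the log of a chi-square-distributed sample variance. Relative errors of
#' sample variances are homoscedastic, so the log-scale fit gives every
#' expression stratum equal say; direct least squares on the raw pairs
#' (`method = "ls"`, optionally `1/mu^2`-weighted) is dominated by the
#' noisiest high- or low-expression cells and its linear coefficient is
#' unstable from data set to data set. Normalizing before pooling prevents
#' library-size differences from inflating the variance estimate; set
#' `normalized = FALSE` to pool raw counts instead.
#'
#' @param counts Count matrix (genes x samples).
#' @param sheet Sample sheet matching the columns of `counts`.
#' @param sf Size factors from [estimate_size_factors()]; default estimates
#'   them from `counts`.
#' @param normalized Pool size-factor-normalized counts (default) or raw.
#' @param method `"log"` (default, bias-corrected log-scale fit) or
#'   `"ls"` (least squares on the raw pairs).
#' @param weighted Use `1/mu^2` regression weights in the `"ls"` method
#'   (default `TRUE`); ignored for `"log"`.
#' @param epsilon Overdispersion floor passed to [variance_function()].
#' @return A `dynb_varfun`, with attributes `n_points` (pooled pairs used)
#'   and `pooled` (the (mean, variance, n) triples).
#' @export
fit_variance_function <- function(counts, sheet, sf = NULL,
                                  normalized = TRUE,
                                  method = c("log", "ls"),
                                  weighted = TRUE, epsilon = 0.01) {
  method <- match.arg(method)
  sheet <- check_design(counts, sheet)
  if (nrow(counts) < 10L)
    stop("need at least 10 genes to fit the mean-variance function")
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  nc <- if (normalized) sweep(counts, 2L, sf[colnames(counts)], "/")
        else counts
  groups <- split(seq_len(nrow(sheet)),
                  paste(sheet$condition, sheet$time_h, sep = "\r"))
  mus <- vars <- nrep <- NULL
  for (idx in groups) {
    if (length(idx) < 2L) next
    block <- nc[, idx, drop = FALSE]
    mus <- c(mus, rowMeans(block))
    vars <- c(vars, apply(block, 1L, stats::var))
    nrep <- c(nrep, rep(length(idx), nrow(block)))
  }
  if (is.null(mus))
    stop("need at least 2 replicates per (condition, timepoint)")
  keep <- is.finite(mus) & is.finite(vars) & mus > 0
  mus <- mus[keep]; vars <- vars[keep]; nrep <- nrep[keep]
  if (length(mus) < 3L)
    stop("fewer than 3 pooled (mean, variance) points; cannot fit")

  ## base fit on the raw scale (also the optimizer start for "log")
  w <- if (weighted) 1 / mus^2 else rep(1, length(mus))
  fit <- stats::lm(vars ~ mus + I(mus^2), weights = w)
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0  # collinear pooled points (e.g. constant means)
  if (any(cf < 0)) {
    ## a variance law needs non-negative coefficients; unconstrained LS
    ## can go negative when few pooled pairs cover part of the mean range
    cf <- nnls_quadratic(mus, vars, w)
  }

  pos <- vars > 0
  if (method == "log" && sum(pos) >= 3L) {
    ## chi-square bias of log(s^2): E[log s^2] - log sigma^2 = -c_n
    cn <- log((nrep[pos] - 1) / 2) - digamma((nrep[pos] - 1) / 2)
    lv <- log(vars[pos]) + cn
    x <- mus[pos]
    obj <- function(a)
      sum((lv - log(pmax(a[1] + a[2] * x + a[3] * x^2, 1e-300)))^2)
    opt <- tryCatch(
      stats::optim(pmax(cf, c(0, 0.01, 1e-6)), obj, method = "L-BFGS-B",
                   lower = c(0, 0, 0)),
      error = function(e) NULL)
    if (!is.null(opt) && all(is.finite(opt$par))) cf <- opt$par
  }

  vf <- variance_function(cf, epsilon = epsilon)
  attr(vf, "n_points") <- length(mus)
  attr(vf, "pooled") <- data.frame(mean = mus, variance = vars, n = nrep)
  vf
}

## Non-negative weighted LS for v ~ a0 + a1*mu + a2*mu^2: active-set over
## the 2^3 sign patterns (drop negative terms, refit, keep the best
## feasible fit). Small and exact for three coefficients.
nnls_quadratic <- function(mus, vars, w) {
  X <- cbind(1, mus, mus^2)
  best <- NULL; best_rss <- Inf
  for (mask in 1:7) {
    use <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    fit <- stats::lm.wfit(X[, use, drop = FALSE], vars, w)
    cf <- rep(0, 3); cf[use] <- fit$coefficients
    cf[is.na(cf)] <- 0
    if (any(cf < 0)) next
    rss <- sum(w * (vars - X %*% cf)^2)
    if (rss < best_rss) { best <- cf; best_rss <- rss }
  }
  best %||% c(0, 1, 0)  # degenerate data: fall back to Poisson-like
}

#' Serialize normalization results to a JSON sidecar
#'
#' Records size factors and the fitted variance polynomial for
#' reproducibility.
#'
#' @param sf Named size-factor vector.
#' @param vf A `dynb_varfun`.
#' @param path Output path for the JSON file.
#' @export
write_normalization <- function(sf, vf, path) {
  jsonlite::write_json(
    list(size_factors = as.list(sf),
         variance_function = list(coefficients = vf$coefficients,
                                  epsilon = vf$epsilon)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normalization sidecar written by [write_normalization()]
#' @param path Path to the JSON file.
#' @return List with elements `sf` (named vector) and `vf` (`dynb_varfun`).
#' @export
read_normalization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(sf = unlist(x$size_factors),
       vf = variance_function(x$variance_function$coefficients,
                              x$variance_function$epsilon))
}
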