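#' Fit the latent-dynamics model for one gene
#'
#' Fits the Gaussian-process negative-binomial time-course model to one
#' gene's counts. With a single condition this is the per-condition model
#' used in the alternative (condition-specific) hypothesis; passing several
#' conditions pools their replicates into one shared-dynamics fit (the
#' null model of [dynb_de()]), each replicate keeping its own size factors
#' and, when enabled, its own time-scaling factor with a single global
#' reference.
#'
#' @param counts Count matrix (genes x samples) with dimnames, or a named
#'   numeric vector for a single gene.
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @param gene Gene identifier (row of `counts`). May be omitted when
#'   `counts` has a single row.
#' @param conditions Condition label(s) to fit; default: all conditions in
#'   the sheet (a pooled fit if there are several).
#' @param sf Size factors: `NULL` to estimate from `counts` by
#'   median-of-ratios, a scalar, or a named per-sample vector. For data
#'   sets with very few genes, pass factors explicitly.
#' @param vf Mean-variance function (`dynb_varfun`); `NULL` fits it from
#'   `counts` (needs >= 10 genes).
#' @param timescale Estimate replicate time-scaling factors (default
#'   `TRUE`).
#' @param reference Reference replicate whose time scale is fixed (k = 1):
#'   an index into the (condition, replicate) groups or a replicate label.
#'   Default: the second replicate group, so earlier and later cultures
#'   can drift in either direction relative to it.
#' @param priors `dynb_priors`; `NULL` builds gene-specific defaults.
#' @param control Sampler settings from [dynb_control()].
#' @return An object of class `dynb_fit` with components `chains` (list of
#'   `dynb_chain`), `logml` (harmonic-mean log evidence, chains pooled),
#'   `logml_boot_sd`, `data` (the assembled gene data), `priors`, `grid`,
#'   `vf`, `control`, `timescale`, `reference`.
#' @examples
#' sim <- fig2_benchmark(seed = 1)
#' vf <- variance_function(sim$truth$dispersion)
#' fit <- dynb_fit(sim$counts, sim$sheet, gene = "IL17A_like",
#'                 sf = 1, vf = vf,
#'                 control = dynb_control(n_iter = 300, burn_in = 100,
#'                                        chains = 2))
#' print(fit)
#' @export
dynb_fit <- function(counts, samples, gene = NULL, conditions = NULL,
                     sf = NULL, vf = NULL, timescale = TRUE,
                     reference = NULL, priors = NULL,
                     control = dynb_control()) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(gene %||% "gene", names(counts)))
  }
  samples <- check_design(counts, validate_sample_sheet(samples))
  if (is.null(gene)) {
    if (nrow(counts) != 1L) stop("specify which gene to fit")
    gene <- rownames(counts)
  }
  if (!gene %in% rownames(counts)) stop("gene '", gene, "' not found")
  conditions <- conditions %||% unique(samples$condition)
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  if (is.null(vf)) vf <- fit_variance_function(counts, samples, sf = sf,
                                               epsilon = control$epsilon)
  dat <- assemble_gene(counts, samples, gene, conditions, sf)
  grid <- timescale_grid(t_end = max(dat$times),
                         max_shift = control$max_shift_h,
                         step = control$step_h)
  priors <- priors %||% default_priors(
    as.vector(dat$y), grid = grid, k_prior = control$k_prior,
    k_prior_mode = control$k_prior_mode, k_prior_sd = control$k_prior_sd,
    sigma1_mult = control$sigma1_mult, sigma2 = control$sigma2)
  ref <- resolve_reference(dat$groups, reference)
  chains <- lapply(seq_len(control$chains), function(i)
    run_mh(dat$y, dat$times, dat$sf, vf, priors, grid,
           n_iter = control$n_iter, burn_in = control$burn_in,
           theta2_sd = control$theta2_sd, f_step = control$f_step,
           timescale = timescale,
           reference = ref, nugget = control$nugget,
           jitter_rel = control$jitter_rel,
           time_unit = control$time_unit_h,
           seed = derive_seed(control$seed, i),
           init = list(theta2 = control$theta2_init)))
  fit <- structure(list(chains = chains, data = dat, priors = priors,
                        grid = grid, vf = vf, control = control,
                        timescale = timescale, reference = ref,
                        gene = gene, conditions = conditions),
                   class = "dynb_fit")
  fit$logml <- log_marginal_likelihood(fit)
  fit$logml_boot_sd <- logml_bootstrap_sd(fit)
  fit
}

## Build the replicate x timepoint matrices for one gene. Groups are the
## (condition, replicate) pairs in canonical order; all groups must share
## the timepoint grid (validated by the sample sheet for each condition,
## checked across conditions here for pooled fits).
assemble_gene <- function(counts, samples, gene, conditions, sf) {
  sel <- samples$condition %in% conditions
  if (!any(sel)) stop("no samples in condition(s) ",
                      paste(conditions, collapse = ", "))
  sub <- samples[sel, ]
  sub <- sub[canonical_order(sub), ]
  times <- sort(unique(sub$time_h))
  groups <- unique(sub[, c("condition", "replicate")])
  rownames(groups) <- NULL
  M <- nrow(groups); N <- length(times)
  y <- sfm <- matrix(NA_real_, M, N)
  if (is.null(names(sf)) && length(sf) == 1L)
    sf <- stats::setNames(rep(sf, nrow(samples)), samples$sample_id)
  for (j in seq_len(M)) {
    rows <- sub$condition == groups$condition[j] &
      sub$replicate == groups$replicate[j]
    g <- sub[rows, ]
    if (!identical(sort(g$time_h), times))
      stop("replicate '", groups$replicate[j],
           "' does not share the pooled timepoint grid")
    g <- g[order(g$time_h), ]
    y[j, ] <- counts[gene, g$sample_id]
    sfm[j, ] <- sf[g$sample_id]
  }
  if (any(!is.finite(sfm)))
    stop("size factors missing for some samples")
  rownames(y) <- rownames(sfm) <-
    paste(groups$condition, groups$replicate, sep = ":")
  list(y = y, sf = sfm, times = times, groups = groups)
}

resolve_reference <- function(groups, reference) {
  if (is.null(reference)) return(min(2L, nrow(groups)))
  if (is.numeric(reference)) {
    ref <- as.integer(reference)
    if (ref < 1L || ref > nrow(groups)) stop("invalid reference replicate")
    return(ref)
  }
  j <- which(groups$replicate == reference |
               paste(groups$condition, groups$replicate, sep = ":") ==
               reference)
  if (length(j) < 1L) stop("reference replicate '", reference, "' not found")
  j[1L]
}

#' @export
print.dynb_fit <- function(x, ...) {
  cat(sprintf("Latent dynamics fit for gene '%s' (%s)\n", x$gene,
              paste(x$conditions, collapse = " + ")))
  cat(sprintf("  %d replicate group(s) x %d timepoints (%s h)\n",
              nrow(x$data$y), length(x$data$times),
              paste(x$data$times, collapse = ", ")))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d), acceptance %.2f\n",
              length(x$chains), x$control$n_iter, x$control$burn_in,
              mean(vapply(x$chains, function(ch) mean(ch$accepted),
                          numeric(1)))))
  cat(sprintf("  log marginal likelihood (harmonic mean): %.2f (boot sd %.2f)\n",
              x$logml, x$logml_boot_sd))
  if (x$timescale) {
    cf <- coef(x)
    d <- cf[grepl("^delta", names(cf))]
    cat("  posterior-mode time differences at ",
        max(x$data$times), " h: ",
        paste(sprintf("%s=%g", sub("delta\\.", "", names(d)), d),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.dynb_fit <- function(object, ...) {
  draws <- pooled_draws(object, object$control$ndraws)
  out <- c(theta2 = mean(draws$theta2))
  if (object$timescale) {
    modes <- apply(draws$delta, 2L, function(d) {
      tab <- table(d)
      as.numeric(names(tab)[which.max(tab)])
    })
    names(modes) <- paste0("delta.", rownames(object$data$y))
    out <- c(out, modes)
  }
  out
}

#' @export
summary.dynb_fit <- function(object, ...) {
  draws <- pooled_draws(object, 1000L)
  th_q <- stats::quantile(draws$theta2, c(0.025, 0.5, 0.975))
  delta_tab <- NULL
  if (object$timescale) {
    delta_tab <- do.call(rbind, lapply(seq_len(object$chains[[1]]$M),
      function(j) {
        p <- timescale_posterior(object, j)
        data.frame(group = rownames(object$data$y)[j],
                   mode = p$delta[which.max(p$prob)],
                   mean = sum(p$delta * p$prob))
      }))
  }
  r <- list(gene = object$gene, logml = object$logml,
            logml_boot_sd = object$logml_boot_sd,
            theta2 = th_q, delta = delta_tab,
            acceptance = vapply(object$chains,
                                function(ch) mean(ch$accepted), numeric(1)),
            psrf = if (length(object$chains) >= 2L)
              c(theta2 = psrf(object$chains, "theta2"),
                loglik = psrf(object$chains, "loglik")) else NULL)
  class(r) <- "summary.dynb_fit"
  r
}

#' @export
print.summary.dynb_fit <- function(x, ...) {
  cat("Gene:", x$gene, "\n")
  cat(sprintf("log marginal likelihood %.2f (bootstrap sd %.2f)\n",
              x$logml, x$logml_boot_sd))
  cat("theta2 posterior quantiles:\n"); print(round(x$theta2, 4))
  if (!is.null(x$delta)) {
    cat("time differences at the last timepoint (h):\n")
    print(x$delta, row.names = FALSE)
  }
  cat("chain acceptance:", paste(round(x$acceptance, 3), collapse = ", "),
      "\n")
  if (!is.null(x$psrf))
    cat(sprintf("PSRF: theta2 %.3f, loglik %.3f\n",
                x$psrf["theta2"], x$psrf["loglik"]))
  invisible(x)
}

#' @export
predict.dynb_fit <- function(object, times = NULL, level = 0.95,
                             ndraws = NULL, ...) {
  posterior_trajectory(object, grid = times,
                       ndraws = ndraws %||% object$control$ndraws,
                       level = level)
}

#' @export
fitted.dynb_fit <- function(object, ...) {
  draws <- pooled_draws(object, object$control$ndraws)
  fbar <- matrix(colMeans(draws$f), nrow(object$data$y))
  dimnames(fbar) <- dimnames(object$data$y)
  fbar * object$data$sf
}

#' @export
residuals.dynb_fit <- function(object, ...) {
  mu <- fitted(object)
  (object$data$y - mu) / sqrt(variance_at(object$vf, mu))
}

#' Posterior predictive counts
#'
#' Draws replicated count matrices from the posterior predictive: for each
#' simulation a stored posterior sample of the latent trajectory is picked
#' at random and counts are drawn from the negative binomial observation
#' model around it.
#'
#' @param object A `dynb_fit`.
#' @param nsim Number of replicated data sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` count matrices shaped like the data.
#' @export
simulate.dynb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- pooled_draws(object, object$control$ndraws)
  n <- length(draws$theta2)
  lapply(seq_len(nsim), function(s) {
    i <- sample.int(n, 1L)
    mu <- pmax(matrix(draws$f[i, ], nrow(object$data$y)), 1e-8) *
      object$data$sf
    v <- variance_at(object$vf, mu)
    out <- matrix(stats::rnbinom(length(mu), size = mu^2 / (v - mu),
                                 mu = mu),
                  nrow(mu), dimnames = dimnames(object$data$y))
    out
  })
}

#' Plot a fitted latent trajectory
#'
#' Shows the size-factor-normalized counts of each replicate at its
#' posterior-mode effective times, with the posterior-mean trajectory and
#' pointwise credible band.
#'
#' @param x A `dynb_fit`.
#' @param level Credible level for the band.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dynb_fit <- function(x, level = 0.95, ...) {
  tr <- posterior_trajectory(x, level = level,
                             ndraws = x$control$ndraws)
  dat <- x$data
  t_end <- attr(x$grid, "t_end")
  cf <- coef(x)
  deltas <- if (x$timescale) cf[grepl("^delta", names(cf))] else
    rep(0, nrow(dat$y))
  yn <- dat$y / dat$sf
  ylim <- range(tr$lower, tr$upper, yn)
  graphics::plot(tr$time, tr$mean, type = "n", ylim = ylim,
                 xlab = "time (h)", ylab = "normalized read count",
                 main = x$gene, ...)
  graphics::polygon(c(tr$time, rev(tr$time)), c(tr$lower, rev(tr$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(tr$time, tr$mean, col = "steelblue", lwd = 2)
  for (j in seq_len(nrow(dat$y))) {
    eff <- (1 + deltas[j] / t_end) * dat$times
    graphics::points(eff, yn[j, ], pch = j, col = j + 1L)
  }
  graphics::legend("topleft", legend = rownames(dat$y),
                   pch = seq_len(nrow(dat$y)),
                   col = seq_len(nrow(dat$y)) + 1L, bty = "n")
  invisible(x)
}
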