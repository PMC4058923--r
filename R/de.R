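#' Test every gene for differential dynamics between two conditions
#'
#' For each expressed gene, fits the alternative model M1 (one latent
#' dynamics fit per condition) and the null model M0 (a single fit pooling
#' both conditions' replicates), estimates the marginal likelihoods by the
#' harmonic mean, and computes the Bayes factor, per-timepoint fold
#' changes, and the differential call (BF > 10 and fold change > 2 in at
#' least one timepoint). Genes without at least one read in each condition
#' are excluded from testing and flagged.
#'
#' Genes are independent given the size factors and the mean-variance
#' function, which are estimated once from the full matrix; per-gene seeds
#' derive deterministically from `control$seed`, so results are
#' reproducible regardless of gene order.
#'
#' @param counts Count matrix (genes x samples).
#' @param samples Sample sheet covering the columns of `counts`.
#' @param conditions Two condition labels; default: the first two in the
#'   sheet.
#' @param timescale Estimate replicate time-scaling factors (default
#'   `TRUE`). The alternative model estimates them per condition; the
#'   pooled null model estimates one set across all replicate groups with
#'   a single global reference.
#' @param sf,vf Optional precomputed size factors / variance function.
#' @param genes Optional subset of gene identifiers to test; size factors
#'   and the variance function are still estimated from the full matrix.
#' @param reference Reference replicate label or index (see [dynb_fit()]).
#' @param control Sampler settings ([dynb_control()]).
#' @param store_details Keep per-gene time-difference posteriors and
#'   trajectories (default `TRUE`; disable for very large panels).
#' @param verbose Print progress.
#' @return An object of class `dynb_de`: `results` (one row per tested
#'   gene: `gene_id`, `log10_bf`, `max_abs_log2_fc`, `de_call`, one
#'   `delta_<condition>.<replicate>` column per group), `excluded`
#'   (untested gene ids), `sf`, `vf`, `conditions`, `control`, `details`.
#' @export
dynb_de <- function(counts, samples, conditions = NULL, timescale = TRUE,
                    sf = NULL, vf = NULL, genes = NULL, reference = NULL,
                    control = dynb_control(), store_details = TRUE,
                    verbose = FALSE) {
  samples <- check_design(counts, validate_sample_sheet(samples))
  conditions <- conditions %||% unique(samples$condition)[1:2]
  if (length(conditions) != 2L || any(is.na(conditions)))
    stop("dynb_de needs exactly two conditions")
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  if (is.null(vf)) vf <- fit_variance_function(counts, samples, sf = sf,
                                               epsilon = control$epsilon)
  cols1 <- samples$sample_id[samples$condition == conditions[1]]
  cols2 <- samples$sample_id[samples$condition == conditions[2]]
  expressed <- rowSums(counts[, cols1, drop = FALSE]) >= 1 &
    rowSums(counts[, cols2, drop = FALSE]) >= 1
  candidates <- genes %||% rownames(counts)
  if (!all(candidates %in% rownames(counts)))
    stop("unknown gene(s): ",
         paste(setdiff(candidates, rownames(counts)), collapse = ", "))
  excluded <- candidates[!expressed[candidates]]
  genes <- candidates[expressed[candidates]]
  if (length(excluded) && verbose)
    message(length(excluded), " gene(s) excluded (no reads in at least ",
            "one condition)")
  if (!length(genes)) stop("no expressed genes to test")

  rows <- vector("list", length(genes))
  details <- if (store_details) vector("list", length(genes)) else NULL
  times <- sort(unique(samples$time_h[samples$condition %in% conditions]))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ctl <- control
    ctl$seed <- derive_seed(control$seed, gi)
    fit1 <- dynb_fit(counts, samples, gene = g,
                     conditions = conditions[1], sf = sf, vf = vf,
                     timescale = timescale, reference = reference,
                     control = ctl)
    ctl$seed <- derive_seed(control$seed, gi + 500000L)
    fit2 <- dynb_fit(counts, samples, gene = g,
                     conditions = conditions[2], sf = sf, vf = vf,
                     timescale = timescale, reference = reference,
                     control = ctl)
    ctl$seed <- derive_seed(control$seed, gi + 1000000L)
    fit0 <- dynb_fit(counts, samples, gene = g, conditions = conditions,
                     sf = sf, vf = vf, timescale = timescale,
                     reference = reference, control = ctl)
    bf <- bayes_factor(fit1, fit2, fit0)
    fcs <- fold_change(fit1, fit2, times = times,
                       ndraws = control$ndraws)
    call <- call_differential(as.numeric(bf), fcs)
    deltas <- delta_modes(fit1, fit2, timescale)
    rows[[gi]] <- data.frame(gene_id = g,
                             log10_bf = attr(bf, "log10"),
                             max_abs_log2_fc = max(abs(log2(fcs))),
                             de_call = call,
                             t(deltas), check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (store_details)
      details[[gi]] <- list(
        gene = g, logml = c(c1 = fit1$logml, c2 = fit2$logml,
                            pooled = fit0$logml),
        fold_change = fcs,
        delta_posterior = if (timescale)
          list(c1 = lapply(seq_len(nrow(fit1$data$y)), function(j)
                 timescale_posterior(fit1, j)),
               c2 = lapply(seq_len(nrow(fit2$data$y)), function(j)
                 timescale_posterior(fit2, j)))
        else NULL)
    if (verbose)
      message(sprintf("[%d/%d] %s: log10 BF = %.2f, max |log2 FC| = %.2f%s",
                      gi, length(genes), g, attr(bf, "log10"),
                      max(abs(log2(fcs))), if (call) " *" else ""))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res, excluded = excluded, sf = sf, vf = vf,
                 conditions = conditions, control = control,
                 timescale = timescale,
                 details = if (store_details)
                   stats::setNames(details, genes) else NULL),
            class = "dynb_de")
}

## posterior-mode time differences of both M1 fits, named per group;
## reference groups are exactly 0 by construction
delta_modes <- function(fit1, fit2, timescale) {
  groups <- c(rownames(fit1$data$y), rownames(fit2$data$y))
  if (!timescale)
    return(stats::setNames(rep(0, length(groups)),
                           paste0("delta_", groups)))
  md <- function(fit, j) {
    p <- timescale_posterior(fit, j)
    p$delta[which.max(p$prob)]
  }
  vals <- c(vapply(seq_len(nrow(fit1$data$y)), function(j) md(fit1, j),
                   numeric(1)),
            vapply(seq_len(nrow(fit2$data$y)), function(j) md(fit2, j),
                   numeric(1)))
  stats::setNames(vals, paste0("delta_", groups))
}

#' @export
print.dynb_de <- function(x, ...) {
  cat(sprintf("Differential dynamics test: %s vs %s\n",
              x$conditions[1], x$conditions[2]))
  cat(sprintf("  %d gene(s) tested, %d excluded (unexpressed)\n",
              nrow(x$results), length(x$excluded)))
  cat(sprintf("  %d differential call(s) (BF > 10 and fold change > 2)\n",
              sum(x$results$de_call)))
  invisible(x)
}

#' @export
summary.dynb_de <- function(object, n_top = 10L, ...) {
  res <- object$results[order(-object$results$log10_bf), ]
  cat(sprintf("Tested %d genes (%s vs %s); %d called differential.\n",
              nrow(res), object$conditions[1], object$conditions[2],
              sum(res$de_call)))
  cat("Top genes by log10 Bayes factor:\n")
  print(utils::head(res[, c("gene_id", "log10_bf", "max_abs_log2_fc",
                            "de_call")], n_top),
        row.names = FALSE, digits = 4)
  invisible(res)
}

#' @export
as.data.frame.dynb_de <- function(x, ...) x$results

#' @export
plot.dynb_de <- function(x, ...) {
  res <- x$results
  graphics::plot(res$max_abs_log2_fc, res$log10_bf,
                 xlab = "max |log2 fold change|",
                 ylab = "log10 Bayes factor",
                 pch = ifelse(res$de_call, 19, 1),
                 col = ifelse(res$de_call, "firebrick", "grey40"), ...)
  graphics::abline(h = 1, v = 1, lty = 2, col = "grey60")
  invisible(x)
}
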