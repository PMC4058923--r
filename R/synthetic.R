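#' Parametric expression-trajectory templates
#'
#' Smooth positive mean-count trajectories used by the simulator:
#' `induction` is a logistic rise `baseline + amplitude *
#' logistic(slope * (t - midpoint))`, `repression` the mirrored fall,
#' `transient` a Gaussian bump, and `flat` a constant. The default
#' induction parameters sketch a late, strong cytokine-style induction
#' from around a hundred reads to around a hundred thousand over 72 h.
#'
#' @param kind One of `"induction"`, `"repression"`, `"transient"`,
#'   `"flat"`.
#' @param baseline Positive baseline count level.
#' @param amplitude Signed amplitude added to the baseline.
#' @param midpoint Inflection / peak time, hours.
#' @param slope Steepness, 1/h.
#' @param t_max Upper end of the validity check interval (default 72 h).
#' @return A function of time `t` (class `dynb_template`) returning
#'   positive mean counts; template parameters are kept as attributes.
#' @export
make_template <- function(kind = c("induction", "repression", "transient",
                                   "flat"),
                          baseline = 100, amplitude = 1e5, midpoint = 56,
                          slope = 0.2, t_max = 72) {
  kind <- match.arg(kind)
  if (baseline <= 0) stop("baseline must be positive")
  f <- switch(kind,
    flat = function(t) rep(baseline, length(t)),
    induction = function(t)
      baseline + amplitude * stats::plogis(slope * (t - midpoint)),
    repression = function(t)
      baseline + amplitude * (1 - stats::plogis(slope * (t - midpoint))),
    transient = function(t)
      baseline + amplitude * exp(-0.5 * (slope * (t - midpoint))^2))
  probe <- f(seq(0, t_max, length.out = 201L))
  if (any(probe <= 0))
    stop("template is non-positive somewhere on [0, ", t_max, "] h")
  structure(f, class = c("dynb_template", "function"), kind = kind,
            baseline = baseline, amplitude = amplitude,
            midpoint = midpoint, slope = slope)
}

#' Simulate a count matrix with known truth
#'
#' Draws counts from the model's own generative process: for gene g,
#' condition c, replicate r and nominal time t, the mean is
#' `sf * template_gc(k_cr * t)` and the count is negative binomial with
#' variance from the quadratic dispersion polynomial (floored to stay
#' overdispersed). Replicate-specific `k` values emulate differing
#' differentiation efficiencies; size factors emulate library-depth
#' differences.
#'
#' @param templates A list, one element per gene: either a single
#'   `dynb_template` (shared by all conditions) or a named list of
#'   templates by condition.
#' @param design Sample sheet data frame (`sample_id`, `condition`,
#'   `replicate`, `time_h`).
#' @param true_k Data frame with columns `condition`, `replicate`,
#'   `delta` (hours at `t_end`); missing pairs get `delta = 0`.
#' @param sf Named per-sample size factors; default all 1.
#' @param dispersion `c(a0, a1, a2)` of the variance polynomial (default
#'   `c(0, 1, 0.05)`, modest overdispersion).
#' @param epsilon Overdispersion floor.
#' @param t_end Endpoint used to convert `delta` to `k` (default: last
#'   design time).
#' @param seed Optional integer seed (reproducible draws).
#' @return A list of class `dynb_sim`: `counts` (genes x samples),
#'   `sheet`, and `truth` (templates, per-group `delta` and `k`, size
#'   factors, dispersion, per-gene differential flags).
#' @export
simulate_counts <- function(templates, design, true_k = NULL, sf = NULL,
                            dispersion = c(0, 1, 0.05), epsilon = 0.01,
                            t_end = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- validate_sample_sheet(design)
  t_end <- t_end %||% max(design$time_h)
  genes <- names(templates) %||% paste0("gene", seq_along(templates))
  if (is.null(names(templates))) names(templates) <- genes
  if (is.null(sf))
    sf <- stats::setNames(rep(1, nrow(design)), design$sample_id)
  key <- paste(design$condition, design$replicate, sep = ":")
  delta <- stats::setNames(rep(0, nrow(design)), key)
  if (!is.null(true_k)) {
    tk <- paste(true_k$condition, true_k$replicate, sep = ":")
    delta[key %in% tk] <- true_k$delta[match(key[key %in% tk], tk)]
  }
  kvec <- 1 + delta / t_end
  counts <- matrix(NA_real_, length(genes), nrow(design),
                   dimnames = list(genes, design$sample_id))
  vfun <- variance_function(dispersion, epsilon)
  de_flag <- logical(length(genes))
  for (gi in seq_along(genes)) {
    tmpl <- templates[[gi]]
    per_cond <- is.list(tmpl) && !inherits(tmpl, "dynb_template")
    de_flag[gi] <- per_cond &&
      length(unique(vapply(tmpl, function(f)
        paste(attributes(f)[c("kind", "baseline", "amplitude", "midpoint",
                              "slope")], collapse = "/"),
        character(1)))) > 1L
    for (s in seq_len(nrow(design))) {
      f <- if (per_cond) tmpl[[design$condition[s]]] else tmpl
      mu <- sf[design$sample_id[s]] * f(kvec[s] * design$time_h[s])
      v <- variance_at(vfun, mu)
      counts[gi, s] <- stats::rnbinom(1L, size = mu^2 / (v - mu), mu = mu)
    }
  }
  ug <- !duplicated(key)
  truth <- list(templates = templates,
                delta = stats::setNames(delta[ug], key[ug]),
                k = stats::setNames(kvec[ug], key[ug]),
                sf = sf, dispersion = dispersion, epsilon = epsilon,
                t_end = t_end, de = stats::setNames(de_flag, genes),
                seed = seed)
  structure(list(counts = counts, sheet = design, truth = truth),
            class = "dynb_sim")
}

#' @export
print.dynb_sim <- function(x, ...) {
  cat(sprintf("Synthetic count data: %d gene(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  conditions: %s; timepoints (h): %s\n",
              paste(unique(x$sheet$condition), collapse = ", "),
              paste(sort(unique(x$sheet$time_h)), collapse = ", ")))
  d <- x$truth$delta[x$truth$delta != 0]
  if (length(d))
    cat("  delayed/accelerated replicates:",
        paste(sprintf("%s (%+g h)", names(d), d), collapse = ", "), "\n")
  invisible(x)
}

#' Delayed-replicate recovery benchmark
#'
#' The canonical time-scaling benchmark: one strongly induced gene
#' measured in one condition with three replicates at 0, 12, 24, 48 and
#' 72 h. Replicates 2 and 3 follow the undelayed induction template;
#' replicate 1 is a delayed version whose nominal 72 h timepoint behaves
#' like 48 h (template evaluated at `(48/72) * t`, i.e. true k = 2/3 and a
#' time difference of -24 h at 72 h). A correct fit with the discrete
#' time-scaling grid should place the posterior mode of replicate 1's time
#' difference at -24 h.
#'
#' @param seed Integer seed for the count draws.
#' @param template Trajectory template for the gene; default a strong
#'   late logistic induction (about 1e2 to 1e5 reads over 72 h).
#' @param dispersion Variance polynomial coefficients.
#' @return A `dynb_sim` (see [simulate_counts()]); the focal gene is
#'   `"IL17A_like"` and the truth records `delta = c(-24, 0, 0)`.
#' @export
fig2_benchmark <- function(seed = 1L, template = make_template("induction"),
                           dispersion = c(0, 1, 0.05)) {
  times <- c(0, 12, 24, 48, 72)
  design <- data.frame(
    sample_id = paste0("r", rep(1:3, each = length(times)), "_t",
                       rep(times, 3L)),
    condition = "sim",
    replicate = paste0("r", rep(1:3, each = length(times))),
    time_h = rep(times, 3L), stringsAsFactors = FALSE)
  simulate_counts(list(IL17A_like = template), design,
                  true_k = data.frame(condition = "sim", replicate = "r1",
                                      delta = -24),
                  dispersion = dispersion, seed = seed)
}

#' Simulate a two-condition benchmark panel
#'
#' Generates a panel matching the standard design (2 conditions x 3
#' replicates x 5 timepoints at 0/12/24/48/72 h) for calibration and power
#' studies. In the `"null"` scenario every gene has identical dynamics in
#' both conditions (a mix of flat and moderately induced templates), so
#' any differential call is a false positive. In the `"de"` scenario
#' `n_genes` focal genes are flat in the first condition and strongly
#' induced (>= 10-fold by 72 h) in the second, embedded in a background of
#' `n_background` genes with shared dynamics — median-of-ratios
#' normalization assumes a null majority, so a panel of exclusively
#' differential genes would confound induction with sequencing depth. The
#' `de` field of the returned truth flags the focal genes. Size factors
#' are drawn log-uniformly on [2/3, 3/2] to exercise normalization; all
#' replicates run at identical speed (k = 1).
#'
#' @param scenario `"null"` or `"de"`.
#' @param n_genes Number of genes (focal differential genes for `"de"`).
#' @param n_background Shared-dynamics background genes added in the
#'   `"de"` scenario (default `4 * n_genes`).
#' @param seed Integer seed.
#' @param conditions Two condition labels.
#' @param dispersion Variance polynomial coefficients.
#' @param fold Peak fold induction of the `"de"` scenario (default 50).
#' @return A `dynb_sim`.
#' @export
simulate_panel <- function(scenario = c("null", "de"), n_genes = 100L,
                           n_background = 4L * n_genes, seed = 1L,
                           conditions = c("Th0", "Th17"),
                           dispersion = c(0, 1, 0.05), fold = 50) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  times <- c(0, 12, 24, 48, 72)
  design <- expand.grid(replicate = paste0("r", 1:3),
                        condition = conditions, time_h = times,
                        stringsAsFactors = FALSE)
  design$sample_id <- paste(design$condition, design$replicate,
                            paste0("t", design$time_h), sep = "_")
  design <- design[, c("sample_id", "condition", "replicate", "time_h")]
  sf <- stats::setNames(exp(stats::runif(nrow(design), log(2 / 3),
                                         log(3 / 2))),
                        design$sample_id)
  sf <- sf / exp(mean(log(sf)))
  n_total <- if (scenario == "de") n_genes + n_background else n_genes
  templates <- vector("list", n_total)
  names(templates) <- sprintf("g%03d", seq_len(n_total))
  shared_template <- function(i) {
    base <- exp(stats::runif(1L, log(2), log(2000)))
    if (i %% 2L == 0L) make_template("flat", baseline = base)
    else make_template("induction", baseline = base, amplitude = 4 * base,
                       midpoint = 30, slope = 0.12)
  }
  for (i in seq_len(n_total)) {
    if (scenario == "null" || i > n_genes) {
      templates[[i]] <- shared_template(i)  # same dynamics both conditions
    } else {
      base <- exp(stats::runif(1L, log(20), log(2000)))
      templates[[i]] <- stats::setNames(
        list(make_template("flat", baseline = base),
             make_template("induction", baseline = base,
                           amplitude = (fold - 1) * base * 1.2,
                           midpoint = 30, slope = 0.15)),
        conditions)
    }
  }
  simulate_counts(templates, design, sf = sf, dispersion = dispersion,
                  seed = derive_seed(seed, 7L))
}
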