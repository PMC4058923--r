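test_that("harmonic-mean evidence: limiting cases and overflow safety", {
  expect_equal(log_marginal_likelihood(-42.5), -42.5)
  expect_equal(log_marginal_likelihood(rep(-7.3, 500)), -7.3)

  # spreads far beyond exp() range stay finite (log-sum-exp path)
  ll <- c(-1000, -400, -2, -1500)
  expect_true(is.finite(log_marginal_likelihood(ll)))
  # harmonic mean is dominated by the smallest likelihoods
  expect_lt(log_marginal_likelihood(ll), -1490)

  expect_warning(out <- log_marginal_likelihood(c(-5, -Inf, -6)),
                 "-Inf")
  expect_true(is.finite(out))
  expect_error(suppressWarnings(log_marginal_likelihood(c(-Inf, -Inf))))

  # numeric oracle on a small vector
  ll2 <- c(-3, -4.5, -2.2, -8)
  expect_equal(log_marginal_likelihood(ll2),
               -log(mean(exp(-ll2))), tolerance = 1e-12)

  expect_gt(logml_bootstrap_sd(rnorm(300, -50, 3)), 0)
})

test_that("Bayes factor combines the three evidences symmetrically", {
  make_ll_fit <- function(ll) {
    cf <- make_constant_fit(rep(100, 5))
    cf$chains[[1]]$loglik <- rep_len(ll, cf$chains[[1]]$n_iter)
    cf
  }
  fa <- make_ll_fit(c(-10, -11)); fb <- make_ll_fit(c(-20, -21))
  f0 <- make_ll_fit(c(-28, -29))
  expect_equal(as.numeric(bayes_factor(fa, fb, f0)),
               as.numeric(bayes_factor(fb, fa, f0)))
  expect_equal(attr(bayes_factor(fa, fb, f0), "log10"),
               (log_marginal_likelihood(fa) + log_marginal_likelihood(fb) -
                  log_marginal_likelihood(f0)) / log(10))
  # log10 attribute stays finite even when the ratio overflows
  fhuge <- make_ll_fit(-2); ftiny <- make_ll_fit(-4000)
  b <- bayes_factor(fhuge, fhuge, ftiny)
  expect_true(is.infinite(as.numeric(b)) || as.numeric(b) > 1e300)
  expect_true(is.finite(attr(b, "log10")))
  expect_error(bayes_factor(fa, fb), "pooled")
})

test_that("posterior trajectory of a constant chain is the constant", {
  vals <- c(100, 110, 120, 115, 105)
  fit <- make_constant_fit(vals)
  tr <- posterior_trajectory(fit, grid = c(0, 12, 24, 48, 72))
  expect_equal(tr$upper - tr$lower, rep(0, 5))
  # GP conditional with a nugget smooths slightly; means stay close
  expect_equal(tr$mean, vals, tolerance = 0.05)
  expect_warning(posterior_trajectory(fit, grid = c(0, 1000)),
                 "extrapolat")
})

test_that("credible bands cover the generating trajectory", {
  set.seed(33)
  design <- make_design(conditions = "c1")
  times <- c(0, 12, 24, 48, 72)
  inside <- total <- 0
  for (g in 1:50) {
    base <- exp(runif(1, log(30), log(300)))
    tmpl <- if (g %% 2 == 0) make_template("flat", baseline = base)
            else make_template("induction", baseline = base,
                               amplitude = runif(1, 2, 30) * base,
                               midpoint = runif(1, 20, 50), slope = 0.15)
    sim <- simulate_counts(list(gene = tmpl), design, seed = 100 + g)
    fit <- dynb_fit(sim$counts, sim$sheet, gene = "gene", sf = 1,
                    vf = variance_function(c(0, 1, 0.05)),
                    timescale = FALSE,
                    control = dynb_control(n_iter = 1500, burn_in = 400,
                                           chains = 2, seed = g))
    tr <- posterior_trajectory(fit, grid = times)
    ok <- tmpl(times) >= tr$lower & tmpl(times) <= tr$upper
    inside <- inside + sum(ok); total <- total + length(ok)
  }
  expect_gte(inside / total, 0.85)
})

test_that("time-difference posteriors are proper and respect the reference", {
  sim <- fig2_benchmark(seed = 4)
  fit <- dynb_fit(sim$counts, sim$sheet, gene = "IL17A_like", sf = 1,
                  vf = variance_function(sim$truth$dispersion),
                  control = tiny_control(seed = 4))
  for (j in 1:3) {
    p <- timescale_posterior(fit, j)
    expect_equal(sum(p$prob), 1)
    expect_true(all(p$prob >= 0))
  }
  pref <- timescale_posterior(fit, 2)  # reference replicate
  expect_equal(pref$prob[pref$delta == 0], 1)

  fit0 <- dynb_fit(sim$counts, sim$sheet, gene = "IL17A_like", sf = 1,
                   vf = variance_function(sim$truth$dispersion),
                   timescale = FALSE, control = tiny_control(seed = 4))
  expect_error(timescale_posterior(fit0, 1), "disabled")
})

test_that("true time differences are recovered within one grid step", {
  hits <- 0
  truths <- rep(c(-24, -16, 0, 16), 5)
  design <- make_design(conditions = "sim")
  for (i in seq_along(truths)) {
    sim <- simulate_counts(list(g = make_template("induction")), design,
                           true_k = data.frame(condition = "sim",
                                               replicate = "r1",
                                               delta = truths[i]),
                           seed = 300 + i)
    fit <- dynb_fit(sim$counts, sim$sheet, gene = "g", sf = 1,
                    vf = variance_function(c(0, 1, 0.05)),
                    control = dynb_control(n_iter = 6000, burn_in = 1500,
                                           chains = 2, seed = 300 + i))
    dp <- timescale_posterior(fit, 1)
    hits <- hits + (abs(dp$delta[which.max(dp$prob)] - truths[i]) <= 4)
  }
  expect_gte(hits / length(truths), 0.8)
})

test_that("fold changes use pseudocounted trajectory means, folded", {
  f100 <- make_constant_fit(rep(100, 5))
  f50 <- make_constant_fit(rep(50, 5))
  fc <- fold_change(f100, f50, times = c(0, 12, 24, 48, 72))
  expect_equal(unname(fc), rep(101 / 51, 5), tolerance = 0.01)
  # symmetric under swapping and exactly 1 for identical fits
  expect_equal(fold_change(f50, f100), fold_change(f100, f50),
               tolerance = 1e-6)
  expect_equal(unname(fold_change(f100, f100)), rep(1, 5),
               tolerance = 1e-9)
})

test_that("the differential call needs both strong evidence and effect", {
  expect_true(call_differential(15, c(1.2, 3, 1)))
  expect_false(call_differential(9.9, c(100, 2)))
  expect_false(call_differential(1000, c(1.5, 1.2)))
  expect_false(call_differential(10, c(2.5)))   # strict inequality
  expect_false(call_differential(12, c(2)))
})
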