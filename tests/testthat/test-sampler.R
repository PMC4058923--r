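test_that("k moves propose +step/-step/stay with equal probability", {
  set.seed(8)
  moves <- k_move(rep(0, 1e5), step = 4)
  freq <- table(factor(moves, levels = c(-4, 0, 4))) / 1e5
  expect_true(all(abs(freq - 1 / 3) < 0.01))
})

test_that("seeded chains are bit-reproducible and internally consistent", {
  sim <- fig2_benchmark(seed = 3)
  vf <- variance_function(sim$truth$dispersion)
  y <- matrix(sim$counts[1, ], 3, 5, byrow = TRUE)
  times <- c(0, 12, 24, 48, 72)
  pri <- default_priors(as.vector(y))
  args <- list(y = y, times = times, sf = 1, vf = vf, priors = pri,
               n_iter = 400L, burn_in = 100L, reference = 2L, seed = 99L)
  ch1 <- do.call(run_mh, args)
  ch2 <- do.call(run_mh, args)
  expect_identical(ch1$f, ch2$f)
  expect_identical(ch1$theta2, ch2$theta2)
  expect_identical(ch1$delta, ch2$delta)

  # stored log-likelihoods equal recomputation from stored states
  idx <- seq(1, 400, by = 25)
  recomputed <- vapply(idx, function(i)
    joint_log_likelihood(y, matrix(ch1$f[i, ], 3, 5), 1, vf), numeric(1))
  expect_equal(ch1$loglik[idx], recomputed, tolerance = 1e-10)

  # state invariants
  expect_true(all(ch1$f > 0))
  expect_true(all(ch1$theta2 >= 0.5 & ch1$theta2 <= 1))
  expect_true(all(ch1$delta %in% seq(-32, 32, 4)))
  expect_true(all(ch1$delta[, 2] == 0))  # reference replicate never moves
})

test_that("prior-only sampling recovers the theta2 and delta priors", {
  # near-constant counts keep the trajectory proposal small relative to
  # its prior, so theta2/k mixing is not throttled by f rejections
  y <- matrix(c(99L, 101L), 2, 2)
  vf <- variance_function(c(0, 1, 0.05))
  pri <- default_priors(as.vector(y), k_prior = "uniform")
  ch <- run_mh(y, c(0, 24), sf = 1, vf = vf, priors = pri,
               n_iter = 20000L, burn_in = 0L, theta2_sd = 0.2,
               prior_only = TRUE, reference = 1L, seed = 12L)
  expect_lt(ks_uniform(ch$theta2, 0.5, 1), 0.05)

  # delta stays on the grid, covers it, and shows no directional drift
  # (the exact prior-recovery check, at full length, lives in the
  # acceptance suite)
  ch2 <- run_mh(y, c(0, 24), sf = 1, vf = vf, priors = pri,
                n_iter = 30000L, burn_in = 0L, theta2_sd = 0.2,
                prior_only = TRUE, reference = 1L, seed = 13L)
  d <- ch2$delta[, 2]
  expect_true(all(abs(d) <= 32) && all(d %% 4 == 0))
  expect_gte(length(unique(d)), 15L)
  expect_lt(abs(mean(d)), 6)
})

test_that("MH stationary distribution matches a brute-force posterior", {
  # 2 replicates x 2 timepoints, enumerable delta grid; the oracle
  # evidence per delta comes from prior Monte Carlo integration over
  # (f, theta2), wholly independent of the sampler
  set.seed(21)
  times <- c(0, 24)
  y <- matrix(c(60L, 45L, 110L, 150L), 2, 2)
  vf <- variance_function(c(0, 1, 0.05))
  grid <- timescale_grid(t_end = 24, max_shift = 8, step = 4)
  pri <- default_priors(as.vector(y), grid = grid, k_prior = "uniform")

  nug <- 0.5
  muhat <- pmax(as.vector(y), 1)
  nugvec <- nug * variance_at(vf, muhat)
  ## importance sampling from a broad data-centred Gaussian; weights use
  ## the exact GP prior density, so the evidence estimate is unbiased
  n_mc <- 1e5
  q_sd <- 4 * sqrt(variance_at(vf, muhat) + nugvec)
  log_ev <- vapply(seq_len(nrow(grid)), function(gi) {
    delta <- c(0, grid$delta[gi])
    st <- as.vector((1 + delta / 24) %o% times) / 24
    S <- pri$sigma1 * exp(-0.5 * pri$sigma2 * outer(st, st, "-")^2)
    diag(S) <- diag(S) + 1e-6 * pri$sigma1 + nugvec
    U <- chol(S)
    fdraw <- muhat + q_sd * matrix(rnorm(4 * n_mc), 4)
    logw <- rep(-Inf, n_mc)
    ok <- colSums(fdraw <= 0) == 0
    fo <- fdraw[, ok, drop = FALSE]
    v <- variance_at(vf, fo)
    ll <- colSums(matrix(
      dnbinom(as.vector(y), size = fo^2 / (v - fo), mu = fo, log = TRUE),
      4))
    wh <- backsolve(U, fo - pri$m, transpose = TRUE)
    log_prior <- -0.5 * (4 * log(2 * pi) + 2 * sum(log(diag(U))) +
                           colSums(wh^2))
    log_q <- colSums(matrix(
      dnorm(as.vector(fo), rep(muhat, ncol(fo)),
            rep(q_sd, ncol(fo)), log = TRUE), 4))
    logw[ok] <- ll + log_prior - log_q
    m <- max(logw)
    m + log(mean(exp(logw - m)))
  }, numeric(1))
  post <- exp(log_ev - max(log_ev)) * pri$k_prior
  post <- post / sum(post)

  ch <- run_mh(y, times, sf = 1, vf = vf, priors = pri, grid = grid,
               n_iter = 1e5, burn_in = 5000L, reference = 1L, seed = 31L)
  emp <- table(factor(ch$delta[5001:1e5, 2], levels = grid$delta)) /
    (1e5 - 5000)
  expect_lt(tv_dist(as.vector(emp), as.vector(post)), 0.05)
})

test_that("chain dumps round trip through the compressed columnar format", {
  y <- matrix(c(9L, 30L, 12L, 25L), 2, 2)
  ch <- run_mh(y, c(0, 24), sf = 1, vf = variance_function(c(0, 1, 0.05)),
               priors = default_priors(as.vector(y)), n_iter = 120L,
               burn_in = 20L, reference = 1L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_chain(ch, path)
  back <- read_chain(path)
  expect_equal(nrow(back), 120L)
  expect_equal(back$theta2, ch$theta2, tolerance = 1e-9)
  expect_equal(back$loglik, ch$loglik, tolerance = 1e-8)
  expect_equal(back$delta_2, ch$delta[, 2])
  expect_equal(back$f_1_1, ch$f[, 1], tolerance = 1e-8)
})

test_that("PSRF: limiting cases and agreement with the oracle", {
  x <- rnorm(500)
  expect_lte(psrf(cbind(x, x)), 1 + 1e-9)
  expect_gt(psrf(cbind(rnorm(500), rnorm(500, 10))), 3)
  set.seed(9)
  for (i in 1:5) {
    draws <- matrix(rnorm(400 * 4, sd = runif(1, 0.5, 2)), 400, 4)
    expect_equal(psrf(draws), oracle_psrf(draws), tolerance = 1e-10)
  }
  expect_error(psrf(matrix(1:10, 10, 1)), "at least 2 chains")
})
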