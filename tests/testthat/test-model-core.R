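test_that("squared exponential kernel closed forms and symmetry", {
  expect_equal(se_kernel(5, 5, theta1 = 3.2, theta2 = 0.7), 3.2)
  expect_equal(se_kernel(0, 1, theta1 = 1, theta2 = 1), exp(-0.5))
  set.seed(3)
  a <- runif(20, 0, 72); b <- runif(20, 0, 72)
  expect_equal(se_kernel(a, b, 2, 0.6), se_kernel(b, a, 2, 0.6))
  expect_error(se_kernel(0, 1, -1, 1), "positive")
  expect_error(se_kernel(0, 1, 1, 0), "positive")
})

test_that("GP covariance matrices are symmetric positive definite", {
  K1 <- gp_covariance(5, theta1 = 2, theta2 = 0.75)
  expect_equal(dim(K1), c(1L, 1L))
  expect_equal(K1[1, 1], 2 + 2e-6)

  K <- gp_covariance(c(0, 12, 24, 48, 72), 1, 0.75)
  expect_true(all(eigen(K, symmetric = TRUE)$values > 0))

  # across the prior support and random grids up to 20 points
  set.seed(4)
  for (rep in 1:25) {
    times <- sort(runif(sample(2:20, 1), 0, 72))
    th2 <- runif(1, 0.5, 1)
    K <- gp_covariance(times, theta1 = 10^runif(1, 0, 6), theta2 = th2)
    expect_equal(K, t(K))
    expect_true(all(eigen(K, symmetric = TRUE)$values > 0))
  }

  # large theta2: off-diagonals vanish
  Kd <- gp_covariance(c(0, 12, 24), 1, 1e4)
  expect_lt(max(abs(Kd[upper.tri(Kd)])), 1e-12)
})

test_that("NB moment parameterization matches its defining moments", {
  p1 <- nb_params_from_moments(2, 4)
  expect_equal(p1$p, 0.5); expect_equal(p1$r, 2)
  p2 <- nb_params_from_moments(10, 20)
  expect_equal(p2$p, 0.5); expect_equal(p2$r, 10)
  expect_error(nb_params_from_moments(10, 10), "overdispersion|exceed")

  # brute-force enumeration: pmf mean and variance hit (mu, sigma2)
  for (case in list(c(5, 10), c(2, 4), c(100, 180))) {
    y <- 0:1e5
    pmf <- exp(nb_log_pmf(y, case[1], case[2]))
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    expect_equal(sum(y * pmf), case[1], tolerance = 1e-8)
    expect_equal(sum(y^2 * pmf) - sum(y * pmf)^2, case[2],
                 tolerance = 1e-6)
  }
})

test_that("NB log pmf matches the lgamma oracle and the Poisson limit", {
  expect_equal(nb_log_pmf(3, 2, 4), oracle_nb_log_pmf(3, 2, 4),
               tolerance = 1e-12)
  set.seed(5)
  y <- rpois(30, 20); mu <- runif(30, 1, 50); s2 <- mu * runif(30, 1.2, 3)
  expect_equal(nb_log_pmf(y, mu, s2), oracle_nb_log_pmf(y, mu, s2),
               tolerance = 1e-10)

  # mode near round(mu)
  lp <- nb_log_pmf(0:500, 100, 150)
  expect_lt(abs(which.max(lp) - 1 - 100), 2)

  # sigma2 -> mu recovers Poisson
  for (mu in c(1, 10, 100)) {
    y <- 0:(mu * 4)
    expect_equal(nb_log_pmf(y, mu, mu * (1 + 1e-6)),
                 dpois(y, mu, log = TRUE), tolerance = 1e-3)
  }
})

test_that("time rescaling reproduces the printed extreme factors", {
  times <- c(0, 12, 24, 48, 72)
  expect_equal(scaled_times(times, 1), times)
  expect_equal(scaled_times(72, 5 / 9), 40)   # -32 h at 72 h
  expect_equal(scaled_times(72, 13 / 9), 104) # +32 h at 72 h
  expect_equal(scaled_times(72, 2, convention = "divide"), 36)
  expect_error(scaled_times(times, 0), "positive")

  grid <- timescale_grid(72, 32, 4)
  expect_equal(nrow(grid), 17L)
  expect_equal(min(grid$k), 5 / 9)
  expect_equal(max(grid$k), 13 / 9)
  expect_true(any(grid$delta == 0 & grid$k == 1))
  expect_error(timescale_grid(72, 32, 5), "divide")
  expect_error(timescale_grid(30, 32, 4), "exceed")
})

test_that("joint log-likelihood reduces, factorizes, and matches the oracle", {
  vf <- variance_function(c(0, 1, 0.05))
  expect_equal(joint_log_likelihood(7, 6.5, 1, vf),
               nb_log_pmf(7, 6.5, variance_at(vf, 6.5)))

  # tied replicates factorize
  y1 <- matrix(c(5, 9, 40), 1); f1 <- matrix(c(6, 10, 35), 1)
  y3 <- y1[rep(1, 3), ]; f3 <- f1[rep(1, 3), ]
  expect_equal(joint_log_likelihood(y3, f3, 1, vf),
               3 * joint_log_likelihood(y1, f1, 1, vf))

  set.seed(6)
  for (i in 1:10) {
    M <- sample(2:4, 1); N <- sample(2:5, 1)
    y <- matrix(rpois(M * N, 30), M, N)
    f <- matrix(runif(M * N, 5, 60), M, N)
    sf <- matrix(runif(M * N, 0.5, 2), M, N)
    expect_equal(joint_log_likelihood(y, f, sf, vf),
                 oracle_joint_loglik(y, f, sf, vf), tolerance = 1e-12)
    # permutation of replicate rows (all k equal) leaves it unchanged
    perm <- sample(M)
    expect_equal(joint_log_likelihood(y[perm, ], f[perm, ], sf[perm, ], vf),
                 joint_log_likelihood(y, f, sf, vf))
  }

  f_bad <- matrix(c(-1, 5, 5, 5), 2, 2)
  expect_identical(joint_log_likelihood(matrix(1, 2, 2), f_bad, 1, vf),
                   -Inf)
})

test_that("default priors implement the gene-specific rules", {
  y <- c(0, 10, 40, 100, 60)
  pri <- default_priors(y)
  expect_equal(pri$m, 50)
  expect_equal(pri$sigma1, 25000)  # 500 * mid-range dominates small ranges
  expect_equal(pri$theta1, 10 * sd(y))
  expect_equal(pri$theta2_range, c(0.5, 1))
  expect_equal(pri$sigma2, 0.75)

  # wide-range gene: prior sd covers half the count swing
  yy <- c(100, 120, 300, 20000, 1e5)
  expect_equal(default_priors(yy)$sigma1, ((1e5 - 100) / 2)^2)

  # constant gene: sd floor keeps the proposal non-degenerate
  expect_equal(default_priors(rep(7, 10))$theta1, 10)

  # k prior: proper and symmetric
  expect_equal(sum(pri$k_prior), 1)
  d <- as.numeric(names(pri$k_prior))
  expect_equal(pri$k_prior[as.character(d)], pri$k_prior[as.character(-d)],
               ignore_attr = TRUE)
  pu <- default_priors(y, k_prior = "uniform")
  expect_equal(unname(pu$k_prior), rep(1 / 17, 17))

  expect_error(default_priors(numeric(0)), "empty")
})
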