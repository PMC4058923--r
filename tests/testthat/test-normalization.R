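test_that("size factors: symmetry, analytic doubling, scale equivariance", {
  m <- matrix(rpois(40, 50) + 1, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  same <- m; same[] <- rep(m[, 1], 4)
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 4))

  doubled <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(2)
  scaled <- m; scaled[, 3] <- scaled[, 3] * 5
  sf0 <- estimate_size_factors(m); sf1 <- estimate_size_factors(scaled)
  expect_equal(unname((sf1[3] / sf1[1]) / (sf0[3] / sf0[1])), 5,
               tolerance = 1e-12)
})

test_that("size factors match the independent median-of-ratios oracle", {
  set.seed(42)
  # odd gene count: the median is a data point, so the ratio-scale and
  # log-scale medians coincide exactly
  m <- matrix(rpois(306, 80) + 1, 51, 6,
              dimnames = list(paste0("g", 1:51), paste0("s", 1:6)))
  expect_equal(estimate_size_factors(m), oracle_size_factors(m),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference estimator", {
  set.seed(7)
  m <- matrix(rnbinom(600, mu = 60, size = 5), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # both are median-of-ratios; normalizations differ, so compare ratios
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]),
               tolerance = 1e-10)
})

test_that("all-zero-overlap matrices suggest the pseudo-reference fallback", {
  m <- matrix(c(0, 5, 3, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(m), "pseudo-reference")
})

test_that("variance polynomial is recovered from simulated overdispersion", {
  set.seed(10)
  n_genes <- 2000
  design <- make_design()
  templates <- lapply(exp(runif(n_genes, log(1), log(1e4))),
                      function(b) make_template("flat", baseline = b))
  names(templates) <- sprintf("g%04d", seq_len(n_genes))
  sim <- simulate_counts(templates, design, dispersion = c(0, 1, 0.1),
                         seed = 11)
  vf <- fit_variance_function(sim$counts, sim$sheet,
                              sf = sim$truth$sf)
  expect_lt(abs(vf$coefficients[2] - 1), 0.1)
  expect_lt(abs(vf$coefficients[3] - 0.1), 0.01)
  expect_lt(abs(vf$coefficients[1]), 5)

  # the raw-scale least-squares option stays available and recovers the
  # dominant overdispersion coefficient (its linear term is noisier)
  vfl <- fit_variance_function(sim$counts, sim$sheet, sf = sim$truth$sf,
                               method = "ls")
  expect_lt(abs(vfl$coefficients[3] - 0.1), 0.015)

  simp <- simulate_counts(templates, design, dispersion = c(0, 1, 0),
                          seed = 12)
  vfp <- fit_variance_function(simp$counts, simp$sheet,
                               sf = simp$truth$sf)
  expect_lt(abs(vfp$coefficients[3]), 0.01)
})

test_that("the overdispersion floor keeps the NB defined", {
  design <- make_design()
  counts <- matrix(100, 12, 30,
                   dimnames = list(paste0("g", 1:12), design$sample_id))
  vf <- fit_variance_function(counts, design, sf = rep(1, 30) |>
                                setNames(design$sample_id))
  # constant replicates: fitted variance collapses, floor takes over
  expect_equal(variance_at(vf, 100), 100 * 1.01)
  mus <- 10^seq(-2, 5, length.out = 100)
  expect_true(all(variance_at(vf, mus) > mus))
})

test_that("variance_at evaluates the polynomial with its floor", {
  vf <- variance_function(c(0, 1, 0.1))
  expect_equal(variance_at(vf, 10), 20)
  vf2 <- variance_function(c(0, 0.5, 0), epsilon = 0.01)
  expect_equal(variance_at(vf2, 10), 10.1)
  expect_error(variance_at(vf, -1), "positive")
  # monotone for non-negative coefficients
  grid <- seq(0.1, 1e4, length.out = 500)
  expect_true(all(diff(variance_at(vf, grid)) > 0))
})

test_that("normalization results round trip through the JSON sidecar", {
  sf <- c(s1 = 0.8, s2 = 1.25)
  vf <- variance_function(c(1.5, 1.1, 0.07), epsilon = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization(sf, vf, path)
  back <- read_normalization(path)
  expect_equal(back$sf, sf)
  expect_equal(back$vf$coefficients, vf$coefficients)
  expect_equal(back$vf$epsilon, 0.02)
})
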