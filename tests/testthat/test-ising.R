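test_that("potential evaluates the Ising energy and its symmetries", {
  # null landscape: every pattern has zero potential
  fl <- list(alpha = rep(0, 4), beta = rep(0, 3))
  expect_equal(potential(fl, c(1, 0, 1, 1)), 0)

  # direct evaluation: alpha = (1, 1), beta = 0.5, pattern (1, 1)
  fl2 <- list(alpha = c(1, 1), beta = 0.5)
  expect_equal(potential(fl2, c(1, 1)), -2.5)

  # negating the fields maps V(x) to V(complement of x)
  set.seed(1)
  for (i in 1:10) {
    N <- sample(2:8, 1)
    fl <- random_fields(N)
    x <- sample(0:1, N, replace = TRUE)
    neg <- list(alpha = -fl$alpha, beta = fl$beta)
    expect_equal(potential(neg, x), potential(fl, 1 - x))
  }

  expect_error(potential(fl2, c(1, 0, 1)), "length")
})

test_that("log partition function matches closed forms and enumeration", {
  expect_equal(log_partition(list(alpha = rep(0, 6), beta = rep(0, 5))),
               6 * log(2))
  # single site: Z = e^alpha + e^-alpha
  expect_equal(log_partition(list(alpha = 1, beta = numeric(0))),
               log(exp(1) + exp(-1)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    fl <- random_fields(8)
    or <- enum_landscape(fl$alpha, fl$beta)
    expect_equal(log_partition(fl), or$logZ, tolerance = 1e-10)
  }
})

test_that("read marginals sum out unobserved and uncovered sites exactly", {
  # uniform landscape: any two observed calls have probability 1/4
  fl <- list(alpha = rep(0, 2), beta = 0)
  expect_equal(read_loglikelihood(fl, 1, "MU"), log(1 / 4))
  fl3 <- list(alpha = rep(0, 3), beta = rep(0, 2))
  expect_equal(read_loglikelihood(fl3, 1, "M.U"), log(1 / 4))

  set.seed(3)
  for (i in 1:20) {
    N <- sample(2:8, 1)
    fl <- random_fields(N)
    or <- enum_landscape(fl$alpha, fl$beta)
    len <- sample(1:N, 1)
    first <- sample(N - len + 1, 1)
    calls <- paste(sample(c("M", "U", "."), len, replace = TRUE,
                          prob = c(0.4, 0.4, 0.2)), collapse = "")
    calls <- sub("^\\.+", "", calls)
    calls <- sub("\\.+$", "", calls)
    if (nchar(calls) == 0) next
    first <- min(first, N - nchar(calls) + 1)
    expect_equal(exp(read_loglikelihood(fl, first, calls)),
                 oracle_read_marginal(or, first, calls),
                 tolerance = 1e-10)
  }
})

test_that("level distributions are exact, normalized, and symmetric", {
  # i.i.d. fair sites
  fl <- list(alpha = rep(0, 2), beta = 0)
  expect_equal(as.numeric(level_distribution(fl)), c(0.25, 0.5, 0.25))

  # saturated field concentrates all mass at full methylation
  fl_sat <- list(alpha = rep(10, 5), beta = rep(0, 4))
  p <- level_distribution(fl_sat)
  expect_gt(p[length(p)], 0.999)

  set.seed(4)
  for (i in 1:15) {
    N <- 10
    fl <- random_fields(N)
    or <- enum_landscape(fl$alpha, fl$beta)
    subset <- sort(sample(N, 5))
    p <- level_distribution(fl, subset)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(as.numeric(p), oracle_level_dist(or, subset),
                 tolerance = 1e-10)
    # negating the field reverses the level distribution
    p_neg <- level_distribution(list(alpha = -fl$alpha, beta = fl$beta),
                                subset)
    expect_equal(as.numeric(p_neg), rev(as.numeric(p)), tolerance = 1e-10)
  }
})

test_that("MML is strictly increasing in the field intercept", {
  gaps <- rep(50, 9)
  rho <- rep(0.2, 10)
  grid <- seq(-4, 4, by = 0.5)
  vals <- vapply(grid, function(a) {
    fl <- ising_fields(list(a = a, b = 0, c = 0), rho, gaps)
    mml(level_distribution(fl))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("maximum-likelihood fit recovers symmetric and saturated cases", {
  map <- tiny_map(seq(101, by = 40, length.out = 10))
  partition <- partition_genome(map, est_span = 600, sub_span = 150)
  reg <- partition$regions[1, ]
  # equal counts of all-M and all-U patterns: symmetric likelihood in a
  n_each <- 1000
  reads <- structure(
    data.frame(chrom = "chr1",
               read_id = paste0("r", 1:(2 * n_each)),
               first = 1L,
               calls = rep(c(strrep("M", 10), strrep("U", 10)), n_each),
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"))
  rr <- assemble_region_reads(reads, map, partition)[[1]]
  expect_equal(rr$n_frag, 2 * n_each)
  cov_rho <- map$sites$rho
  cov_gaps <- diff(map$sites$pos)
  fit <- fit_parameters(rr, cov_rho, cov_gaps,
                        start_grid = ising_start_grid(c(-5, 0, 5), 0,
                                                      c(-10, 0, 10)),
                        fix_b = TRUE)
  expect_lt(abs(fit$params$a), 0.05)
  expect_equal(fit$params$b, 0)

  # all reads fully methylated: a runs to the +10 box bound
  reads_m <- reads
  reads_m$calls <- strrep("M", 10)
  rr_m <- assemble_region_reads(reads_m, map, partition)[[1]]
  fit_m <- fit_parameters(rr_m, cov_rho, cov_gaps)
  expect_equal(fit_m$params$a, 10)
})

test_that("compiled Nelder-Mead agrees with stats::optim on the likelihood", {
  map <- tiny_map(seq(101, by = 60, length.out = 8))
  partition <- partition_genome(map, est_span = 600, sub_span = 150)
  sim <- simulate_reads(map, partition,
                        data.frame(region_id = 1, a = 0.8, b = 0, c = 1.5),
                        depth = 30, read_span = 5, miss_rate = 0.05,
                        seed = 9)
  rr <- assemble_region_reads(sim$reads, map, partition)[[1]]
  rho <- map$sites$rho
  gaps <- pmin(diff(map$sites$pos), 1000)
  fit <- fit_parameters(rr, rho, gaps)

  negll <- function(par) {
    par <- pmax(pmin(par, c(10, 10, 20)), c(-10, -10, -20))
    alpha <- par[1] + par[2] * rho
    -methpel:::cpp_total_loglik(alpha, par[3] / gaps, rr$starts, rr$lens,
                                rr$calls, rr$counts)
  }
  ref <- Inf
  for (s in seq_len(nrow(ising_start_grid()))) {
    r <- stats::optim(ising_start_grid()[s, ], negll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 2000))
    ref <- min(ref, r$value)
  }
  expect_equal(fit$logL, -ref, tolerance = 1e-4)
})

test_that("parameter recovery on the density-contrast region is accurate", {
  rec <- cached_recovery()
  err <- abs(sweep(rec$estimates, 2, rec$truth))
  # intercept recovery is tight; the module-level requirement
  expect_lt(median(err[, "a"]), 0.15)
})
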