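test_that("mode detection resolves unimodal and well-separated bimodal data", {
  set.seed(11)
  uni <- dental_distribution(values = rnorm(5000, 18.9, 2.9))
  m1 <- estimate_modes(uni)
  expect_length(m1$locations, 1)
  expect_lt(abs(m1$locations - 18.9), 0.5)

  bi <- dental_distribution(values = c(rnorm(2500, 10, 1), rnorm(2500, 20, 1)))
  m2 <- estimate_modes(bi)
  expect_length(m2$locations, 2)
  expect_lt(abs(m2$locations[1] - 10), 0.5)
  expect_lt(abs(m2$locations[2] - 20), 0.5)

  flat <- dental_distribution(values = rep(7.5, 60))
  m3 <- estimate_modes(flat)
  expect_equal(m3$locations, 7.5)

  expect_error(estimate_modes(dental_distribution(values = rep(c(1, 2), 5))),
               "20")
})

test_that("mode count of a histogram is invariant to count rescaling", {
  set.seed(3)
  x <- c(rnorm(3000, 11, 1.2), rnorm(3000, 19, 1.5))
  h <- hist(x, breaks = seq(0, 30, by = 0.5), plot = FALSE)
  d1 <- dental_distribution(edges_mm = h$breaks, counts = h$counts)
  d2 <- dental_distribution(edges_mm = h$breaks, counts = h$counts * 7)
  expect_identical(length(estimate_modes(d1)$locations),
                   length(estimate_modes(d2)$locations))
  expect_equal(as.numeric(compute_shape_vector(d1)),
               as.numeric(compute_shape_vector(d2)), tolerance = 1e-12)
})

test_that("shape vector recovers Gaussian and mixture geometry", {
  set.seed(21)
  mu <- 18
  sg <- 3
  g <- dental_distribution(values = rnorm(20000, mu, sg))
  sv <- compute_shape_vector(g)
  expect_equal(sv[["p25"]], mu - 0.6745 * sg, tolerance = 0.02)
  expect_equal(sv[["p50"]], mu, tolerance = 0.02)
  expect_equal(sv[["p75"]], mu + 0.6745 * sg, tolerance = 0.02)
  expect_equal(sv[["n_modes"]], 1)
  expect_identical(sv[["delta_mode"]], 0)

  mix <- dental_distribution(values = c(rnorm(2500, 10, 1),
                                        rnorm(2500, 20, 1)))
  sm <- compute_shape_vector(mix)
  expect_equal(sm[["n_modes"]], 2)
  expect_equal(sm[["delta_mode"]], 10, tolerance = 1)
})

test_that("shape vector invariants hold across random samples", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(50:500, 1)
    x <- exp(rnorm(n, log(15), runif(1, 0.05, 0.4)))
    sv <- compute_shape_vector(dental_distribution(values = x))
    expect_true(sv[["variance"]] >= 0)
    expect_true(sv[["p25"]] <= sv[["p50"]] && sv[["p50"]] <= sv[["p75"]])
    expect_true(sv[["n_modes"]] >= 1)
    expect_true(sv[["delta_mode"]] >= 0)
    expect_identical(sv[["delta_mode"]] == 0, sv[["n_modes"]] == 1)
  }
})

test_that("epsilon obeys its identities and the zero-denominator rule", {
  obs <- c(mean = 16, variance = 8, p25 = 4, p50 = 2, p75 = 1,
           n_modes = 1, delta_mode = 2)
  expect_identical(as.numeric(error_epsilon(obs, obs)), 0)
  expect_equal(as.numeric(error_epsilon(1.5 * obs, obs)), 3.5,
               tolerance = 1e-12)
  # monotone in each component deviation
  worse <- obs + c(2, 0, 0, 0, 0, 0, 0)
  worst <- obs + c(4, 0, 0, 0, 0, 0, 0)
  expect_lt(error_epsilon(worse, obs), error_epsilon(worst, obs))
  # unimodal observed distribution: delta_mode denominator floored at 0.1
  obs0 <- obs
  obs0["delta_mode"] <- 0
  sim <- obs0
  sim["delta_mode"] <- 2
  eps <- error_epsilon(sim, obs0)
  expect_equal(as.numeric(eps), abs(2 - 0) / 0.1, tolerance = 1e-12)
  expect_true(7 %in% attr(eps, "floored"))
})

test_that("bootstrap spread matches the s/sqrt(n) closed form", {
  set.seed(7)
  d <- dental_distribution(values = rnorm(400, 14, 3.4))
  tab <- bootstrap_shape_uncertainty(d, B = 400, seed = 2)
  se_mean <- tab$se[tab$parameter == "mean"]
  expect_equal(se_mean, sd(d$values) / sqrt(400), tolerance = 0.2)
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  expect_error(bootstrap_shape_uncertainty(d, B = 50), "100")
})

test_that("degenerate and fossil-scale samples bootstrap sensibly", {
  same <- dental_distribution(values = rep(12.5, 50))
  tab0 <- bootstrap_shape_uncertainty(same, B = 100, seed = 1)
  expect_true(all(tab0$se == 0))
  # at the sample size and spread of the Arctic assemblage, the mean and
  # median are pinned down well below half a millimetre
  banks <- generate_mixture_sample(locality_mixture_spec("banks_island"))
  tab <- bootstrap_shape_uncertainty(banks, B = 300, seed = 3)
  expect_lt(tab$se[tab$parameter == "mean"], 0.5)
  expect_lt(tab$se[tab$parameter == "p50"], 0.5)
})
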