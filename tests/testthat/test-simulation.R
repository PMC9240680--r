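test_that("juvenile dispersal rate is a logistic in mass", {
  disp <- dispersal_params(m_j = 50000, xi_j = 4000, k_j_max = 0.06)
  expect_equal(juvenile_dispersal_rate(50000, disp), 0.03)
  expect_equal(juvenile_dispersal_rate(54000, disp),
               0.06 / (1 + exp(-1)), tolerance = 1e-12)
  m <- seq(1000, 160000, length.out = 100)
  expect_true(all(diff(juvenile_dispersal_rate(m, disp)) > 0))
  # tight window approaches a step: the logistic tail is e^(-x) at x windows
  # below threshold, negligible within a few hundred grams when xi_j is small
  strict <- dispersal_params(m_j = 50000, xi_j = 10, k_j_max = 0.06)
  expect_lt(juvenile_dispersal_rate(50000 - 100, strict),
            exp(-10) * 1.01 * 0.06)
  expect_lt(juvenile_dispersal_rate(50000 - 200, strict), 1e-8 * 0.06)
})

test_that("adult dispersal pulse peaks on t_peak and integrates to k_a_annual", {
  disp <- dispersal_params(t_peak = 130, xi_a = 18, k_a_annual = 2.5)
  t <- seq(0, 364.75, by = 0.25)
  rate <- adult_dispersal_rate(t, disp)
  expect_equal(t[which.max(rate)], 130)
  expect_equal(adult_dispersal_rate(t, disp),
               adult_dispersal_rate(t + 365, disp), tolerance = 1e-12)
  annual <- integrate(function(x) adult_dispersal_rate(x, disp), 0, 365,
                      subdivisions = 2000)$value
  expect_equal(annual, 2.5, tolerance = 1e-3)
  # wide window still integrates to the configured migrations/year
  wide <- dispersal_params(t_peak = 130, xi_a = 100, k_a_annual = 1)
  annual_w <- integrate(function(x) adult_dispersal_rate(x, wide), 0, 365,
                        subdivisions = 2000)$value
  expect_equal(annual_w, 1, tolerance = 1e-3)
})

test_that("with only mortality acting, decay is exactly exponential", {
  cfg <- default_config()
  cfg$demography <- demography_params(r = 0)
  cfg$dispersal$k_j_max <- 0
  cfg$dispersal$k_a_annual <- 0
  cfg$grid$n_years <- 10
  cfg$grid$burn_in_years <- 0
  res <- run_simulation(cfg)
  expected <- exp(-cfg$demography$mu * 10 * 365)
  expect_equal(total_abundance(res$state), expected, tolerance = 1e-8)
})

test_that("two-bin toy dynamics match the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  st <- population_state(c(1000, 2000, 4000), n_delay = 0)
  st$juv <- c(3, 2)
  st$adult <- c(0.5, 1)
  demo <- demography_params(r = 0, mu = 0.01)
  disp <- dispersal_params(m_j = 2000, xi_j = 1500, k_j_max = 0.04,
                           k_a_annual = 0)
  growth <- growth_params(m0 = 1100, M = 1e9, a_ref = 1e-12)
  dt <- 2.5e-4
  t_end <- 5
  s <- st
  for (k in seq_len(t_end / dt)) {
    s <- step_population(s, dt, constant_envs(15), demo, disp, growth)
  }
  k1 <- juvenile_dispersal_rate(s$centers[1], disp)
  k2 <- juvenile_dispersal_rate(s$centers[2], disp)
  A <- rbind(c(-0.01 - k1, 0, 0, 0),
             c(0, -0.01 - k2, 0, 0),
             c(k1, 0, -0.01, 0),
             c(0, k2, 0, -0.01))
  oracle <- as.numeric(Matrix::expm(A * t_end) %*% c(3, 2, 0.5, 1))
  expect_equal(c(s$juv, s$adult), oracle, tolerance = 1e-6)
})

test_that("supercritical nursery grows when dispersal is off", {
  cfg <- default_config()
  # maturation just above newborn mass so residents reproduce, no dispersal
  cfg$dispersal <- dispersal_params(m_j = 6000, xi_j = 500, k_j_max = 0,
                                    k_a_annual = 0)
  cfg$grid$n_years <- 8
  cfg$grid$burn_in_years <- 0
  res <- run_simulation(cfg)
  expect_true(all(diff(res$trajectory$juvenile[3:8]) > 0))
})

test_that("simulation is deterministic and abundances stay non-negative", {
  cfg <- short_config()
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$accumulator$counts, r2$accumulator$counts)
  expect_true(all(r1$accumulator$counts >= 0))
  expect_true(all(r1$state$juv >= 0) && all(r1$state$adult >= 0) &&
                all(r1$state$visit >= 0))
})

test_that("CFL violations raise named errors", {
  st <- population_state(exp(seq(log(2650), log(168840), length.out = 31)))
  st$juv[1] <- 1
  demo <- demography_params()
  growth <- growth_params()
  fast <- dispersal_params(k_j_max = 0.5)
  expect_error(step_population(st, 1000, constant_envs(24), demo, fast,
                               growth), "growth advection")
  expect_error(step_population(st, 3, constant_envs(15), demo, fast, growth),
               "juvenile dispersal")
  pulse <- dispersal_params(xi_a = 1, k_a_annual = 300)
  st$time <- pulse$t_peak
  expect_error(step_population(st, 1, constant_envs(15), demo, pulse, growth),
               "adult dispersal")
})

test_that("tooth accumulation scales with rate but not in shape", {
  st <- population_state(exp(seq(log(2650), log(168840), length.out = 31)))
  st$juv <- seq_along(st$centers) * 1.0
  st$adult <- rev(st$juv)
  allom <- allometry_params()
  edges <- seq(0, 30, by = 0.5)
  a1 <- accumulate_teeth(st, 1, shedding_model(base_rate = 0.05), allom,
                         tooth_accumulator(edges))
  a2 <- accumulate_teeth(st, 1, shedding_model(base_rate = 0.10), allom,
                         tooth_accumulator(edges))
  expect_identical(normalized_counts(a1), normalized_counts(a2))
  expect_equal(a2$counts, 2 * a1$counts)
  # empty population leaves the accumulator empty
  empty <- population_state(st$edges)
  a0 <- accumulate_teeth(empty, 1, shedding_model(), allom,
                         tooth_accumulator(edges))
  expect_true(all(a0$counts == 0))
})

test_that("halving the time step barely changes the dental distributions", {
  cfg <- short_config()
  r1 <- run_simulation(cfg)
  cfg$grid$dt <- 0.5
  r2 <- run_simulation(cfg)
  n1 <- normalized_counts(r1$accumulator)
  n2 <- normalized_counts(r2$accumulator)
  expect_lt(tv_distance(n1["juvenile", ], n2["juvenile", ]), 0.01)
  expect_lt(tv_distance(n1["adult", ], n2["adult", ]), 0.01)
})
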