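test_that("self-match against a grid simulation gives exactly zero error", {
  sims <- cached_short_sims()
  grid <- sims$grid
  idx <- 5 # centre of the 3x3 grid
  obs <- sims$shapes_j[[idx]]
  surf <- compute_error_surface(obs, sims = sims)
  expect_identical(surf$epsilon_j[2, 2], 0)
  expect_true(all(surf$epsilon_j[-5] > 0))
  # determinism: recomputation gives identical matrices
  surf2 <- compute_error_surface(obs, sims = sims)
  expect_identical(surf$epsilon_j, surf2$epsilon_j)
  expect_identical(surf$epsilon_a, surf2$epsilon_a)
})

test_that("surface minimum equals a brute-force recomputation", {
  sims <- cached_short_sims()
  obs <- sims$shapes_a[[7]]
  surf <- compute_error_surface(obs, sims = sims)
  brute <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      brute[i, j] <- error_epsilon(sims$shapes_a[[(i - 1) * 3 + j]], obs)
    }
  }
  expect_equal(surf$epsilon_a, brute)
  fit <- classify_site(surf)
  best <- which(brute == min(brute), arr.ind = TRUE)
  expect_equal(fit$best_index, as.integer(best[1, ]))
})

make_surface <- function(eps_j, eps_a) {
  g <- dispersal_grid(c(100, 1000, 10000), c(1, 10, 100))
  structure(list(grid = g,
                 epsilon_j = matrix(eps_j, 3, 3),
                 epsilon_a = matrix(eps_a, 3, 3),
                 failures = 0),
            class = "error_surface")
}

test_that("classification reproduces the study's site calls from minima", {
  # contemporary mid-Atlantic aggregation: clear adult site
  delaware <- classify_site(make_surface(1.4, 0.74))
  expect_equal(delaware$site_identity, "adult")
  expect_false(delaware$ambiguous)
  # Antarctic shelf assemblage: nominally juvenile but within the ambiguity
  # band
  seymour <- classify_site(make_surface(0.36, 0.40))
  expect_equal(seymour$site_identity, "juvenile")
  expect_true(seymour$ambiguous)
  # exact tie
  tie <- classify_site(make_surface(0.5, 0.5))
  expect_equal(tie$site_identity, "ambiguous")
  expect_true(tie$ambiguous)
})

test_that("classification is invariant to rescaling both surfaces", {
  s1 <- make_surface(c(2, 1.5, 3, 2, 2, 2, 2, 2, 2),
                     c(3, 3, 3, 3, 2.5, 3, 3, 3, 3))
  f1 <- classify_site(s1)
  s2 <- s1
  s2$epsilon_j <- 10 * s1$epsilon_j
  s2$epsilon_a <- 10 * s1$epsilon_a
  f2 <- classify_site(s2)
  expect_equal(f1$site_identity, f2$site_identity)
  expect_equal(f1$ambiguous, f2$ambiguous)
  expect_equal(f1$best_index, f2$best_index)
})

test_that("argmin ties break toward stricter (smaller) windows", {
  fit <- classify_site(make_surface(1, 2))
  expect_equal(fit$best_index, c(1L, 1L))
  expect_equal(fit$best_xi_j, 100)
  expect_equal(fit$best_xi_a, 1)
})

test_that("error bands step in 10% increments above the minimum", {
  flat <- make_surface(2, 3)
  bands <- error_contours(flat)
  expect_true(all(bands$band_j == 0L))
  graded <- make_surface(c(1, 1.05, 1.15, 1.25, 1.7, 2.2, 1, 1, 1), 1)
  bj <- error_contours(graded)$band_j
  expect_equal(bj[1, 1], 0L)
  expect_equal(bj[2, 1], 0L) # 1.05x the minimum is inside the first band
  expect_equal(bj[3, 1], 1L) # 1.15x falls in the second
  expect_equal(bj[1, 2], 2L)
  # a monotone ridge gets nondecreasing band indices
  ridge <- make_surface(c(1, 1.12, 1.31, 1.55, 1.74, 1.96, 2.2, 2.5, 2.9), 1)
  expect_true(all(diff(c(error_contours(ridge)$band_j)) >= 0))
})

test_that("parameter recovery finds a mid-grid truth on the short config", {
  sims <- cached_short_sims()
  grid <- sims$grid
  hits <- 0
  for (s in 1:5) {
    r <- recover_parameters(grid$xi_j_values[2], grid$xi_a_values[2],
                            "adult", short_config(), grid,
                            n_teeth = 4000, seed = s, sims = sims)
    hits <- hits + (r$identity_correct && r$grid_error <= 1)
  }
  expect_gte(hits, 4)
})

test_that("larger samples recover parameters at least as well on average", {
  sims <- cached_short_sims()
  grid <- sims$grid
  err_at <- function(n) {
    mean(vapply(1:6, function(s) {
      recover_parameters(grid$xi_j_values[2], grid$xi_a_values[2], "adult",
                         short_config(), grid, n_teeth = n, seed = s,
                         sims = sims)$grid_error
    }, numeric(1)))
  }
  expect_lte(err_at(4000), err_at(150))
})
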