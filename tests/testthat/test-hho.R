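test_that("search space validates bounds and clip clamps component-wise", {
  sp <- search_space(c(0, -1), c(1, 1))
  expect_equal(sp$dim, 2)
  expect_error(search_space(1, 1, dim = 2), "strictly below")

  sp <- search_space(0, 1, dim = 3)
  expect_equal(clip_to_bounds(c(0.2, 0.5, 0.9), sp), c(0.2, 0.5, 0.9))
  expect_equal(clip_to_bounds(rep(-5, 3), sp), rep(0, 3))
  set.seed(1)
  for (i in 1:20) {
    x <- runif(5, -3, 3)
    sp5 <- search_space(-1, 1, dim = 5)
    expect_equal(clip_to_bounds(x, sp5), pmin(pmax(x, -1), 1))
  }
})

test_that("escaping energy follows the linear envelope", {
  expect_equal(escaping_energy(0.73, 10, 10), 0)
  expect_equal(escaping_energy(0.5, 0, 10), 1)
  expect_equal(escaping_energy(-0.3, 5, 10), -0.3)
  expect_error(escaping_energy(0.5, 0, 0), "T_max")
})

test_that("mean position is the column mean", {
  expect_equal(mean_position(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(mean_position(c(3, 4)), c(3, 4))
  set.seed(2)
  p <- matrix(rnorm(500), 100, 5)
  expect_equal(mean_position(p), colSums(p) / 100, tolerance = 1e-12)
})

test_that("exploration branches collapse as the formulas dictate", {
  sp <- search_space(0, 1, dim = 3)
  pop <- matrix(runif(15), 5, 3)
  xr <- rep(0.5, 3)
  # q-branch with r1 = 0 returns the random hawk exactly
  out <- hho_explore(pop[1, ], pop, xr, sp, q = 0.9, r1 = 0, rand_index = 3)
  expect_equal(out, pop[3, ])
  # else-branch with r3 = 0 returns X_rabbit - X_m (clipped)
  out <- hho_explore(pop[2, ], pop, xr, sp, q = 0.1, r3 = 0)
  expect_equal(out, clip_to_bounds(xr - colMeans(pop), sp))
})

test_that("besiege operators match element-wise re-evaluation", {
  # trivial collapses
  x <- c(0.1, 0.9)
  xr <- c(0.4, 0.2)
  expect_equal(hho_soft_besiege(x, xr, 0, 1.3), xr - x)
  expect_equal(hho_hard_besiege(x, xr, 0), xr)
  expect_equal(hho_soft_besiege(xr, xr, 0.7, 1), rep(0, 2))
  expect_equal(hho_hard_besiege(xr, xr, 0.7), xr)
  # random instances vs literal oracle
  set.seed(3)
  for (i in 1:100) {
    x <- runif(5, -2, 2)
    xr <- runif(5, -2, 2)
    E <- runif(1, -2, 2)
    J <- runif(1, 0, 2)
    expect_equal(hho_soft_besiege(x, xr, E, J), oracle_soft_besiege(x, xr, E, J),
      tolerance = 1e-12
    )
    expect_equal(hho_hard_besiege(x, xr, E), oracle_hard_besiege(x, xr, E),
      tolerance = 1e-12
    )
  }
})

test_that("Levy sigma matches the closed form and flights are seeded", {
  expect_equal(levy_sigma(1.5), oracle_levy_sigma(1.5), tolerance = 1e-14)
  for (b in c(0.5, 1, 1.2, 1.9)) {
    expect_equal(levy_sigma(b), oracle_levy_sigma(b), tolerance = 1e-12)
  }
  set.seed(4)
  a <- levy_flight(10)
  set.seed(4)
  b <- levy_flight(10)
  expect_identical(a, b)
  expect_length(a, 10)
})

test_that("dive acceptance is greedy with strict improvement", {
  x <- c(1, 1)
  fx <- sphere(x)
  # constant objective: neither Y nor Z improves -> X unchanged
  res <- dive_accept(x, c(0, 0), c(2, 2), 5, function(z) 5)
  expect_equal(res$x, x)
  expect_false(res$moved)
  # Y improves -> Y chosen
  res <- dive_accept(x, c(0.1, 0.1), c(5, 5), fx, sphere)
  expect_equal(res$x, c(0.1, 0.1))
  # Y worse, Z better -> Z chosen
  res <- dive_accept(x, c(5, 5), c(0.2, 0.2), fx, sphere)
  expect_equal(res$x, c(0.2, 0.2))
  # random instances vs explicit three-way comparison
  set.seed(5)
  for (i in 1:100) {
    x <- runif(4)
    y <- runif(4)
    z <- runif(4)
    fx <- sphere(x)
    res <- dive_accept(x, y, z, fx, sphere)
    want <- if (sphere(y) < fx) y else if (sphere(z) < fx) z else x
    expect_equal(res$x, want)
  }
})

test_that("regime thresholds partition (E, r) exhaustively and exclusively", {
  set.seed(6)
  for (i in 1:10000) {
    E <- runif(1, -2, 2)
    r <- runif(1)
    picks <- c(
      explore = abs(E) >= 1,
      soft = abs(E) < 1 && r >= 0.5 && abs(E) >= 0.5,
      hard = abs(E) < 1 && r >= 0.5 && abs(E) < 0.5,
      soft_dive = abs(E) < 1 && r < 0.5 && abs(E) >= 0.5,
      hard_dive = abs(E) < 1 && r < 0.5 && abs(E) < 0.5
    )
    expect_equal(sum(picks), 1)
  }
})

test_that("population initialization hits the affine endpoints", {
  sp <- search_space(c(-2, 0), c(2, 10))
  zero_map <- chaotic_map("piecewise", x0 = 0.5)
  set.seed(8)
  p1 <- hawkfs:::init_population(sp, 4, zero_map)
  set.seed(8)
  p2 <- hawkfs:::init_population(sp, 4, zero_map)
  expect_identical(p1, p2)
  expect_true(all(p1[, 1] >= -2 & p1[, 1] <= 2))
  expect_true(all(p1[, 2] >= 0 & p1[, 2] <= 10))
  expect_error(hawkfs:::init_population(sp, 1), "at least 2")
})

test_that("hho_run is elitist, bounded and seeded-deterministic", {
  sp <- search_space(-5, 5, dim = 2)
  res <- hho_run(sphere, sp, n_agents = 10, n_iter = 50, seed = 1)
  expect_true(all(diff(res$trace$best) <= 0))
  expect_true(all(res$best_position >= -5 & res$best_position <= 5))
  res2 <- hho_run(sphere, sp, n_agents = 10, n_iter = 50, seed = 1)
  expect_identical(res$trace, res2$trace)
  # constant objective: best equals the constant immediately
  resc <- hho_run(function(x) 42, sp, n_agents = 5, n_iter = 10, seed = 2)
  expect_true(all(resc$trace$best == 42))
  expect_error(hho_run(sphere, sp, n_iter = 0), "n_iter")
})

test_that("hho_run converges on the sphere across seeds", {
  sp <- search_space(-5, 5, dim = 10)
  finals <- vapply(1:3, function(s) {
    hho_run(sphere, sp, n_agents = 30, n_iter = 200, seed = s)$best_fitness
  }, numeric(1))
  expect_true(all(finals < 1e-2))
})
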