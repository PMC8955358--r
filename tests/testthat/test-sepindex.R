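test_that("theoretical index matches the closed form on spherical clusters", {
  z <- qnorm(0.975)
  # unit-variance spherical clusters 5 apart along the center line
  expect_equal(projected_index_theoretical(c(0, 0), diag(2), c(5, 0), diag(2),
                                           c(1, 0)),
               (5 - 2 * z) / (5 + 2 * z), tolerance = 1e-12)
  # centers exactly 2z apart -> the central 95% bodies just touch
  expect_equal(projected_index_theoretical(c(0, 0), diag(2), c(2 * z, 0),
                                           diag(2), c(1, 0)),
               0, tolerance = 1e-12)
  # coincident centers -> complete overlap limit
  expect_equal(projected_index_theoretical(c(1, 1), diag(2), c(1, 1), diag(2),
                                           c(1, 0)),
               -1, tolerance = 1e-12)
  # direction is normalised internally
  expect_equal(projected_index_theoretical(c(0, 0), diag(2), c(5, 0), diag(2),
                                           c(10, 0)),
               projected_index_theoretical(c(0, 0), diag(2), c(5, 0), diag(2),
                                           c(1, 0)))
})

test_that("theoretical index rejects bad covariances and directions", {
  bad <- matrix(c(1, 2, 2, 1), 2)      # indefinite
  expect_error(projected_index_theoretical(c(0, 0), bad, c(5, 0), diag(2),
                                           c(1, 0)),
               class = "invalid_model")
  expect_error(projected_index_theoretical(c(0, 0), diag(2), c(5, 0), diag(2),
                                           c(0, 0)),
               class = "invalid_argument")
})

test_that("optimal direction solves known geometries and beats the angle grid", {
  # spherical equal clusters: direction along the center line
  a <- optimal_direction(c(0, 0), diag(2), c(3, 4), diag(2))
  expect_equal(a, c(3, 4) / 5, tolerance = 1e-8)
  # equal covariances Sigma: direction proportional to solve(Sigma, d)
  S <- matrix(c(4, 1, 1, 2), 2)
  d <- c(1, 2)
  a <- optimal_direction(c(0, 0), S, d, S)
  expect_equal(a, solve(S, d) / sqrt(sum(solve(S, d)^2)), tolerance = 1e-8)
  # crossed anisotropic pair against the dense grid oracle
  c1 <- diag(c(5, 1)); c2 <- diag(c(1, 5))
  a <- optimal_direction(c(0, 0), c1, c(1, 0), c2)
  j <- projected_index_theoretical(c(0, 0), c1, c(1, 0), c2, a)
  expect_gte(j, oracle_grid_max_j(c(0, 0), c1, c(1, 0), c2) - 1e-6)
  expect_error(optimal_direction(c(1, 1), diag(2), c(1, 1), diag(2)),
               class = "degenerate_geometry")
})

test_that("optimal-direction index matches the grid oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    c1 <- rand_spd(); c2 <- rand_spd()
    m2 <- rnorm(2, sd = 3)
    while (sqrt(sum(m2^2)) < 0.1) m2 <- rnorm(2, sd = 3)
    a <- optimal_direction(c(0, 0), c1, m2, c2)
    j <- projected_index_theoretical(c(0, 0), c1, m2, c2, a)
    expect_gte(j, oracle_grid_max_j(c(0, 0), c1, m2, c2) - 1e-6)
  }
})

test_that("index is swap-symmetric and affine invariant", {
  set.seed(7)
  for (i in 1:20) {
    c1 <- rand_spd(); c2 <- rand_spd(); m2 <- rnorm(2, sd = 4)
    a <- optimal_direction(c(0, 0), c1, m2, c2)
    j12 <- projected_index_theoretical(c(0, 0), c1, m2, c2, a)
    j21 <- projected_index_theoretical(m2, c2, c(0, 0), c1, a)
    expect_equal(j12, j21, tolerance = 1e-9)
    # common rotation + translation + positive uniform scaling
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 3); t <- rnorm(2)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    jt <- projected_index_theoretical(
      s * R %*% c(0, 0) + t, s^2 * R %*% c1 %*% t(R),
      s * R %*% m2 + t, s^2 * R %*% c2 %*% t(R), R %*% a)
    expect_equal(jt, j12, tolerance = 1e-9)
  }
})

test_that("index at the optimal direction is strictly increasing in distance", {
  set.seed(11)
  for (i in 1:100) {
    c1 <- rand_spd(); c2 <- rand_spd()
    u <- rnorm(2); u <- u / sqrt(sum(u^2))
    js <- vapply(c(0.5, 1, 2, 4, 8), function(delta) {
      a <- optimal_direction(c(0, 0), c1, delta * u, c2)
      projected_index_theoretical(c(0, 0), c1, delta * u, c2, a)
    }, numeric(1))
    expect_true(all(diff(js) > 0))
  }
})

test_that("empirical index converges to the theoretical value", {
  set.seed(202)
  # spherical clusters 5 apart: theoretical J = 0.121
  jtheo <- projected_index_theoretical(c(0, 0), diag(2), c(5, 0), diag(2),
                                       c(1, 0))
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    A <- matrix(rnorm(2 * n), ncol = 2)
    B <- sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(5, 0), "+")
    abs(separation_index_empirical(A, B)$value - jtheo)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1])
})

test_that("empirical index is swap-symmetric and saturates at far separation", {
  set.seed(303)
  A <- matrix(rnorm(400), ncol = 2)
  B <- sweep(matrix(rnorm(400), ncol = 2), 2, c(4, 1), "+")
  r1 <- separation_index_empirical(A, B)
  r2 <- separation_index_empirical(B, A)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  expect_equal(sqrt(sum(r1$direction^2)), 1, tolerance = 1e-9)
  expect_gt(r1$value, -1); expect_lt(r1$value, 1)
  far <- A; far[, 1] <- far[, 1] + 1e6
  expect_gt(separation_index_empirical(A, far)$value, 0.99)
  # degenerate cloud
  flat <- cbind(A[, 1], 2 * A[, 1])
  expect_error(separation_index_empirical(flat, B),
               class = "degenerate_geometry")
  expect_error(separation_index_empirical(A[1:5, ], B),
               class = "invalid_argument")
})

test_that("solve_center_distance inverts the index within tolerance", {
  z <- qnorm(0.975)
  # closed form for spherical unit clusters: delta = 2z (1+J)/(1-J)
  d0 <- solve_center_distance(diag(2), diag(2), c(1, 0), 0)
  expect_equal(d0, 2 * z, tolerance = 0.02)
  dneg <- solve_center_distance(diag(2), diag(2), c(1, 0), -0.1)
  expect_lt(abs(projected_index_theoretical(c(0, 0), diag(2), c(dneg, 0),
                                            diag(2), c(1, 0)) + 0.1),
            0.005)
  expect_lt(abs(dneg - 2 * z * 0.9 / 1.1), 0.05)
  # near-complete-overlap target collapses the distance to ~0
  expect_lt(solve_center_distance(diag(2), diag(2), c(1, 0), -1 + 1e-9), 0.1)
  # achieved index always within tol for random geometries
  set.seed(13)
  for (i in 1:10) {
    c1 <- rand_spd(); c2 <- rand_spd()
    tgt <- runif(1, -0.4, 0.4)
    u <- rnorm(2); u <- u / sqrt(sum(u^2))
    delta <- solve_center_distance(c1, c2, u, tgt)
    a <- optimal_direction(c(0, 0), c1, delta * u, c2)
    expect_lt(abs(projected_index_theoretical(c(0, 0), c1, delta * u, c2, a) -
                    tgt), 0.005)
  }
  expect_error(solve_center_distance(diag(2), diag(2), c(1, 0), 1.5),
               class = "invalid_argument")
})
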