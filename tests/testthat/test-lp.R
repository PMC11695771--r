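test_that("simplex matches boot::simplex on random standard-form LPs", {
  skip_if_not_installed("boot")
  set.seed(42)
  for (k in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:7, 1)
    A <- matrix(round(stats::runif(m * n, 0, 3), 2), m, n)
    b <- round(stats::runif(m, 1, 5), 2)
    cc <- round(stats::runif(n, 0, 2), 2)
    ref <- boot::simplex(a = cc, A1 = A, b1 = b, maxi = TRUE)
    res <- solve_lp(cbind(A, diag(m)), rep(0, n + m), rep(1e4, n + m),
                    obj = c(cc, rep(0, m)), b = b)
    expect_equal(res$status, "optimal")
    expect_equal(res$objval, unname(ref$value), tolerance = 1e-7)
  }
})

test_that("equality systems with negative bounds solve exactly", {
  A <- matrix(c(1, -1, 2, 1), 2, 2, byrow = TRUE)
  res <- solve_lp(A, c(-10, -10), c(10, 10), obj = c(1, 1), b = c(1, 4),
                  maximize = FALSE)
  expect_equal(res$x, c(5 / 3, 2 / 3), tolerance = 1e-9)
})

test_that("infeasibility is detected and distinguished from errors", {
  res <- solve_lp(matrix(1, 1, 1), 0, 1, b = 5)
  expect_equal(res$status, "infeasible")
  res2 <- solve_lp(matrix(c(1, 1), 1, 2), c(0, 0), c(1, 1), b = 3)
  expect_equal(res2$status, "infeasible")
})

test_that("warm starts reproduce the cold-start optimum after bound edits", {
  set.seed(7)
  m <- 4; n <- 8
  A <- matrix(round(stats::runif(m * n, -1, 2), 2), m, n)
  lb <- rep(0, n); ub <- rep(5, n)
  obj <- round(stats::runif(n), 2)
  b <- as.numeric(A %*% rep(1, n))
  r1 <- solve_lp(A, lb, ub, obj = obj, b = b)
  expect_equal(r1$status, "optimal")
  ub2 <- ub; ub2[which.max(obj)] <- 0.5
  warm <- solve_lp(A, lb, ub2, obj = obj, b = b, state = r1$state)
  cold <- solve_lp(A, lb, ub2, obj = obj, b = b)
  expect_equal(warm$status, "optimal")
  expect_equal(warm$objval, cold$objval, tolerance = 1e-8)
})
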