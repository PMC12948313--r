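# Sobol' sequence, Saltelli design, and the index estimators against
# closed-form benchmarks.

test_that("Sobol' sequence reproduces the canonical first points", {
  X <- sobol_sequence(8, 2)
  expect_equal(X[, 1], c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(X[, 2], c(0, 0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  # digital shift keeps points in [0,1) and is reproducible
  Y1 <- sobol_sequence(64, 5, seed = 3)
  Y2 <- sobol_sequence(64, 5, seed = 3)
  expect_identical(Y1, Y2)
  expect_true(all(Y1 >= 0 & Y1 < 1))
  # equidistribution: each dyadic half contains half the points
  for (j in 1:5) expect_equal(sum(Y1[, j] < 0.5), 32)
})

test_that("Saltelli design has the N(2K+2) block structure", {
  d <- sensitivity_design(N = 8, seed = 1,
                          parameters = c("a", "b"), scale_bounds = c(0, 1))
  X <- saltelli_matrix(d)
  expect_equal(nrow(X), 8 * (2 * 2 + 2))   # 48 rows
  d4 <- sensitivity_design(N = 500)
  expect_equal(with(d4, N * (2 * length(parameters) + 2)), 5000)
  suppressWarnings(X4 <- saltelli_matrix(d4))
  expect_equal(nrow(X4), 5000)
  expect_true(all(X4 >= 0.5 & X4 <= 10))
  # AB_j blocks differ from A only in column j
  blk <- attr(X, "block")
  A <- X[blk == "A", ]; AB1 <- X[blk == "AB1", ]; B <- X[blk == "B", ]
  expect_equal(AB1[, 2], A[, 2])
  expect_equal(AB1[, 1], B[, 1])
  # degenerate interval: every scale exactly the single admissible value
  dd <- sensitivity_design(N = 8, scale_bounds = c(1, 1))
  expect_true(all(saltelli_matrix(dd) == 1))
})

test_that("estimators recover closed-form indices of benchmark functions", {
  # single factor: y = x1, x2 dummy
  d <- sensitivity_design(parameters = c("x1", "x2"), scale_bounds = c(0, 1),
                          N = 512, seed = 5)
  X <- saltelli_matrix(d)
  r <- sobol_indices(X[, 1], X)
  expect_lt(abs(r$S[1] - 1), 0.05)
  expect_lt(abs(r$S[2]), 0.05)
  expect_lt(abs(r$ST[2]), 0.05)
  # additive symmetric: S1 = S2 = 0.5
  r2 <- sobol_indices(X[, 1] + X[, 2], X)
  expect_lt(max(abs(r2$S - 0.5)), 0.05)
  expect_lt(max(abs(r2$ST - 0.5)), 0.05)
})

test_that("estimators match the analytic Ishigami indices", {
  a <- 7; b <- 0.1
  # closed forms: V1 = (1 + b pi^4 / 5)^2 / 2, V2 = a^2/8,
  # V13 = 8 b^2 pi^8 / 225, V3 = 0
  D1 <- 0.5 * (1 + b * pi^4 / 5)^2
  D2 <- a^2 / 8
  D13 <- 8 * b^2 * pi^8 / 225
  D <- D1 + D2 + D13
  S_exact <- c(D1, D2, 0) / D
  ST_exact <- c(D1 + D13, D2, D13) / D
  d <- sensitivity_design(parameters = c("x1", "x2", "x3"),
                          scale_bounds = c(-pi, pi), N = 1024, seed = 11)
  X <- saltelli_matrix(d)
  y <- sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  r <- sobol_indices(y, X)
  expect_lt(max(abs(r$S - S_exact)), 0.05)
  expect_lt(max(abs(r$ST - ST_exact)), 0.05)
  # theoretical ordering within estimator noise
  expect_true(all(r$ST >= r$S - 0.05))
  expect_lt(sum(r$S), 1 + 0.1)
})

test_that("index estimation rejects degenerate inputs", {
  d <- sensitivity_design(parameters = c("x1", "x2"), scale_bounds = c(0, 1),
                          N = 64, seed = 2)
  X <- saltelli_matrix(d)
  expect_error(sobol_indices(rep(1, nrow(X)), X), "variance")
  expect_error(sobol_indices(c(1, 2, 3), X), "length")
  y <- X[, 1]; y[5] <- NA
  expect_error(sobol_indices(y, X), "finite")
})

test_that("doubling N leaves benchmark indices stable", {
  mk <- function(N) {
    d <- sensitivity_design(parameters = c("x1", "x2"), scale_bounds = c(0, 1),
                            N = N, seed = 9)
    X <- saltelli_matrix(d)
    sobol_indices(X[, 1] + 0.3 * X[, 2] * X[, 1], X)
  }
  r1 <- mk(512); r2 <- mk(1024)
  expect_lt(max(abs(r1$S - r2$S)), 0.05)
  expect_lt(max(abs(r1$ST - r2$ST)), 0.05)
})
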