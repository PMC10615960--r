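test_that("factorial designs are balanced, contiguous and deterministic", {
  d <- factorial_design("X", 50)
  expect_equal(nrow(d), 100)
  expect_equal(sum(d$X == 0), 50)
  expect_equal(sum(d$X == 1), 50)
  expect_identical(d, factorial_design("X", 50))     # no randomness

  d2 <- factorial_design(c("X", "W"), 25)
  expect_equal(nrow(d2), 100)
  expect_equal(as.vector(table(d2$X, d2$W)), rep(25L, 4))
  # first factor varies slowest
  expect_equal(d2$X, rep(c(0, 1), each = 50))

  dmin <- factorial_design("X", 1)
  expect_equal(dmin$X, c(0, 1))

  expect_error(factorial_design("X", 0), "invalid design")
  expect_error(factorial_design("X", -3), "invalid design")
})

test_that("unbalanced designs via per-cell sizes are honored", {
  d <- factorial_design("X", c(10, 30))
  expect_equal(sum(d$X == 0), 10)
  expect_equal(sum(d$X == 1), 30)
})

test_that("interaction columns are elementwise products of their parents", {
  d <- data.frame(X = c(1, 1, 0, 0), W = c(1, 0, 1, 0))
  class(d) <- c("mm_design", "data.frame")
  d <- add_interaction(d, "X", "W")
  expect_equal(d[["X:W"]], c(1, 0, 0, 0))
  # product with an all-zero column is all zero
  d$Z <- 0
  expect_equal(add_interaction(d, "X", "Z")[["X:Z"]], rep(0, 4))
  # 0/1 dummies are idempotent under self-product
  expect_equal(add_interaction(d, "X", "X", name = "XX")$XX, d$X)
  expect_error(add_interaction(d, "X", "nope"), "missing column")
})

test_that("covariate moments match direct enumeration of the design rows", {
  d <- factorial_design("X", 50)
  mo <- covariate_moments(d)
  # oracle: sample covariance of the enumerated rows
  expect_equal(mo$covariance["X", "X"], var(rep(c(0, 1), each = 50)))
  expect_equal(mo$covariance["X", "X"], 25 / 99, tolerance = 1e-12)

  d2 <- design_2x2(25)
  mo2 <- covariate_moments(d2)
  raw <- as.data.frame(d2)
  expect_equal(mo2$covariance, cov(as.matrix(raw)), tolerance = 1e-12)
  expect_equal(mo2$covariance["X", "W"], 0)
  expect_equal(mo2$covariance["X", "X:W"], 12.5 / 99, tolerance = 1e-12)

  # population divisor: exactly p(1-p) for a balanced dummy
  mop <- covariate_moments(d, divisor = "population")
  expect_equal(mop$covariance["X", "X"], 0.25)
  expect_equal(mo$covariance["X", "X"], 0.25 * 100 / 99)
})

test_that("moments are invariant to row permutation and reject degenerate input", {
  d <- design_2x2(5)
  perm <- as.data.frame(d)[sample(nrow(d)), ]
  class(perm) <- c("mm_design", "data.frame")
  expect_equal(covariate_moments(d)$covariance,
               covariate_moments(perm)$covariance)
  one <- as.data.frame(d)[1, ]
  class(one) <- c("mm_design", "data.frame")
  expect_error(covariate_moments(one), "degenerate")
})

test_that("group columns are recoded to sequential integers and moved last", {
  d <- set_group(factorial_design(c("W", "X"), 10), "W")
  expect_equal(names(d)[ncol(d)], "W")
  expect_equal(sort(unique(d$W)), c(1L, 2L))
  # the grouping column is excluded from covariate moments
  expect_equal(colnames(covariate_moments(d)$covariance), "X")
})
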