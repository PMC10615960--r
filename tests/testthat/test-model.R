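test_that("parameter matrices validate shape, roles and fixed/population consistency", {
  dn <- list(c("M", "Y"), "X")
  KA <- mm_matrix("KA", free = matrix(c("a", "c"), 2, 1, dimnames = dn),
                  pop = matrix(c(0.5, 0.2), 2, 1, dimnames = dn))
  expect_equal(KA$pop["M", "X"], 0.5)
  expect_equal(KA$labels["Y", "X"], "c")

  expect_error(mm_matrix("KA", free = matrix(NA_character_, 2, 1),
                         pop = matrix(0, 1, 1)), "identical dimensions")
  # a numeric-string cell is fixed at that value and must agree with pop
  expect_error(mm_matrix("KA", free = matrix(c("0.3", "c"), 2, 1),
                         pop = matrix(c(0.5, 0.2), 2, 1)), "fixed at")
  ok <- mm_matrix("KA", free = matrix(c("0.5", "c"), 2, 1),
                  pop = matrix(c(0.5, 0.2), 2, 1))
  expect_true(is.na(ok$labels[1, 1]))

  expect_error(mm_matrix("BE", free = matrix("b", 2, 2),
                         pop = matrix(0.1, 2, 2)), "zero diagonal")
  expect_error(mm_matrix("PS", free = matrix(c(NA, "r", "r", NA), 2, 2),
                         pop = matrix(c(1, 0, 0, 1), 2, 2)), "off-diagonal")
  # all-fixed zero matrix is a valid null matrix
  null <- mm_matrix("BE", free = matrix(NA_character_, 2, 2),
                    pop = matrix(0, 2, 2))
  expect_true(all(is.na(null$labels)))
})

test_that("recursive validation orders variables and detects cycles", {
  m <- simple_mediation_model()
  expect_equal(validate_recursive(m$groups[[1]]$BE), c("M", "Y"))
  zero <- mm_matrix("BE", free = matrix(NA_character_, 2, 2,
                                        dimnames = list(c("M", "Y"), c("M", "Y"))),
                    pop = matrix(0, 2, 2, dimnames = list(c("M", "Y"), c("M", "Y"))))
  expect_equal(validate_recursive(zero), c("M", "Y"))  # declaration order
  cyc <- mm_matrix("BE", free = matrix(c(NA, "b1", "b2", NA), 2, 2,
                                       dimnames = list(c("M", "Y"), c("M", "Y"))),
                   pop = matrix(0, 2, 2, dimnames = list(c("M", "Y"), c("M", "Y"))))
  expect_error(validate_recursive(cyc), "non-recursive")
  expect_error(path_model(BE = cyc, PS = mm_psi(c("e1", "e2"), c(1, 1), c("M", "Y")),
                          meanstructure = FALSE), "non-recursive")
})

test_that("standardization solver reproduces the closed-form simple-mediation variances", {
  m <- simple_mediation_model()
  d <- factorial_design("X", 50)
  psi <- solve_residual_variances(m, covariate_moments(d))
  # independent algebra on the reduced form: var(X) = 25/99 under n-1
  vx <- 25 / 99
  expect_equal(unname(psi["M"]), 1 - 0.25 * vx, tolerance = 1e-12)
  expect_equal(unname(psi["Y"]),
               1 - (0.04 * vx + 0.16 + 2 * 0.2 * 0.4 * 0.5 * vx),
               tolerance = 1e-12)
  # all slopes zero: residual variance equals the target
  m0 <- simple_mediation_model(a = 0, b = 0, c = 0)
  expect_equal(unname(solve_residual_variances(m0, covariate_moments(d))),
               c(1, 1))
  # infeasible standardization names the variable
  mbig <- simple_mediation_model(a = 2.2)
  expect_error(solve_residual_variances(mbig, covariate_moments(d)),
               "nonpositive residual variance for 'M'")
})

test_that("implied covariance round-trips the solver and handles degenerate cases", {
  d <- design_2x2(25)
  mo <- covariate_moments(d)
  for (seed in 1:20) {
    m <- random_recursive_model(seed)
    m <- standardize_model(m, mo)
    V <- implied_covariance(m, mo)
    expect_lt(max(abs(diag(V) - 1)), 1e-10)
  }
  # K = 0, B = 0: implied covariance equals the residual matrix
  m0 <- simple_mediation_model(a = 0, b = 0, c = 0, psi = c(0.7, 0.9))
  V0 <- implied_covariance(m0, covariate_moments(factorial_design("X", 50)))
  expect_equal(unname(diag(V0)), c(0.7, 0.9))
  expect_equal(V0["M", "Y"], 0)
  # var(Y) decomposition includes b^2 * var(M) through the mediator
  m1 <- simple_mediation_model()
  mo1 <- covariate_moments(factorial_design("X", 50))
  m1 <- standardize_model(m1, mo1)
  psiM <- diag(m1$groups[[1]]$PS$pop)["M"]
  expect_equal(0.16 * unname(psiM), 0.1498990, tolerance = 1e-7)
})

test_that("standardization is invariant to declaration order of tied variables", {
  # two parallel mediators (topological tie) feeding Y
  slopes <- c(M1 = 0.4, M2 = 0.3, Y = 0.1)
  build <- function(order) {
    endo <- c(order, "Y")
    kdn <- list(endo, "X")
    K <- matrix(slopes[endo], 3, 1, dimnames = kdn)
    bdn <- list(endo, endo)
    B <- matrix(0, 3, 3, dimnames = bdn)
    B["Y", "M1"] <- 0.2; B["Y", "M2"] <- 0.25
    path_model(KA = mm_matrix("KA", matrix(NA_character_, 3, 1, dimnames = kdn), K),
               BE = mm_matrix("BE", matrix(NA_character_, 3, 3, dimnames = bdn), B),
               PS = mm_psi(paste0("e", 1:3), rep(NA, 3), endo),
               meanstructure = FALSE)
  }
  mo <- covariate_moments(factorial_design("X", 50))
  p1 <- solve_residual_variances(build(c("M1", "M2")), mo)
  p2 <- solve_residual_variances(build(c("M2", "M1")), mo)
  expect_equal(p1[c("M1", "M2", "Y")], p2[c("M1", "M2", "Y")], tolerance = 1e-12)
})

test_that("group variance scaling and intercept offsets follow the stated rules", {
  st <- preset_modmed_multigroup()
  ps1 <- diag(st$population$groups[[1]]$PS$pop)
  ps2 <- diag(st$population$groups[[2]]$PS$pop)
  expect_equal(unname(ps2 / ps1), c(1.5, 1.5))
  expect_equal(unname(ps2), c(1.3077651, 1.2092424), tolerance = 1e-6)

  m <- preset_simple_mediation_multigroup()$population
  m1 <- scale_group_variances(m, 1, 1)            # identity
  expect_equal(m1$groups[[1]]$PS$pop, m$groups[[1]]$PS$pop)
  m2 <- scale_group_variances(m, 1, 0.5)          # control only
  expect_equal(m2$groups[[2]]$PS$pop, m$groups[[2]]$PS$pop)
  expect_equal(diag(m2$groups[[1]]$PS$pop), diag(m$groups[[1]]$PS$pop) / 2)
  expect_error(scale_group_variances(m, "nope", 2), "unknown group")

  off <- intercept_offsets(c(M = 0.5, Y = 0.2))
  expect_equal(off$control, c(M = -0.25, Y = -0.1))
  expect_equal(off$treatment, c(M = 0.25, Y = 0.1))
  expect_equal(off$treatment - off$control, c(M = 0.5, Y = 0.2))
  expect_equal(unname(intercept_offsets(c(M = 0))$control), 0)
  expect_error(intercept_offsets(c(Q = 1), endogenous = c("M", "Y")), "unknown")
})

test_that("shared labels collapse to single free parameters across groups", {
  st <- preset_simple_mediation_multigroup()
  labs <- free_labels(st$analysis)
  # a0, c0, a1, c1, shared b, shared eM, eY
  expect_setequal(labs, c("a0", "c0", "a1", "c1", "b", "eM", "eY"))
  un <- preset_simple_mediation_multigroup(constrain = FALSE)
  expect_length(free_labels(un$analysis), 10)  # nothing shared
})
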