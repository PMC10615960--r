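test_that("unconstrained fits coincide with per-equation least squares", {
  st <- preset_simple_mediation()
  dat <- generate_sample(st$population, st$design, seed = 3)
  fit <- fit_path_model(st$analysis, dat)
  oM <- lm(M ~ 0 + X, dat)
  oY <- lm(Y ~ 0 + M + X, dat)
  expect_equal(unname(coef(fit)["a"]), unname(coef(oM)["X"]), tolerance = 1e-8)
  expect_equal(unname(coef(fit)["b"]), unname(coef(oY)["M"]), tolerance = 1e-8)
  expect_equal(unname(coef(fit)["c"]), unname(coef(oY)["X"]), tolerance = 1e-8)
  # ML residual variances use divisor n
  expect_equal(unname(coef(fit)["psi.M"]), sum(resid(oM)^2) / 100, tolerance = 1e-8)
  # slope standard errors: psi_ML * (X'X)^-1
  expect_equal(unname(sqrt(diag(vcov(fit))["a"])),
               unname(sqrt(diag(vcov(oM)) * oM$df.residual / 100)),
               tolerance = 1e-6)
})

test_that("OLS equivalence holds for random recursive models (property)", {
  d <- design_2x2(15)
  mo <- covariate_moments(d)
  for (seed in c(11, 12, 13, 14, 15)) {
    m <- standardize_model(random_recursive_model(seed), mo)
    dat <- generate_sample(m, d, seed = seed + 100)
    fit <- fit_path_model(m, dat)
    expect_true(fit$converged)
    o1 <- lm(M1 ~ 0 + X + W, dat)
    o2 <- lm(M2 ~ 0 + X + W + M1, dat)
    o3 <- lm(Y ~ 0 + X + W + M1 + M2, dat)
    expect_equal(unname(coef(fit)[c("k1", "k4")]), unname(coef(o1)),
                 tolerance = 1e-8)
    expect_equal(unname(coef(fit)[c("k2", "k5", "be1")]), unname(coef(o2)),
                 tolerance = 1e-8)
    expect_equal(unname(coef(fit)[c("k3", "k6", "be2", "be3")]),
                 unname(coef(o3)), tolerance = 1e-8)
  }
})

test_that("zero-noise equations recover generating slopes with boundary variances", {
  # noise only in M: the Y equation is exact, so b and c are recovered
  # exactly and psi.Y sits at the zero boundary.  (With BOTH equations
  # noiseless M is an exact multiple of X and the Y equation is not
  # identified; the fitter must flag that, not crash.)
  m <- simple_mediation_model(psi = c(0.5, 0))
  ana <- simple_mediation_model(psi = c(NA, NA))
  dat <- generate_sample(m, factorial_design("X", 25), seed = 1)
  fit <- fit_path_model(ana, dat)
  expect_true(fit$boundary)
  expect_equal(unname(coef(fit)[c("b", "c")]), c(0.4, 0.2), tolerance = 1e-6)
  expect_lt(coef(fit)["psi.Y"], 1e-8)

  m0 <- simple_mediation_model(psi = c(0, 0))
  dat0 <- generate_sample(m0, factorial_design("X", 25), seed = 1)
  fit0 <- fit_path_model(ana, dat0)
  expect_false(fit0$converged)     # flagged, no exception
  expect_false(fit0$vcov_ok)
})

test_that("constrained log-likelihood never exceeds the unconstrained one", {
  stc <- preset_simple_mediation_multigroup(constrain = TRUE)
  stu <- preset_simple_mediation_multigroup(constrain = FALSE)
  dat <- generate_sample(stc$population, stc$design, seed = 8)
  llc <- logLik(fit_path_model(stc$analysis, dat))
  llu <- logLik(fit_path_model(stu$analysis, dat))
  expect_lte(as.numeric(llc), as.numeric(llu) + 1e-8)
  # equality when the constraints hold exactly in-sample: duplicate one
  # group's rows into both groups
  half <- dat[dat$X == 1, ]
  dup <- rbind(transform(half, X = 1L), transform(half, X = 2L))
  llc2 <- logLik(fit_path_model(stc$analysis, dup))
  llu2 <- logLik(fit_path_model(stu$analysis, dup))
  expect_equal(as.numeric(llc2), as.numeric(llu2), tolerance = 1e-6)
})

test_that("constrained multigroup fit equals the dummy-coded single-group fit", {
  st1 <- preset_simple_mediation(meanstructure = TRUE)
  st2 <- preset_simple_mediation_multigroup()
  for (seed in c(1, 2, 3)) {
    dat <- generate_sample(st1$population, st1$design, seed = seed)
    dat2 <- dat; dat2$X <- dat$X + 1L      # same rows, X as group codes
    f1 <- fit_path_model(st1$analysis, dat)
    f2 <- fit_path_model(st2$analysis, dat2)
    expect_equal(unname(f1$defined["ab"]), unname(f2$defined["ab"]),
                 tolerance = 1e-8)
    expect_equal(unname(delta_se(f1)["ab"]), unname(delta_se(f2)["ab"]),
                 tolerance = 1e-6)
    expect_equal(unname(coef(f1)["a"]),
                 unname(coef(f2)["a1"] - coef(f2)["a0"]), tolerance = 1e-8)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  }
})

test_that("defined parameters evaluate correctly at fitted and nominal values", {
  v <- evaluate_defined("ab := a*b", list(a = 0.5, b = 0.4))
  expect_equal(v$ab, 0.2)
  v2 <- evaluate_defined(c("ind.w1 := (a.w0 + a.mod)*b"),
                         list(a.w0 = 0.5, a.mod = 0.3, b = 0.4))
  expect_equal(v2$ind.w1, 0.32)
})

test_that("delta-method SE matches the Sobel closed form and symbolic gradients", {
  st <- preset_simple_mediation()     # no intercepts: cov(a, b) = 0
  dat <- generate_sample(st$population, st$design, seed = 31)
  fit <- fit_path_model(st$analysis, dat)
  a <- coef(fit)["a"]; b <- coef(fit)["b"]
  V <- vcov(fit)
  sobel <- sqrt(b^2 * V["a", "a"] + a^2 * V["b", "b"])
  expect_equal(unname(delta_se(fit)["ab"]), unname(sobel), tolerance = 1e-6)
  # worked numeric case
  expect_equal(sqrt(0.4^2 * 0.19^2 + 0.5^2 * 0.09^2), 0.0883, tolerance = 1e-3)
  # identity function: SE equals the label's own SE
  fit1 <- fit_path_model(st$analysis, dat)
  fit1$model$defined <- defined_params(c("ab := a*b", "justa := a"))
  expect_equal(unname(delta_se(fit1, names = "justa")),
               unname(sqrt(V["a", "a"])), tolerance = 1e-6)
  # sum c + ab: symbolic gradient (1, b, a) over (c, a, b)
  g <- c(1, unname(b), unname(a))
  Vs <- V[c("c", "a", "b"), c("c", "a", "b")]
  expect_equal(unname(delta_se(fit)["total"]),
               sqrt(drop(t(g) %*% Vs %*% g)), tolerance = 1e-6)
})

test_that("fitting the generating model recovers population values (3 SE)", {
  st <- preset_simple_mediation(n_per_group = 5000)
  truths <- c(a = 0.5, c = 0.2, b = 0.4)
  bad <- 0
  for (seed in 1:20) {
    dat <- generate_sample(st$population, st$design, seed = seed)
    fit <- fit_path_model(st$analysis, dat)
    se <- sqrt(diag(vcov(fit))[names(truths)])
    bad <- bad + any(abs(coef(fit)[names(truths)] - truths) > 3 * se)
  }
  expect_lte(bad, 1)   # >= 99% of parameters within 3 SE, allow one unlucky seed
})

test_that("delta SE of ab tracks the empirical sampling SD at N=100", {
  st <- preset_simple_mediation(nRep = 2000, seed = 77, methods = "delta")
  res <- run_power_study(st)
  abs_est <- vapply(res$records, function(r) r$estimates[["ab"]], 0)
  mean_se <- mean(vapply(res$records,
                         function(r) r$delta$se[r$delta$parameter == "ab"], 0))
  expect_equal(mean_se, sd(abs_est), tolerance = 0.1)
})

test_that("residuals method returns per-equation, per-group residuals", {
  st <- preset_simple_mediation()
  dat <- generate_sample(st$population, st$design, seed = 4)
  fit <- fit_path_model(st$analysis, dat)
  r <- residuals(fit)
  expect_equal(nrow(r), 200)   # 100 obs x 2 equations
  expect_setequal(unique(r$variable), c("M", "Y"))
  rm_ <- r$residual[r$variable == "M"]
  expect_equal(rm_, unname(dat$M - coef(fit)["a"] * dat$X), tolerance = 1e-8)
})
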