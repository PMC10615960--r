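test_that("summaries compute power, bias and coverage from records", {
  mk_rec <- function(est, rej, lo, hi) {
    list(converged = TRUE, estimates = c(ab = est),
         delta = data.frame(parameter = "ab", estimate = est, se = 0.1,
                            ci_low = lo, ci_high = hi, reject = rej))
  }
  recs <- list(mk_rec(0.22, TRUE, 0.02, 0.42), mk_rec(0.20, TRUE, 0.00, 0.40),
               mk_rec(0.18, FALSE, -0.02, 0.38), mk_rec(0.24, TRUE, 0.04, 0.44))
  s <- summarize_replications(recs, truth = c(ab = 0.20))
  expect_equal(s$power_delta, 0.75)                 # 3 of 4 reject
  expect_equal(s$estimate_average, 0.21)
  expect_equal(s$average_bias, 0.01)
  expect_false(s$bias_flag)                          # |bias| < .10
  expect_equal(s$coverage, 1)                        # all CIs contain 0.20
  # 95 of 100 CIs containing the truth -> coverage .95
  recs2 <- c(rep(list(mk_rec(0.2, TRUE, 0.1, 0.3)), 95),
             rep(list(mk_rec(0.2, TRUE, 0.25, 0.3)), 5))
  expect_equal(summarize_replications(recs2, c(ab = 0.2))$coverage, 0.95)
  # a parameter without a truth still gets power
  s3 <- summarize_replications(recs)
  expect_equal(s3$power_delta, 0.75)
  expect_true(is.na(s3$average_bias))
})

test_that("a trivially strong effect yields power 1 in one replication", {
  st <- preset_simple_mediation(a = 0.9, b = 0.9, c = 0.2, n_per_group = 500,
                                nRep = 1, seed = 5, methods = "delta")
  res <- run_power_study(st)
  expect_equal(res$summary$power_delta[res$summary$parameter == "ab"], 1)
  expect_equal(res$n_converged, 1)
})

test_that("the engine is deterministic given the master seed", {
  st <- preset_simple_mediation(nRep = 25, seed = 303, mcci_draws = 500)
  r1 <- run_power_study(st)
  r2 <- run_power_study(st)
  expect_identical(r1$summary, r2$summary)
  st2 <- preset_simple_mediation(nRep = 25, seed = 304, mcci_draws = 500)
  expect_false(identical(run_power_study(st2)$summary$power_mcci,
                         r1$summary$power_mcci))
})

test_that("defined parameters inherit auto-derived population values", {
  st <- preset_simple_mediation(nRep = 10, seed = 7, methods = "delta")
  res <- run_power_study(st)
  expect_equal(unname(res$truth["ab"]), 0.2)
  expect_equal(unname(res$truth["total"]), 0.4)
  expect_equal(unname(res$truth["psi.M"]), 0.9368687, tolerance = 1e-6)
  s <- res$summary
  expect_false(any(is.na(s$average_bias)))
})

test_that("power curves rerun the study per N and reject empty grids", {
  st <- preset_simple_mediation(nRep = 40, seed = 88, methods = "delta")
  expect_error(power_curve(st, integer(0)), "empty")
  cur <- power_curve(st, 50)
  expect_s3_class(cur, "mm_curve")
  expect_setequal(unique(cur$N), 100)
  # single-point grid equals a plain run at the same derived seed
  st1 <- preset_simple_mediation(nRep = 40, seed = (88 + 997) %% .Machine$integer.max,
                                 methods = "delta")
  res1 <- run_power_study(st1)
  expect_equal(cur$power[cur$parameter == "ab"],
               res1$summary$power_delta[res1$summary$parameter == "ab"])
})

test_that("heteroskedastic truth fitted under a homoskedasticity constraint flags no bias in slopes", {
  # analysis constrains residual variances equal although the population is
  # heteroskedastic; slope estimates stay consistent
  st <- preset_modmed_multigroup(nRep = 60, seed = 55, methods = "delta")
  ana <- st$analysis
  # share the psi labels across groups
  for (g in 1:2) {
    ana$groups[[g]]$PS <- mm_psi(c("eM", "eY"), c(NA, NA), c("M", "Y"))
    diag(ana$groups[[g]]$PS$pop) <- diag(st$population$groups[[g]]$PS$pop)
  }
  st2 <- power_study(st$population, ana, st$design, nRep = 60, seed = 55,
                     methods = "delta")
  res <- run_power_study(st2)
  s <- res$summary
  expect_lt(abs(s$average_bias[s$parameter == "b"]), 0.1)
  # the shared psi labels bind cells with conflicting truths -> NA bias
  expect_true(is.na(s$average_bias[s$parameter == "eM"]))
})
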