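# Preset study builders for the four canonical designs: single- and
# multigroup simple mediation, and single- and multigroup moderated
# mediation (Hayes model 7 / Preacher model 2 with a dichotomous moderator).
# Defaults are the standardized smallest-effects-of-interest used throughout
# the package's worked examples: a = .5, b = .4, c' = .2, a.mod = .3,
# moderator simple effects +.1 (on M) and -.1 (on Y), 50 per arm / 25 per
# cell, alpha = .05.

#' Single-group simple mediation study (X -> M -> Y)
#'
#' Population and analysis model: \code{M ~ a*X}, \code{Y ~ b*M + c*X},
#' standardized slopes (residual variances solved so total variances are 1
#' given the fixed balanced design), no mean structure.  Defined
#' parameters: the indirect effect \code{ab := a*b} and the total effect
#' \code{total := c + a*b}.
#'
#' @param a,b,c standardized population paths.
#' @param n_per_group observations per treatment arm.
#' @param meanstructure also estimate (zero-population) intercepts; with
#'   intercepts the model is an exact reparameterization of the
#'   constrained multigroup formulation, fit for fit.
#' @param ... passed to \code{\link{power_study}} (nRep, seed, alpha,
#'   methods, mcci_draws).
#' @return an \code{mm_study}.
#' @export
preset_simple_mediation <- function(a = 0.5, b = 0.4, c = 0.2,
                                    n_per_group = 50, meanstructure = FALSE,
                                    ...) {
  build <- function(n) {
    design <- factorial_design("X", n)
    KA <- mm_matrix("KA", free = matrix(c("a", "c"), 2, 1,
                                        dimnames = list(c("M", "Y"), "X")),
                    pop = matrix(c(a, c), 2, 1, dimnames = list(c("M", "Y"), "X")))
    BE <- mm_matrix("BE", free = matrix(c(NA, "b", NA, NA), 2, 2,
                                        dimnames = list(c("M", "Y"), c("M", "Y"))),
                    pop = matrix(c(0, b, 0, 0), 2, 2,
                                 dimnames = list(c("M", "Y"), c("M", "Y"))))
    PS <- mm_psi(free = c("psi.M", "psi.Y"), pop = c(NA, NA), names = c("M", "Y"))
    AL <- if (meanstructure)
      mm_matrix("AL", free = cbind(c("i.M", "i.Y")), pop = cbind(c(0, 0)))
    mod <- path_model(KA = KA, BE = BE, PS = PS, AL = AL,
                      defined = c("ab := a*b", "total := c + a*b"),
                      meanstructure = meanstructure)
    mod <- standardize_model(mod, covariate_moments(design))
    list(population = mod, analysis = mod, design = design)
  }
  parts <- build(n_per_group)
  power_study(parts$population, parts$analysis, parts$design,
              builder = build, ...)
}

#' Multigroup simple mediation study (grouping on X)
#'
#' The statistically equivalent multigroup formulation: the predictor is
#' the grouping variable, the a and c' paths become differences between
#' group intercepts (offsets -effect/2 in control, +effect/2 in
#' treatment), and the analysis optionally constrains b and the residual
#' variances equal across groups.  Residual variances are taken from the
#' single-group standardization so parameters stay in pooled-SD units.
#' Defined parameters: \code{ab := (a1 - a0)*b},
#' \code{total := (c1 - c0) + (a1 - a0)*b}.
#'
#' @param a,b,c standardized population paths.
#' @param n_per_group observations per group.
#' @param constrain constrain b and residual variances across groups
#'   (default TRUE, which makes the model equivalent to the single-group
#'   one).
#' @param ... passed to \code{\link{power_study}}.
#' @export
preset_simple_mediation_multigroup <- function(a = 0.5, b = 0.4, c = 0.2,
                                               n_per_group = 50,
                                               constrain = TRUE, ...) {
  build <- function(n) {
    # pooled-SD standardization from the equivalent single-group model
    single <- factorial_design("X", n)
    sKA <- mm_matrix("KA", free = matrix(c("a", "c"), 2, 1,
                                         dimnames = list(c("M", "Y"), "X")),
                     pop = matrix(c(a, c), 2, 1, dimnames = list(c("M", "Y"), "X")))
    sBE <- mm_matrix("BE", free = matrix(c(NA, "b", NA, NA), 2, 2,
                                         dimnames = list(c("M", "Y"), c("M", "Y"))),
                     pop = matrix(c(0, b, 0, 0), 2, 2,
                                  dimnames = list(c("M", "Y"), c("M", "Y"))))
    smod <- path_model(KA = sKA, BE = sBE,
                       PS = mm_psi(c("psi.M", "psi.Y"), c(NA, NA), c("M", "Y")),
                       meanstructure = FALSE)
    psi <- solve_residual_variances(smod, covariate_moments(single))

    off <- intercept_offsets(c(M = a, Y = c))
    be_names <- list(c("M", "Y"), c("M", "Y"))
    BE <- mm_matrix("BE", free = matrix(c(NA, if (constrain) "b" else NA, NA, NA),
                                        2, 2, dimnames = be_names),
                    pop = matrix(c(0, b, 0, 0), 2, 2, dimnames = be_names))
    BE2 <- if (constrain) BE else
      mm_matrix("BE", free = matrix(c(NA, "b1", NA, NA), 2, 2, dimnames = be_names),
                pop = matrix(c(0, b, 0, 0), 2, 2, dimnames = be_names))
    if (!constrain)
      BE <- mm_matrix("BE", free = matrix(c(NA, "b0", NA, NA), 2, 2,
                                          dimnames = be_names),
                      pop = matrix(c(0, b, 0, 0), 2, 2, dimnames = be_names))
    psi_lab <- function(g) if (constrain) c("eM", "eY")
                           else paste0(c("eM", "eY"), g)
    mk_group <- function(alpha_pop, labels, g)
      list(KA = NULL, BE = if (g == 1) BE else BE2,
           PS = mm_psi(psi_lab(g), unname(psi), c("M", "Y")),
           AL = mm_matrix("AL", free = cbind(labels),
                          pop = cbind(unname(alpha_pop))))
    groups <- list(control = mk_group(off$control, c("a0", "c0"), 1),
                   treatment = mk_group(off$treatment, c("a1", "c1"), 2))
    bb <- if (constrain) "b" else "b1"   # treatment-group b in definitions
    mod <- path_model(groups = groups, endogenous = c("M", "Y"),
                      covariates = character(0),
                      defined = c(sprintf("ab := (a1 - a0)*%s", bb),
                                  sprintf("total := (c1 - c0) + (a1 - a0)*%s", bb)),
                      meanstructure = TRUE, group_column = "X")
    design <- set_group(factorial_design("X", n), "X")
    list(population = mod, analysis = mod, design = design)
  }
  parts <- build(n_per_group)
  power_study(parts$population, parts$analysis, parts$design,
              builder = build, ...)
}

#' Single-group moderated mediation study (W moderates the a path)
#'
#' A 2x2 design over X (predictor) and W (moderator) with the interaction
#' column X:W.  Slopes to M over (X, W, X:W) are (a.w0, w_on_m, a.mod);
#' slopes to Y are (c.w0, w_on_y, 0 fixed) plus the b path.  Residual
#' variances are solved so total variances equal 1.  Defined parameters:
#' the conditional indirect effects \code{ind.w0 := a.w0*b} and
#' \code{ind.w1 := (a.w0 + a.mod)*b}, the index of moderated mediation
#' \code{index := a.mod*b}, and its algebraically identical difference form
#' \code{ind.diff := ind.w1 - ind.w0}.
#'
#' @param a.w0 X -> M slope when W = 0.
#' @param a.mod change in the a path when W = 1 (the moderation effect).
#' @param b M -> Y slope.
#' @param c.w0 X -> Y direct effect.
#' @param w_on_m,w_on_y simple effects of the moderator on M and Y
#'   (nonzero nuisance paths of the population model).
#' @param n_per_cell observations per design cell (N = 4 cells).
#' @param ... passed to \code{\link{power_study}}.
#' @export
preset_modmed <- function(a.w0 = 0.5, a.mod = 0.3, b = 0.4, c.w0 = 0.2,
                          w_on_m = 0.1, w_on_y = -0.1, n_per_cell = 25, ...) {
  build <- function(n) {
    design <- add_interaction(factorial_design(c("X", "W"), n), "X", "W")
    covs <- c("X", "W", "X:W")
    dn <- list(c("M", "Y"), covs)
    KA <- mm_matrix("KA",
                    free = matrix(c("a.w0", "c.w0", "w.m", "w.y", "a.mod", NA),
                                  2, 3, dimnames = dn),
                    pop = matrix(c(a.w0, c.w0, w_on_m, w_on_y, a.mod, 0),
                                 2, 3, dimnames = dn))
    BE <- mm_matrix("BE", free = matrix(c(NA, "b", NA, NA), 2, 2,
                                        dimnames = list(c("M", "Y"), c("M", "Y"))),
                    pop = matrix(c(0, b, 0, 0), 2, 2,
                                 dimnames = list(c("M", "Y"), c("M", "Y"))))
    mod <- path_model(KA = KA, BE = BE,
                      PS = mm_psi(c("psi.M", "psi.Y"), c(NA, NA), c("M", "Y")),
                      defined = c("ind.w0 := a.w0*b",
                                  "ind.w1 := (a.w0 + a.mod)*b",
                                  "index := a.mod*b",
                                  "ind.diff := ind.w1 - ind.w0"),
                      meanstructure = FALSE)
    mod <- standardize_model(mod, covariate_moments(design))
    list(population = mod, analysis = mod, design = design)
  }
  parts <- build(n_per_cell)
  power_study(parts$population, parts$analysis, parts$design,
              builder = build, ...)
}

#' Multigroup moderated mediation study (moderator as grouping variable)
#'
#' The moderator W defines the groups; X stays a dummy covariate, balanced
#' within each group.  Moderation of the a path is expressed as different
#' within-group X -> M slopes (a.w0 vs a.w1); the b path is
#' equality-constrained across groups via a shared label.  Control-group
#' residual variances are the pooled standardizing values of the
#' single-group formulation; treatment variances are \code{var_ratio}
#' times larger (heteroskedasticity).  Analysis model: b shared, a and
#' residual variances free per group, and the X -> Y path free per group
#' by default (\code{constrain_c = TRUE} shares it).  Defined parameters:
#' \code{ind.w0 := a.w0*b}, \code{ind.w1 := a.w1*b},
#' \code{ind.diff := ind.w1 - ind.w0} (the index of moderated mediation).
#'
#' @param a.w0,a.w1 within-group X -> M slopes (control, treatment).
#' @param b shared M -> Y slope.
#' @param c X -> Y direct effect (same population value in both groups).
#' @param var_ratio treatment/control residual-variance ratio.
#' @param n_per_group observations per moderator group (even; X balanced
#'   within group).
#' @param constrain_c share the X -> Y label across groups.
#' @param intercepts estimate free per-group intercepts in the analysis
#'   model (default TRUE, the standard behavior of multigroup SEM fitters;
#'   the population stays zero-mean either way).
#' @param ... passed to \code{\link{power_study}}.
#' @export
preset_modmed_multigroup <- function(a.w0 = 0.5, a.w1 = 0.8, b = 0.4, c = 0.2,
                                     var_ratio = 1.5, n_per_group = 50,
                                     constrain_c = FALSE, intercepts = TRUE,
                                     ...) {
  build <- function(n) {
    if (n %% 2L) stop("'n_per_group' must be even (X balanced within group)",
                      call. = FALSE)
    # pooled standardizing variances from the single-group 2x2 formulation
    pooled_design <- add_interaction(factorial_design(c("X", "W"), n / 2), "X", "W")
    covs <- c("X", "W", "X:W")
    dn <- list(c("M", "Y"), covs)
    pooledKA <- mm_matrix("KA",
                          free = matrix(NA_character_, 2, 3, dimnames = dn),
                          pop = matrix(c(a.w0, c, 0.1, -0.1, a.w1 - a.w0, 0),
                                       2, 3, dimnames = dn))
    be_names <- list(c("M", "Y"), c("M", "Y"))
    BEfree <- matrix(c(NA, "b", NA, NA), 2, 2, dimnames = be_names)
    BEpop <- matrix(c(0, b, 0, 0), 2, 2, dimnames = be_names)
    pooled <- path_model(KA = pooledKA, BE = mm_matrix("BE", BEfree, BEpop),
                         PS = mm_psi(c("psi.M", "psi.Y"), c(NA, NA), c("M", "Y")),
                         meanstructure = FALSE)
    psi <- solve_residual_variances(pooled, covariate_moments(pooled_design))

    kdn <- list(c("M", "Y"), "X")
    mk_group <- function(g, a_lab, a_val, c_lab, psi_vals)
      list(KA = mm_matrix("KA", free = matrix(c(a_lab, c_lab), 2, 1, dimnames = kdn),
                          pop = matrix(c(a_val, c), 2, 1, dimnames = kdn)),
           BE = mm_matrix("BE", BEfree, BEpop),
           PS = mm_psi(paste0(c("psi.M", "psi.Y"), g), unname(psi_vals),
                       c("M", "Y")))
    c_labs <- if (constrain_c) c("c", "c") else c("c.w0", "c.w1")
    groups <- list(control = mk_group(1, "a.w0", a.w0, c_labs[1], psi),
                   treatment = mk_group(2, "a.w1", a.w1, c_labs[2],
                                        psi * var_ratio))
    mod <- path_model(groups = groups, endogenous = c("M", "Y"),
                      covariates = "X",
                      defined = c("ind.w0 := a.w0*b", "ind.w1 := a.w1*b",
                                  "ind.diff := ind.w1 - ind.w0"),
                      meanstructure = FALSE, group_column = "W")
    ana <- mod
    if (intercepts) {
      # analysis estimates per-group intercepts (population means are zero),
      # matching how multigroup SEM fitters parameterize group models
      for (g in 1:2)
        ana$groups[[g]]$AL <- mm_matrix(
          "AL", free = cbind(paste0(c("i.M", "i.Y"), g)), pop = cbind(c(0, 0)))
      ana$meanstructure <- TRUE
    }
    design <- set_group(factorial_design(c("W", "X"), n / 2), "W")
    list(population = mod, analysis = ana, design = design)
  }
  parts <- build(n_per_group)
  power_study(parts$population, parts$analysis, parts$design,
              builder = build, ...)
}
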