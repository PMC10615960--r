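# Shared fixtures, built in code.

simple_mediation_model <- function(a = 0.5, b = 0.4, c = 0.2, psi = c(NA, NA),
                                   meanstructure = FALSE) {
  dn <- list(c("M", "Y"), "X")
  KA <- mm_matrix("KA", free = matrix(c("a", "c"), 2, 1, dimnames = dn),
                  pop = matrix(c(a, c), 2, 1, dimnames = dn))
  BE <- mm_matrix("BE",
                  free = matrix(c(NA, "b", NA, NA), 2, 2,
                                dimnames = list(c("M", "Y"), c("M", "Y"))),
                  pop = matrix(c(0, b, 0, 0), 2, 2,
                               dimnames = list(c("M", "Y"), c("M", "Y"))))
  AL <- if (meanstructure)
    mm_matrix("AL", free = cbind(c("i.M", "i.Y")), pop = cbind(c(0, 0)))
  path_model(KA = KA, BE = BE, PS = mm_psi(c("psi.M", "psi.Y"), psi, c("M", "Y")),
             AL = AL, defined = c("ab := a*b", "total := c + a*b"),
             meanstructure = meanstructure)
}

# a random recursive 3-variable model over 2 covariates, slopes small enough
# that standardization is feasible
random_recursive_model <- function(seed) {
  set.seed(seed)
  endo <- c("M1", "M2", "Y")
  covs <- c("X", "W")
  kdn <- list(endo, covs)
  K <- matrix(round(runif(6, -0.3, 0.3), 3), 3, 2, dimnames = kdn)
  bdn <- list(endo, endo)
  B <- matrix(0, 3, 3, dimnames = bdn)
  B[lower.tri(B)] <- round(runif(3, -0.3, 0.3), 3)
  kfree <- matrix(paste0("k", seq_len(6)), 3, 2, dimnames = kdn)
  bfree <- matrix(NA_character_, 3, 3, dimnames = bdn)
  bfree[lower.tri(bfree)] <- paste0("be", 1:3)
  path_model(KA = mm_matrix("KA", kfree, K),
             BE = mm_matrix("BE", bfree, B),
             PS = mm_psi(paste0("ps", 1:3), rep(NA, 3), endo),
             meanstructure = FALSE)
}

design_2x2 <- function(n = 25) add_interaction(factorial_design(c("X", "W"), n),
                                               "X", "W")

# binomial Monte Carlo standard error
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
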