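#' Two-sided Wald test of H0: parameter = 0
#'
#' Standard normal-theory test: \eqn{z = \hat\theta / SE}, two-sided p
#' value, symmetric \eqn{(1-\alpha)} confidence interval
#' \eqn{\hat\theta \pm z_{1-\alpha/2} SE}; the null is rejected exactly
#' when the interval excludes zero.
#'
#' @param estimate point estimate.
#' @param se standard error (must be positive).
#' @param alpha significance level (default 0.05).
#' @param parameter optional name carried through to the result.
#' @return a one-row data frame of class \code{mm_test}: parameter, method
#'   ("delta"), estimate, se, ci_low, ci_high, reject, alpha.
#' @examples
#' wald_test(0.2, 0.0883)   # z = 2.26, rejected at alpha = .05
#' @export
wald_test <- function(estimate, se, alpha = 0.05, parameter = NA_character_) {
  if (!is.finite(se) || se <= 0) stop("invalid SE: must be positive", call. = FALSE)
  zc <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(parameter = parameter, method = "delta",
                    estimate = estimate, se = se,
                    ci_low = estimate - zc * se, ci_high = estimate + zc * se,
                    reject = abs(estimate / se) > zc, alpha = alpha)
  class(out) <- c("mm_test", "data.frame")
  out
}

#' Monte Carlo confidence intervals for defined parameters
#'
#' Parametric-bootstrap (Monte Carlo) interval: only the free parameter
#' estimates themselves are assumed normal.  Draws are taken from the
#' multivariate normal sampling distribution of the estimates (restricted
#' to the labels the expressions use), each expression is evaluated per
#' draw, and the interval is the empirical \eqn{(\alpha/2, 1-\alpha/2)}
#' percentile range; H0: parameter = 0 is rejected when the interval
#' excludes zero.  More robust than the delta method in small samples
#' because the product of normals need not be normal.
#'
#' @param fit an \code{mm_fit} with available \code{vcov}.
#' @param defined definitions to test (default: the fitted model's).
#' @param draws number of parameter draws (default 20000; at least 100).
#' @param alpha significance level.
#' @param seed optional integer seed; \code{stream} (an L'Ecuyer state)
#'   takes precedence and is what the power engine uses so interval noise
#'   is independent of data noise.
#' @param stream optional RNG stream state.
#' @return an \code{mm_test} data frame, one row per defined parameter
#'   (method "mcci").
#' @export
mcci <- function(fit, defined = fit$model$defined, draws = 20000L,
                 alpha = 0.05, seed = NULL, stream = NULL) {
  defined <- defined_params(defined)
  if (draws < 100L) stop("draws < 100 gives unstable percentiles", call. = FALSE)
  if (!fit$vcov_ok) stop("vcov unavailable; cannot form Monte Carlo CI", call. = FALSE)
  base_labs <- intersect(defined_base_labels(defined), names(fit$estimates))
  V <- fit$vcov[base_labs, base_labs, drop = FALSE]
  est <- fit$estimates[base_labs]
  point <- unlist(evaluate_defined(defined, as.list(fit$estimates)))
  run <- function() {
    # draw from MVN(est, V); V may be rank-deficient, use eigen square root
    ev <- eigen(V, symmetric = TRUE)
    rt <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
    E <- matrix(stats::rnorm(draws * length(est)), draws) %*% rt
    E <- sweep(E, 2, est, "+")
    colnames(E) <- base_labs
    vals <- evaluate_defined(defined, as.data.frame(E))
    rows <- lapply(names(defined), function(nm) {
      ci <- unname(stats::quantile(vals[[nm]], c(alpha / 2, 1 - alpha / 2),
                                   type = 7, names = FALSE))
      data.frame(parameter = nm, method = "mcci",
                 estimate = unname(point[nm]), se = NA_real_,
                 ci_low = ci[1], ci_high = ci[2],
                 reject = ci[1] > 0 || ci[2] < 0, alpha = alpha)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("mm_test", "data.frame")
    out
  }
  if (!is.null(stream)) with_stream(stream, run())
  else if (!is.null(seed)) { set.seed(seed); run() }
  else run()
}
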