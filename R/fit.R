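# Fitting: conditional Gaussian maximum likelihood for recursive path models
# with fixed covariates and shared-label equality constraints.
#
# Because the model is recursive with diagonal residual covariance, the
# conditional likelihood factors into one Gaussian regression per
# (group, equation) cell; equality constraints couple cells through shared
# coefficient or variance labels.  Coefficients enter linearly, so for fixed
# variances the ML coefficients solve one stacked weighted least-squares
# problem, and for fixed coefficients each shared variance is a pooled
# residual mean square (ML divisor n).  Alternating the two exact updates is
# a fast coordinate ascent on the log-likelihood; unconstrained models
# converge in one round to the per-equation OLS solution.

# --- build the per-(group, equation) regression cells ----------------------
fit_context <- function(model, data) {
  endo <- model$endogenous
  gcol <- model$group_column
  G <- n_groups(model)
  if (G > 1L) {
    if (is.null(gcol) || !gcol %in% names(data))
      stop("multigroup model: data must contain group column '",
           gcol %||% "group", "'", call. = FALSE)
    grp <- data[[gcol]]
    if (!setequal(unique(grp), seq_len(G)))
      stop("group codes must be sequential integers 1..", G, call. = FALSE)
  } else grp <- rep(1L, nrow(data))
  missing <- setdiff(c(endo, model$covariates), names(data))
  if (length(missing))
    stop("data lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)

  cells <- list()
  coef_labels <- character(0)
  psi_labels <- character(0)
  for (g in seq_len(G)) {
    rows <- which(grp == g)
    spec <- model$groups[[g]]
    for (v in endo) {
      i <- match(v, endo)
      y <- data[[v]][rows]
      n <- length(y)
      offset <- rep(0, n)
      Zcols <- list()
      # intercept
      if (model$meanstructure) {
        al <- spec$AL
        lab <- if (!is.null(al)) al$labels[i, 1] else NA_character_
        val <- if (!is.null(al)) al$pop[i, 1] else 0
        if (!is.na(lab)) Zcols[[lab]] <- rep(1, n)
        else offset <- offset + val
      }
      # covariate regressors (KA row)
      if (!is.null(spec$KA)) for (cv in colnames(spec$KA$pop)) {
        j <- match(cv, colnames(spec$KA$pop))
        lab <- spec$KA$labels[i, j]
        col <- data[[cv]][rows]
        if (!is.na(lab))
          Zcols[[lab]] <- (Zcols[[lab]] %||% 0) + col
        else if (spec$KA$pop[i, j] != 0)
          offset <- offset + spec$KA$pop[i, j] * col
      }
      # endogenous regressors (BE row)
      for (ev in endo) {
        j <- match(ev, endo)
        lab <- spec$BE$labels[i, j]
        col <- data[[ev]][rows]
        if (!is.na(lab))
          Zcols[[lab]] <- (Zcols[[lab]] %||% 0) + col
        else if (!is.na(spec$BE$pop[i, j]) && spec$BE$pop[i, j] != 0)
          offset <- offset + spec$BE$pop[i, j] * col
      }
      plab <- spec$PS$labels[i, i]
      pfix <- if (is.na(plab)) spec$PS$pop[i, i] else NA_real_
      Z <- if (length(Zcols)) do.call(cbind, Zcols) else matrix(0, n, 0)
      cells[[length(cells) + 1L]] <- list(
        group = g, var = v, y = y, n = n, offset = offset, Z = Z,
        labels = names(Zcols), psi_label = plab, psi_fixed = pfix)
      coef_labels <- union(coef_labels, names(Zcols))
      if (!is.na(plab)) psi_labels <- union(psi_labels, plab)
    }
  }
  list(cells = cells, coef_labels = coef_labels, psi_labels = psi_labels,
       n_per_group = tabulate(grp, G))
}

cell_loglik <- function(n, rss, psi) {
  -n / 2 * log(2 * pi * psi) - rss / (2 * psi)
}

#' Fit a path model by conditional maximum likelihood
#'
#' Fits the analysis model to one dataset, honoring every equality
#' constraint encoded by shared labels (across equations and across
#' groups).  Estimation maximizes the Gaussian log-likelihood of the
#' endogenous variables conditional on the fixed covariates, by
#' alternating exact weighted-least-squares updates of the coefficients
#' and pooled residual-mean-square updates of the variances.  With no
#' shared labels the solution coincides with per-equation ordinary least
#' squares (ML variance divisor \eqn{n_g}).  The asymptotic covariance of
#' the distinct free parameters comes from the observed information at the
#' optimum (analytic second derivatives); the expected information is
#' available for cross-checks.
#'
#' @param model the analysis \code{mm_model}.
#' @param data an \code{mm_data} frame (or any data frame with the model's
#'   covariate, endogenous and group columns).
#' @param information \code{"observed"} (default) or \code{"expected"}.
#' @param max_iter,tol iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return an object of class \code{mm_fit}: \code{estimates} (named over
#'   distinct labels, slopes then residual variances), \code{vcov},
#'   \code{loglik}, \code{converged}, \code{boundary} (TRUE when a residual
#'   variance hit zero), \code{defined} (values of user-defined
#'   parameters), \code{n_per_group}.  Nonconvergence and boundary issues
#'   are reported through flags, never exceptions, so batch simulation can
#'   proceed.
#' @examples
#' st <- preset_simple_mediation()
#' dat <- generate_sample(st$population, st$design, seed = 1)
#' fit <- fit_path_model(st$analysis, dat)
#' coef(fit)
#' @export
fit_path_model <- function(model, data, information = c("observed", "expected"),
                           max_iter = 500L, tol = 1e-12) {
  information <- match.arg(information)
  ctx <- fit_context(model, data)
  cells <- ctx$cells
  k <- length(ctx$coef_labels)
  theta <- stats::setNames(rep(0, k), ctx$coef_labels)
  psi <- stats::setNames(rep(1, length(ctx$psi_labels)), ctx$psi_labels)
  psi_of <- function(cell) if (is.na(cell$psi_label)) cell$psi_fixed else psi[[cell$psi_label]]
  boundary <- FALSE
  singular <- FALSE
  ll <- NA_real_
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # exact WLS update of all coefficients given variances
    if (k) {
      A <- matrix(0, k, k, dimnames = list(ctx$coef_labels, ctx$coef_labels))
      bvec <- stats::setNames(rep(0, k), ctx$coef_labels)
      for (cell in cells) {
        if (!length(cell$labels)) next
        w <- 1 / max(psi_of(cell), 1e-10)
        A[cell$labels, cell$labels] <- A[cell$labels, cell$labels] +
          w * crossprod(cell$Z)
        bvec[cell$labels] <- bvec[cell$labels] +
          w * drop(crossprod(cell$Z, cell$y - cell$offset))
      }
      theta_new <- tryCatch(drop(solve(A, bvec)), error = function(e) NULL)
      if (is.null(theta_new)) { singular <- TRUE; break }
      theta <- stats::setNames(theta_new, ctx$coef_labels)
    }
    # exact pooled update of shared variances given coefficients
    rss_cell <- vapply(cells, function(cell) {
      r <- cell$y - cell$offset -
        if (length(cell$labels)) drop(cell$Z %*% theta[cell$labels]) else 0
      sum(r * r)
    }, 0)
    if (length(psi)) {
      for (pl in names(psi)) {
        sel <- vapply(cells, function(c) identical(c$psi_label, pl), TRUE)
        psi[[pl]] <- sum(rss_cell[sel]) / sum(vapply(cells[sel], `[[`, 0, "n"))
      }
      if (any(psi < 1e-10)) { boundary <- TRUE; psi[psi < 1e-10] <- 1e-10 }
    }
    ll <- sum(vapply(seq_along(cells), function(i)
      cell_loglik(cells[[i]]$n, rss_cell[i], psi_of(cells[[i]])), 0))
    if (is.finite(ll) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  estimates <- c(theta, psi)

  # residuals per cell at the optimum (reused by information and methods)
  resid_cell <- lapply(cells, function(cell) {
    cell$y - cell$offset -
      if (length(cell$labels)) drop(cell$Z %*% theta[cell$labels]) else 0
  })

  V <- if (singular)
    list(vcov = matrix(NA_real_, length(estimates), length(estimates),
                       dimnames = list(names(estimates), names(estimates))),
         ok = FALSE)
  else fit_information(cells, theta, psi, resid_cell, information)
  defined_values <- if (!is.null(model$defined))
    unlist(evaluate_defined(model$defined, as.list(estimates))) else NULL

  structure(list(estimates = estimates, vcov = V$vcov,
                 vcov_ok = V$ok, loglik = ll, converged = converged,
                 boundary = boundary, iterations = iter,
                 defined = defined_values,
                 n_per_group = ctx$n_per_group, model = model,
                 residuals_by_cell = resid_cell,
                 cells = lapply(cells, function(c) c[c("group", "var", "n")])),
            class = "mm_fit")
}

# analytic observed (or expected) information over (coefficients, variances)
fit_information <- function(cells, theta, psi, resid_cell, information) {
  labs <- c(names(theta), names(psi))
  k <- length(theta); q <- length(psi)
  H <- matrix(0, k + q, k + q, dimnames = list(labs, labs))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    p <- if (is.na(cell$psi_label)) cell$psi_fixed else psi[[cell$psi_label]]
    r <- resid_cell[[ci]]
    rss <- sum(r * r)
    if (length(cell$labels))
      H[cell$labels, cell$labels] <- H[cell$labels, cell$labels] +
        crossprod(cell$Z) / p
    if (!is.na(cell$psi_label)) {
      pl <- cell$psi_label
      H[pl, pl] <- H[pl, pl] +
        if (information == "observed") rss / p^3 - cell$n / (2 * p^2)
        else cell$n / (2 * p^2)
      if (length(cell$labels) && information == "observed") {
        cross <- drop(crossprod(cell$Z, r)) / p^2
        H[cell$labels, pl] <- H[cell$labels, pl] + cross
        H[pl, cell$labels] <- H[pl, cell$labels] + cross
      }
    }
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  ok <- !is.null(V) && all(is.finite(V)) && all(diag(V) > -1e-8)
  list(vcov = if (ok) V else matrix(NA_real_, k + q, k + q,
                                    dimnames = list(labs, labs)),
       ok = ok)
}

#' Delta-method standard error of a defined parameter
#'
#' First-order (delta-method) standard error of a smooth function of the
#' estimates: \eqn{\sqrt{g' V g}} with \eqn{g} the gradient of the
#' expression at the point estimates (central finite differences).  For the
#' product \eqn{ab} with independent estimates this reduces to the Sobel
#' formula \eqn{\sqrt{b^2 SE_a^2 + a^2 SE_b^2}}.
#'
#' @param fit an \code{mm_fit} with available \code{vcov}.
#' @param defined definitions (see \code{\link{defined_params}}); defaults
#'   to the fitted model's.
#' @param names which defined parameters (default all).
#' @return named vector of standard errors (NA when vcov is unavailable).
#' @export
delta_se <- function(fit, defined = fit$model$defined, names = NULL) {
  defined <- defined_params(defined)
  if (is.null(names)) names <- base::names(defined)
  out <- stats::setNames(rep(NA_real_, length(names)), names)
  if (!fit$vcov_ok) return(out)
  for (nm in names) {
    upto <- seq_len(match(nm, base::names(defined)))
    base_labs <- intersect(defined_base_labels(defined[upto]),
                           base::names(fit$estimates))
    g <- defined_gradient(defined[upto], nm, fit$estimates[base_labs])
    V <- fit$vcov[base_labs, base_labs, drop = FALSE]
    out[nm] <- sqrt(drop(t(g) %*% V %*% g))
  }
  out
}

# ---- S3 methods -----------------------------------------------------------

#' @export
coef.mm_fit <- function(object, ...) object$estimates

#' @export
vcov.mm_fit <- function(object, ...) object$vcov

#' @export
logLik.mm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates), class = "logLik")
}

#' @export
residuals.mm_fit <- function(object, ...) {
  out <- data.frame(
    group = rep(vapply(object$cells, `[[`, 0L, "group"),
                vapply(object$cells, `[[`, 0L, "n")),
    variable = rep(vapply(object$cells, `[[`, "", "var"),
                   vapply(object$cells, `[[`, 0L, "n")),
    residual = unlist(object$residuals_by_cell))
  rownames(out) <- NULL
  out
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Path model fit: logLik %.3f, %s%s\n", x$loglik,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              if (x$boundary) " (residual variance at boundary)" else ""))
  print(round(x$estimates, digits))
  if (!is.null(x$defined)) {
    cat("Defined parameters:\n")
    print(round(x$defined, digits))
  }
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, alpha = 0.05, ...) {
  se <- if (object$vcov_ok) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, length(object$estimates))
  z <- object$estimates / se
  tab <- data.frame(estimate = object$estimates, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    ci_low = object$estimates - stats::qnorm(1 - alpha / 2) * se,
                    ci_high = object$estimates + stats::qnorm(1 - alpha / 2) * se)
  dtab <- NULL
  if (!is.null(object$model$defined)) {
    dse <- delta_se(object)
    est <- object$defined
    zd <- est / dse
    dtab <- data.frame(estimate = est, se = dse, z = zd,
                       p = 2 * stats::pnorm(-abs(zd)),
                       ci_low = est - stats::qnorm(1 - alpha / 2) * dse,
                       ci_high = est + stats::qnorm(1 - alpha / 2) * dse)
  }
  structure(list(coefficients = tab, defined = dtab, fit = object,
                 alpha = alpha), class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nFree parameters (delta-method Wald):\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$defined)) {
    cat("\nDefined parameters (delta-method Wald):\n")
    print(round(x$defined, digits))
  }
  invisible(x)
}
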