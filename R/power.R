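#' Define a Monte Carlo power study
#'
#' Bundles everything one simulation experiment needs: the population model
#' data are generated from, the analysis model fitted to each sample (the
#' two may differ, e.g. a heteroskedastic truth analyzed under constraints),
#' the fixed design, and the Monte Carlo settings.  Residual variances
#' declared automatic (\code{NA}) in the population model are solved at
#' construction so slopes are standardized.
#'
#' @param population \code{mm_model} generating the data.
#' @param analysis \code{mm_model} fitted to each sample (default: the
#'   population model itself).
#' @param design the fixed \code{mm_design}.
#' @param nRep number of replications (1000-5000 recommended).
#' @param seed master seed; every source of randomness descends from it.
#' @param alpha significance level.
#' @param methods subset of \code{c("delta", "mcci")}.
#' @param mcci_draws parameter draws per Monte Carlo CI.
#' @param builder optional function \code{function(n_per_cell)} returning a
#'   list \code{(population, analysis, design)}; enables
#'   \code{\link{power_curve}} to rebuild the study at other sample sizes.
#' @return an object of class \code{mm_study}.
#' @export
power_study <- function(population, analysis = population, design,
                        nRep = 1000L, seed = 12345L, alpha = 0.05,
                        methods = c("delta", "mcci"), mcci_draws = 20000L,
                        builder = NULL) {
  stopifnot(nRep >= 1L, alpha > 0, alpha < 1)
  methods <- match.arg(methods, several.ok = TRUE)
  if (anyNA(unlist(lapply(population$groups, function(g) diag(g$PS$pop))))) {
    mo <- covariate_moments(design)
    population <- standardize_model(population, mo)
  }
  structure(list(population = population, analysis = analysis,
                 design = design, nRep = as.integer(nRep),
                 seed = as.integer(seed), alpha = alpha, methods = methods,
                 mcci_draws = as.integer(mcci_draws), builder = builder),
            class = "mm_study")
}

# population values of the analysis model's labels, read off the population
# model's matrices (NA when a constrained label binds cells whose population
# values disagree)
truth_values <- function(population, analysis) {
  fc <- free_cells(analysis)
  if (!nrow(fc)) return(numeric(0))
  vals <- vapply(seq_len(nrow(fc)), function(r) {
    mat <- population$groups[[fc$group[r]]][[fc$role[r]]]
    if (is.null(mat)) {
      # absent population AL = zero intercepts (no mean structure)
      if (fc$role[r] == "AL") 0 else NA_real_
    } else mat$pop[fc$i[r], fc$j[r]]
  }, 0)
  out <- tapply(vals, fc$label, function(v)
    if (length(unique(round(v, 12))) == 1L) v[1] else NA_real_)
  truth <- stats::setNames(as.numeric(out), names(out))
  if (!is.null(analysis$defined) && !anyNA(truth)) {
    dv <- unlist(evaluate_defined(analysis$defined, as.list(truth)))
    truth <- c(truth, dv)
  } else if (!is.null(analysis$defined)) {
    base <- defined_base_labels(analysis$defined)
    if (all(base %in% names(truth)) && !anyNA(truth[base])) {
      dv <- unlist(evaluate_defined(analysis$defined, as.list(truth[base])))
      truth <- c(truth, dv)
    }
  }
  truth
}

#' Run a Monte Carlo power study
#'
#' The engine: for each replication, generate a sample conditional on the
#' fixed design (its own RNG substream), fit the analysis model, and test
#' every free and defined parameter with the requested methods.  Results
#' are deterministic given the master seed and independent of any worker
#' count because each replication owns a dedicated substream (data and
#' Monte Carlo CI draws use disjoint streams).
#'
#' @param study an \code{mm_study}.
#' @param progress print a dot every 100 replications.
#' @return an object of class \code{mm_power}: \code{summary} (a
#'   \code{\link{summarize_replications}} table), \code{records} (one entry
#'   per replication), \code{n_converged}, and the study.  All replications
#'   failing is an error; convergence below 95\% triggers a warning.
#' @examples
#' \donttest{
#' st <- preset_simple_mediation(nRep = 200, seed = 1)
#' run_power_study(st)
#' }
#' @export
run_power_study <- function(study, progress = FALSE) {
  stopifnot(inherits(study, "mm_study"))
  streams <- mm_streams(study$seed, 2L * study$nRep)
  records <- vector("list", study$nRep)
  for (r in seq_len(study$nRep)) {
    dat <- generate_sample(study$population, study$design,
                           stream = streams[[2L * r - 1L]])
    fit <- fit_path_model(study$analysis, dat)
    rec <- list(index = r, converged = fit$converged && fit$vcov_ok,
                boundary = fit$boundary)
    if (rec$converged) {
      est <- c(fit$estimates, fit$defined)
      se <- sqrt(pmax(diag(fit$vcov), 0))
      if (!is.null(study$analysis$defined))
        se <- c(se, delta_se(fit))
      rec$estimates <- est
      if ("delta" %in% study$methods) {
        zc <- stats::qnorm(1 - study$alpha / 2)
        rec$delta <- data.frame(parameter = names(est), estimate = est,
                                se = se,
                                ci_low = est - zc * se, ci_high = est + zc * se,
                                reject = abs(est / se) > zc)
      }
      if ("mcci" %in% study$methods && !is.null(study$analysis$defined)) {
        rec$mcci <- mcci(fit, draws = study$mcci_draws, alpha = study$alpha,
                         stream = streams[[2L * r]])
      }
    }
    records[[r]] <- rec
    if (progress && r %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  n_conv <- sum(vapply(records, `[[`, TRUE, "converged"))
  if (n_conv == 0L) stop("no replication converged", call. = FALSE)
  if (n_conv < 0.95 * study$nRep)
    warning(sprintf("convergence rate %.1f%% is below 95%%",
                    100 * n_conv / study$nRep), call. = FALSE)
  truth <- truth_values(study$population, study$analysis)
  structure(list(summary = summarize_replications(records, truth, study$alpha),
                 records = records, truth = truth,
                 n_converged = n_conv, study = study),
            class = "mm_power")
}

#' Aggregate replication records into a power summary
#'
#' Per parameter (free and defined), over converged replications: the
#' estimate average, average bias (estimate average minus population
#' value), coverage (proportion of delta-method confidence intervals
#' containing the population value), and power per method (proportion of
#' replications rejecting H0: parameter = 0).  Average bias with absolute
#' value at or above 0.10 is flagged.  Parameters without a population
#' value (e.g. a constrained label binding cells with conflicting truths)
#' get \code{NA} bias/coverage but still get power.
#'
#' @param records replication records from \code{\link{run_power_study}}.
#' @param truth named vector of population values.
#' @param alpha significance level used for the intervals.
#' @return data frame of class \code{mm_power_summary} with columns
#'   parameter, estimate_average, average_bias, bias_flag, coverage,
#'   power_delta, power_mcci, n_converged, nRep.
#' @export
summarize_replications <- function(records, truth = numeric(0), alpha = 0.05) {
  conv <- Filter(function(r) isTRUE(r$converged), records)
  if (!length(conv)) stop("no converged replication to summarize", call. = FALSE)
  params <- names(conv[[1]]$estimates)
  est_mat <- do.call(rbind, lapply(conv, function(r) r$estimates[params]))
  has_delta <- !is.null(conv[[1]]$delta)
  has_mcci <- !is.null(conv[[1]]$mcci)
  out <- data.frame(parameter = params,
                    estimate_average = colMeans(est_mat))
  out$average_bias <- if (length(truth))
    out$estimate_average - unname(truth[params]) else NA_real_
  out$bias_flag <- !is.na(out$average_bias) & abs(out$average_bias) >= 0.10
  cover <- power_d <- rep(NA_real_, length(params))
  if (has_delta) {
    lo <- do.call(rbind, lapply(conv, function(r) r$delta$ci_low))
    hi <- do.call(rbind, lapply(conv, function(r) r$delta$ci_high))
    rej <- do.call(rbind, lapply(conv, function(r) r$delta$reject))
    tv <- if (length(truth)) unname(truth[params]) else rep(NA_real_, length(params))
    cover <- colMeans(sweep(lo, 2, tv, "<=") & sweep(hi, 2, tv, ">="))
    power_d <- colMeans(rej)
  }
  out$coverage <- cover
  out$power_delta <- power_d
  out$power_mcci <- NA_real_
  if (has_mcci) {
    mnames <- conv[[1]]$mcci$parameter
    mrej <- colMeans(do.call(rbind, lapply(conv, function(r) r$mcci$reject)))
    out$power_mcci[match(mnames, out$parameter)] <- mrej
  }
  out$n_converged <- length(conv)
  out$nRep <- length(records)
  rownames(out) <- NULL
  class(out) <- c("mm_power_summary", "data.frame")
  out
}

#' Sweep sample size for a power curve
#'
#' Reruns the study over a grid of per-cell sample sizes.  Each grid point
#' rebuilds the design and re-solves the standardizing residual variances
#' (covariate moments depend on N through the unbiased divisor) via the
#' study's builder, and runs with its own independent seed offset.
#'
#' @param study an \code{mm_study} carrying a builder (presets do).
#' @param n_grid vector of per-cell (or per-group) sample sizes.
#' @return data frame of class \code{mm_curve}: N (total), n_per_cell,
#'   parameter, method, power; sorted by N.
#' @export
power_curve <- function(study, n_grid) {
  if (!length(n_grid)) stop("empty sample-size grid", call. = FALSE)
  if (is.null(study$builder))
    stop("study has no builder; construct it via a preset or supply one",
         call. = FALSE)
  n_grid <- sort(unique(n_grid))
  rows <- list()
  for (i in seq_along(n_grid)) {
    parts <- study$builder(n_grid[i])
    st <- power_study(parts$population, parts$analysis, parts$design,
                      nRep = study$nRep,
                      seed = (study$seed + 997L * i) %% .Machine$integer.max,
                      alpha = study$alpha, methods = study$methods,
                      mcci_draws = study$mcci_draws)
    res <- run_power_study(st)
    s <- res$summary
    for (m in study$methods) {
      p <- if (m == "delta") s$power_delta else s$power_mcci
      keep <- !is.na(p)
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          N = nrow(parts$design), n_per_cell = n_grid[i],
          parameter = s$parameter[keep], method = m, power = p[keep])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$N), ]
  rownames(out) <- NULL
  class(out) <- c("mm_curve", "data.frame")
  out
}

# ---- methods --------------------------------------------------------------

#' @export
print.mm_power <- function(x, digits = 4, ...) {
  st <- x$study
  cat(sprintf("Monte Carlo power study: nRep = %d (%d converged), N = %d, alpha = %g\n",
              st$nRep, x$n_converged, nrow(st$design), st$alpha))
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], digits)
  print.data.frame(s)
  if (any(x$summary$bias_flag))
    cat("note: parameters flagged for |average bias| >= 0.10\n")
  invisible(x)
}

#' @export
summary.mm_power <- function(object, ...) object$summary

#' @export
print.mm_power_summary <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y)
  invisible(x)
}

#' Plot a power curve
#'
#' @param x an \code{mm_curve} from \code{\link{power_curve}}.
#' @param parameters which parameters to draw (default all present).
#' @param ... passed to \code{matplot}.
#' @export
plot.mm_curve <- function(x, parameters = unique(x$parameter), ...) {
  x <- x[x$parameter %in% parameters, ]
  combos <- unique(x[, c("parameter", "method")])
  Ns <- sort(unique(x$N))
  mat <- sapply(seq_len(nrow(combos)), function(i) {
    sub <- x[x$parameter == combos$parameter[i] & x$method == combos$method[i], ]
    sub$power[match(Ns, sub$N)]
  })
  graphics::matplot(Ns, mat, type = "b", pch = 19, lty = 1,
                    xlab = "total sample size N", ylab = "empirical power",
                    ylim = c(0, 1), ...)
  graphics::abline(h = 0.8, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = paste(combos$parameter, combos$method, sep = " / "),
                   col = seq_len(nrow(combos)), pch = 19)
  invisible(x)
}

#' @export
print.mm_study <- function(x, ...) {
  cat(sprintf("Power study spec: nRep = %d, N = %d, alpha = %g, methods = %s, seed = %d\n",
              x$nRep, nrow(x$design), x$alpha,
              paste(x$methods, collapse = "+"), x$seed))
  invisible(x)
}
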