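#' Assemble a path model specification
#'
#' Collects per-group parameter matrices, user-defined parameters, and the
#' mean-structure flag into a single model object used both to generate
#' population data and as the analysis model fitted to each sample.  Free
#' labels shared across cells or groups denote equality-constrained
#' parameters; the model must be recursive (the endogenous slope matrix
#' \code{BE} permutable to strictly lower triangular).
#'
#' @param KA,BE,PS,AL parameter matrices (see \code{\link{mm_matrix}}) for a
#'   single-group model; \code{KA} and \code{AL} may be \code{NULL}.
#' @param groups alternatively, a named list of groups, each a list with
#'   elements \code{KA}, \code{BE}, \code{PS}, and optionally \code{AL}.
#' @param covariates covariate names (defaults to \code{colnames} of KA).
#' @param endogenous endogenous variable names (defaults to rownames of BE).
#' @param defined user-defined parameters (see \code{\link{defined_params}}).
#' @param meanstructure logical; if \code{FALSE}, intercepts are absent and
#'   population means are zero.
#' @param group_column name of the data column holding group codes
#'   (sequential integers 1..G); required for multigroup models.
#' @return an object of class \code{mm_model}.
#' @export
path_model <- function(KA = NULL, BE, PS, AL = NULL, groups = NULL,
                       covariates = NULL, endogenous = NULL,
                       defined = NULL, meanstructure = !is.null(AL) ||
                         (!is.null(groups) && any(vapply(groups, function(g) !is.null(g$AL), TRUE))),
                       group_column = if (!is.null(groups) && length(groups) > 1L) "group" else NULL) {
  if (is.null(groups)) {
    groups <- list(g1 = list(KA = KA, BE = BE, PS = PS, AL = AL))
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  g1 <- groups[[1]]
  if (is.null(endogenous)) {
    endogenous <- rownames(g1$BE$pop)
    if (is.null(endogenous)) endogenous <- paste0("V", seq_len(nrow(g1$BE$pop)))
  }
  if (is.null(covariates))
    covariates <- if (is.null(g1$KA)) character(0) else colnames(g1$KA$pop)
  p <- length(endogenous)
  for (gn in names(groups)) {
    g <- groups[[gn]]
    if (!inherits(g$BE, "mm_matrix") || g$BE$role != "BE" ||
        !inherits(g$PS, "mm_matrix") || g$PS$role != "PS")
      stop("each group needs BE and PS mm_matrix objects", call. = FALSE)
    if (nrow(g$BE$pop) != p || nrow(g$PS$pop) != p)
      stop("matrix dimensions must agree across groups", call. = FALSE)
    if (!is.null(g$KA) && (nrow(g$KA$pop) != p || ncol(g$KA$pop) != length(covariates)))
      stop("KA must be (endogenous x covariates) in every group", call. = FALSE)
    if (!is.null(g$AL) && nrow(g$AL$pop) != p)
      stop("AL must have one entry per endogenous variable", call. = FALSE)
    if (!meanstructure && !is.null(g$AL))
      stop("AL supplied but meanstructure is FALSE", call. = FALSE)
    validate_recursive(g$BE, endogenous)   # errors on cycles
  }
  if (!is.null(defined)) {
    defined <- defined_params(defined)
    known <- unique(stats::na.omit(unlist(lapply(groups, function(g)
      lapply(g[c("KA", "BE", "PS", "AL")], function(m) if (!is.null(m)) m$labels)))))
    bad <- setdiff(defined_base_labels(defined), known)
    if (length(bad))
      stop("defined parameters reference unknown label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- structure(list(groups = groups, endogenous = endogenous,
                      covariates = covariates, meanstructure = meanstructure,
                      defined = defined, group_column = group_column),
                 class = "mm_model")
  m
}

n_groups <- function(model) length(model$groups)

#' Topological order of a recursive endogenous slope matrix
#'
#' Returns an ordering of the endogenous variables in which each depends
#' only on earlier ones; errors if the structural graph has a cycle
#' (non-recursive model).  A cell of \code{BE} is structurally nonzero when
#' it is free or has a nonzero population value.
#'
#' @param BE a \code{BE} \code{mm_matrix}.
#' @param names optional variable names.
#' @return character vector: the endogenous variables in topological order.
#' @export
validate_recursive <- function(BE, names = rownames(BE$pop)) {
  p <- nrow(BE$pop)
  if (is.null(names)) names <- paste0("V", seq_len(p))
  active <- !is.na(BE$labels) | (!is.na(BE$pop) & BE$pop != 0)
  order <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    # a variable is ready when all its predecessors are already ordered
    ready <- remaining[vapply(remaining, function(i)
      !any(active[i, remaining]), TRUE)]
    # keep declaration order among ties
    if (!length(ready))
      stop("non-recursive model: cycle among endogenous variables", call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  names[order]
}

# population matrices of one group, as plain numerics
pop_matrices <- function(model, group = 1L) {
  g <- model$groups[[group]]
  p <- length(model$endogenous)
  K <- if (is.null(g$KA)) matrix(0, p, 0) else g$KA$pop
  list(K = K, B = g$BE$pop, PS = g$PS$pop,
       AL = if (is.null(g$AL)) rep(0, p) else drop(g$AL$pop))
}

#' Model-implied covariance matrix of the endogenous variables
#'
#' Reduced-form algebra for a recursive path model with fixed covariates:
#' \deqn{y = (I-B)^{-1}(Kx + \zeta)} so the endogenous covariance is
#' \eqn{\Pi \Sigma_x \Pi' + (I-B)^{-1}\Psi(I-B)^{-T}} with
#' \eqn{\Pi = (I-B)^{-1}K}.  Serves as the oracle for the standardization
#' solver: feeding solved residual variances back in must reproduce the
#' target total variances.
#'
#' @param model an \code{mm_model} with population values set.
#' @param moments \code{mm_moments} of the covariates (see
#'   \code{\link{covariate_moments}}).
#' @param group group index or name.
#' @return covariance matrix over the endogenous variables.
#' @export
implied_covariance <- function(model, moments, group = 1L) {
  m <- pop_matrices(model, group)
  if (anyNA(diag(m$PS)))
    stop("PS population diagonal not set; run solve_residual_variances first",
         call. = FALSE)
  p <- nrow(m$B)
  ImB <- diag(p) - m$B
  if (abs(det(ImB)) < 1e-12) stop("singular (I - B)", call. = FALSE)
  IB <- solve(ImB)
  Sx <- moments$covariance[colnames(m$K), colnames(m$K), drop = FALSE]
  Pi <- IB %*% m$K
  V <- Pi %*% Sx %*% t(Pi) + IB %*% m$PS %*% t(IB)
  dimnames(V) <- list(model$endogenous, model$endogenous)
  V
}

#' Solve residual variances that standardize total variances
#'
#' Chooses each endogenous variable's residual variance so that its
#' model-implied total variance equals a target (1 by default), i.e.
#' "residual variance = target minus explained variance".  Explained
#' variance is computed in topological order from the joint covariance of
#' the covariates and previously solved endogenous variables under the
#' population slopes.  With standardized targets this makes the population
#' slopes standardized coefficients.
#'
#' @param model an \code{mm_model}.
#' @param moments \code{mm_moments} of the covariates.
#' @param target named (or unnamed) vector of target total variances,
#'   recycled over endogenous variables; default 1.
#' @param group group index or name.
#' @return named vector of residual variances (the \code{PS} population
#'   diagonal for that group).
#' @export
solve_residual_variances <- function(model, moments, target = 1, group = 1L) {
  m <- pop_matrices(model, group)
  endo <- model$endogenous
  target <- rep_len(target, length(endo))
  names(target) <- endo
  order <- validate_recursive(model$groups[[group]]$BE, endo)
  covs <- colnames(m$K)
  if (is.null(covs)) covs <- character(0)
  # joint covariance over (covariates, solved endogenous), grown as we solve
  C <- moments$covariance[covs, covs, drop = FALSE]
  psi <- stats::setNames(numeric(length(endo)), endo)
  for (v in order) {
    i <- match(v, endo)
    pred <- c(stats::setNames(as.numeric(m$K[i, , drop = FALSE]), colnames(m$K)),
              stats::setNames(as.numeric(m$B[i, , drop = FALSE]), endo))
    pred <- pred[names(pred) %in% colnames(C)]
    w <- pred[pred != 0]
    explained <- if (length(w))
      drop(t(w) %*% C[names(w), names(w), drop = FALSE] %*% w) else 0
    psi[v] <- target[v] - explained
    if (psi[v] <= 0)
      stop(sprintf("nonpositive residual variance for '%s': explained variance %.4f >= target %.4f",
                   v, explained, target[v]), call. = FALSE)
    # extend C with the solved variable
    cross <- if (length(w) && ncol(C))
      drop(C[, names(w), drop = FALSE] %*% w) else rep(0, ncol(C))
    C <- rbind(cbind(C, cross), c(cross, target[v]))
    rownames(C)[nrow(C)] <- colnames(C)[ncol(C)] <- v
  }
  psi
}

#' Fill automatic ("auto") residual variances in place
#'
#' Applies \code{\link{solve_residual_variances}} to every group whose
#' \code{PS} population diagonal contains \code{NA}, using the supplied
#' covariate moments (one \code{mm_moments}, or one per group).
#'
#' @param model an \code{mm_model}.
#' @param moments an \code{mm_moments}, or a list of them (one per group).
#' @param target target total variances (default 1).
#' @return the model with all residual variances set.
#' @export
standardize_model <- function(model, moments, target = 1) {
  for (g in seq_along(model$groups)) {
    ps <- model$groups[[g]]$PS
    if (anyNA(diag(ps$pop))) {
      mo <- if (inherits(moments, "mm_moments")) moments else moments[[g]]
      psi <- solve_residual_variances(model, mo, target, group = g)
      d <- diag(ps$pop)
      d[is.na(d)] <- psi[is.na(d)]
      diag(model$groups[[g]]$PS$pop) <- d
    }
  }
  model
}

#' Scale one group's residual variances (heteroskedasticity)
#'
#' Multiplies the named group's residual-variance population values by a
#' constant, leaving other groups untouched -- e.g. making a treatment
#' group's variances 50\% larger with \code{factor = 1.5}.
#'
#' @param model an \code{mm_model}.
#' @param group group index or name.
#' @param factor positive scale factor.
#' @return the modified model.
#' @export
scale_group_variances <- function(model, group, factor) {
  if (factor <= 0) stop("'factor' must be positive", call. = FALSE)
  if (is.character(group) && !group %in% names(model$groups))
    stop("unknown group: ", group, call. = FALSE)
  diag(model$groups[[group]]$PS$pop) <- diag(model$groups[[group]]$PS$pop) * factor
  model
}

#' Intercept offsets encoding between-group effects
#'
#' In a multigroup formulation of a treatment effect, the effect of group
#' membership on an endogenous variable is the difference between group
#' intercepts.  Centering at zero, each effect is split as -effect/2 in the
#' control group and +effect/2 in the treatment group, so the grand mean is
#' zero and the intercept difference equals the effect exactly.
#'
#' @param effects named vector mapping endogenous variables to between-group
#'   effects (e.g. \code{c(M = 0.5, Y = 0.2)}).
#' @param endogenous endogenous variable names (order of the AL vector).
#' @return list with numeric vectors \code{control} and \code{treatment}.
#' @export
intercept_offsets <- function(effects, endogenous = names(effects)) {
  bad <- setdiff(names(effects), endogenous)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  half <- stats::setNames(rep(0, length(endogenous)), endogenous)
  half[names(effects)] <- effects / 2
  list(control = -half, treatment = +half)
}

# ---- free-parameter bookkeeping ------------------------------------------

# one row per free cell: label, group, role, i, j
free_cells <- function(model) {
  out <- list()
  for (g in seq_along(model$groups)) {
    for (role in c("KA", "BE", "PS", "AL")) {
      mat <- model$groups[[g]][[role]]
      if (is.null(mat)) next
      idx <- which(!is.na(mat$labels), arr.ind = TRUE)
      if (nrow(idx))
        out[[length(out) + 1L]] <- data.frame(
          label = mat$labels[idx], group = g, role = role,
          i = idx[, 1], j = idx[, 2], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(label = character(0), group = integer(0),
                                      role = character(0), i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

#' Distinct free parameters of a model
#'
#' @param model an \code{mm_model}.
#' @return character vector of distinct free-parameter labels (a label bound
#'   to several cells or groups counts once: it is one constrained parameter).
#' @export
free_labels <- function(model) unique(free_cells(model)$label)

# population value per distinct label; NA when the cells bound by a label
# carry conflicting population values (e.g. a homoskedasticity constraint
# fitted to a heteroskedastic population)
label_population <- function(model) {
  fc <- free_cells(model)
  vals <- vapply(seq_len(nrow(fc)), function(r) {
    model$groups[[fc$group[r]]][[fc$role[r]]]$pop[fc$i[r], fc$j[r]]
  }, 0)
  out <- tapply(vals, fc$label, function(v)
    if (length(unique(round(v, 12))) == 1L) v[1] else NA_real_)
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.mm_model <- function(x, ...) {
  cat(sprintf("Path model: %d group(s); endogenous [%s]; covariates [%s]; meanstructure %s\n",
              n_groups(x), paste(x$endogenous, collapse = ", "),
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none",
              if (x$meanstructure) "on" else "off"))
  fl <- free_labels(x)
  cat(sprintf("  %d distinct free parameters: %s\n", length(fl),
              paste(fl, collapse = ", ")))
  if (!is.null(x$defined))
    cat("  defined:", paste(names(x$defined), collapse = ", "), "\n")
  invisible(x)
}
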