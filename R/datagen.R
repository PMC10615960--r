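# RNG substreams ------------------------------------------------------------
#
# One master seed spawns independent L'Ecuyer-CMRG substreams, one per
# replication (and a parallel set for Monte Carlo CIs), so results are
# reproducible for any worker count and data noise is decoupled from
# interval noise.

mm_streams <- function(seed, n) {
  old <- RNGkind()
  on.exit(RNGkind(old[1], old[2], old[3]), add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed %% .Machine$integer.max)
  s <- .Random.seed
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

with_stream <- function(stream, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream, envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(code)
}

# one group's endogenous draws given its fixed covariate rows
draw_group <- function(model, group, x, n) {
  m <- pop_matrices(model, group)
  endo <- model$endogenous
  order <- validate_recursive(model$groups[[group]]$BE, endo)
  psi <- diag(m$PS)
  if (anyNA(psi)) stop("PS population diagonal not set", call. = FALSE)
  if (any(psi < 0)) stop("PS must be positive semidefinite", call. = FALSE)
  # diagonal PS in this release: independent normal residuals
  zeta <- matrix(stats::rnorm(n * length(endo)), n) %*% diag(sqrt(psi), length(endo))
  colnames(zeta) <- endo
  y <- matrix(0, n, length(endo), dimnames = list(NULL, endo))
  xb <- if (ncol(m$K)) as.matrix(x[, colnames(m$K), drop = FALSE]) %*% t(m$K)
        else matrix(0, n, length(endo))
  for (v in order) {
    i <- match(v, endo)
    y[, v] <- m$AL[i] + xb[, i] + y %*% m$B[i, ] + zeta[, v]
  }
  y
}

#' Generate one sample conditional on the fixed design
#'
#' Draws the endogenous variables from the population model, row by row of
#' the fixed design matrix: residuals are normal with the group's residual
#' covariance, and endogenous values follow the recursive structural
#' equations.  Covariate columns are copied verbatim -- they are never
#' resampled, reflecting an experimental design fixed by the researcher.
#' For multigroup models the design's group column selects each row's
#' parameter matrices, and the group column (sequential integers 1..G) is
#' kept as the last column.
#'
#' @param model an \code{mm_model} with population values fully specified.
#' @param design an \code{mm_design} (with a group column iff the model is
#'   multigroup).
#' @param seed optional integer seed (a plain \code{set.seed}); for
#'   replication-stream control use \code{stream}.
#' @param stream optional L'Ecuyer-CMRG stream state (internal engine use).
#' @return a data frame of class \code{mm_data}: covariates, endogenous
#'   columns, optional group column last.
#' @examples
#' des <- factorial_design("X", 50)
#' mod <- preset_simple_mediation()$population
#' head(generate_sample(mod, des, seed = 777))
#' @export
generate_sample <- function(model, design, seed = NULL, stream = NULL) {
  gen <- function() {
    gcol <- group_of(design)
    G <- n_groups(model)
    if (G > 1L && is.null(gcol))
      stop("multigroup model needs a design with a group column", call. = FALSE)
    covs <- intersect(covariate_names(design), model$covariates)
    x <- as.data.frame(design)
    if (is.null(gcol)) {
      y <- draw_group(model, 1L, x, nrow(x))
      out <- cbind(x[covariate_names(design)], as.data.frame(y))
    } else {
      g <- x[[gcol]]
      if (!setequal(unique(g), seq_len(G)))
        stop("group codes must be sequential integers 1..G matching the model",
             call. = FALSE)
      y <- matrix(NA_real_, nrow(x), length(model$endogenous),
                  dimnames = list(NULL, model$endogenous))
      for (gr in seq_len(G)) {
        rows <- which(g == gr)
        y[rows, ] <- draw_group(model, gr, x[rows, , drop = FALSE], length(rows))
      }
      out <- cbind(x[setdiff(covariate_names(design), gcol)],
                   as.data.frame(y))
      out[[gcol]] <- g     # group column last
    }
    structure(out, class = c("mm_data", "data.frame"),
              group = gcol, seed = seed)
  }
  if (!is.null(stream)) with_stream(stream, gen())
  else if (!is.null(seed)) { set.seed(seed); gen() }
  else gen()
}

#' Generate a multigroup sample from per-group sizes
#'
#' Convenience wrapper building a design of \code{sizes[g]} rows per group
#' (no within-group covariates beyond those supplied) and generating from
#' the multigroup model.  The group column is appended as the last column
#' with codes 1..G.
#'
#' @param model a multigroup \code{mm_model}.
#' @param sizes integer vector (or list) of per-group sample sizes.
#' @param designs optional list of per-group covariate designs (data frames
#'   with the model's covariate columns); overrides \code{sizes}.
#' @param seed,stream as in \code{\link{generate_sample}}.
#' @export
generate_multigroup_sample <- function(model, sizes = NULL, designs = NULL,
                                       seed = NULL, stream = NULL) {
  G <- n_groups(model)
  gcol <- model$group_column %||% "group"
  if (is.null(designs)) {
    sizes <- unlist(sizes)
    if (length(sizes) != G) stop("need one size per group", call. = FALSE)
    if (any(sizes < 1)) stop("every group must be nonempty", call. = FALSE)
    designs <- lapply(sizes, function(n)
      as.data.frame(matrix(numeric(0), n, 0)))
  }
  if (length(designs) != G) stop("need one design per group", call. = FALSE)
  if (any(vapply(designs, nrow, 0L) == 0L))
    stop("every group must be nonempty", call. = FALSE)
  x <- do.call(rbind, lapply(designs, as.data.frame))
  x[[gcol]] <- rep(seq_len(G), vapply(designs, nrow, 0L))
  rownames(x) <- NULL
  d <- structure(x, class = c("mm_design", "data.frame"), group = gcol)
  generate_sample(model, d, seed = seed, stream = stream)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate datasets from a path model
#'
#' \code{\link[stats]{simulate}} method: draws \code{nsim} independent
#' samples conditional on the fixed design.
#'
#' @param object an \code{mm_model}.
#' @param nsim number of datasets.
#' @param seed master seed (substreams give the per-dataset independence).
#' @param design the fixed \code{mm_design}.
#' @param ... unused.
#' @return list of \code{mm_data} frames.
#' @export
simulate.mm_model <- function(object, nsim = 1, seed = NULL, design, ...) {
  streams <- mm_streams(seed %||% 1L, nsim)
  lapply(streams, function(s) generate_sample(object, design, stream = s))
}
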