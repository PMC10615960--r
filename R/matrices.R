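#' Create a parameter matrix (free/fixed pattern paired with population values)
#'
#' A path model is specified by four matrices per group, in the LISREL-style
#' notation for models with fixed exogenous covariates:
#' \describe{
#'   \item{KA}{covariate -> endogenous slopes (kappa); one row per endogenous
#'     variable, one column per covariate.}
#'   \item{BE}{endogenous -> endogenous slopes (beta); square with a
#'     structurally zero diagonal.}
#'   \item{PS}{residual (co)variances (psi); symmetric, and in this release
#'     diagonal (off-diagonal entries must be fixed at zero).}
#'   \item{AL}{intercepts (alpha); a column vector over endogenous variables.}
#' }
#' Each cell carries two pieces of information, mirroring the free/population
#' dual-matrix idiom of simulation-based SEM software: whether the analysis
#' model estimates it freely (a character label) or fixes it (\code{NA}, or a
#' numeric string), and the numeric value used to generate population data.
#' A label repeated across cells -- or across groups -- denotes a single,
#' equality-constrained parameter.
#'
#' @param role one of \code{"KA"}, \code{"BE"}, \code{"PS"}, \code{"AL"}.
#' @param free character matrix (or vector for \code{AL}): \code{NA} marks a
#'   cell fixed at its population value; a string that parses as a number
#'   marks a cell fixed at that number (it must then equal the population
#'   value -- disagreement is a specification error, not a silent override);
#'   any other string is a free-parameter label.
#' @param pop numeric matrix (or vector) of population values, same shape as
#'   \code{free}.  Diagonal \code{PS} entries may be \code{NA} to request
#'   automatic standardization (see \code{\link{solve_residual_variances}}).
#' @return an object of class \code{mm_matrix}.
#' @examples
#' mm_matrix("KA", free = rbind(M = "a", Y = "c"),
#'           pop = rbind(M = 0.5, Y = 0.2))
#' @export
mm_matrix <- function(role = c("KA", "BE", "PS", "AL"), free, pop) {
  role <- match.arg(role)
  free <- as.matrix(free); pop <- as.matrix(pop)
  if (!all(dim(free) == dim(pop)))
    stop("'free' and 'pop' must have identical dimensions", call. = FALSE)
  storage.mode(pop) <- "double"
  labels <- matrix(NA_character_, nrow(free), ncol(free), dimnames = dimnames(free))
  for (i in seq_len(nrow(free))) for (j in seq_len(ncol(free))) {
    cell <- free[i, j]
    if (is.na(cell)) next
    num <- suppressWarnings(as.numeric(cell))
    if (!is.na(num)) {
      if (!is.na(pop[i, j]) && num != pop[i, j])
        stop(sprintf("cell (%d,%d) of %s fixed at %s but population value is %s",
                     i, j, role, cell, format(pop[i, j])), call. = FALSE)
      pop[i, j] <- num
    } else {
      labels[i, j] <- cell
    }
  }
  if (is.null(dimnames(pop)) && !is.null(dimnames(free))) dimnames(pop) <- dimnames(free)
  x <- structure(list(role = role, labels = labels, pop = pop),
                 class = "mm_matrix")
  validate_mm_matrix(x)
  x
}

validate_mm_matrix <- function(x) {
  role <- x$role; pop <- x$pop; lab <- x$labels
  if (role == "BE") {
    if (nrow(pop) != ncol(pop)) stop("BE must be square", call. = FALSE)
    if (any(!is.na(diag(lab))) || any(diag(pop) != 0, na.rm = TRUE))
      stop("BE must have a structurally zero diagonal", call. = FALSE)
  }
  if (role == "PS") {
    if (nrow(pop) != ncol(pop)) stop("PS must be square", call. = FALSE)
    off <- row(pop) != col(pop)
    if (any(!is.na(lab[off])) || any(pop[off] != 0, na.rm = TRUE))
      stop("off-diagonal PS entries must be fixed at zero in this release",
           call. = FALSE)
    if (any(diag(pop) < 0, na.rm = TRUE))
      stop("PS diagonal population values must be nonnegative", call. = FALSE)
  }
  if (role == "AL" && ncol(pop) != 1L)
    stop("AL must be a column vector", call. = FALSE)
  invisible(x)
}

#' Diagonal residual matrix shorthand
#'
#' Convenience wrapper building a diagonal \code{PS} matrix from per-variable
#' free labels (or NA) and population variances (NA = solve automatically).
#'
#' @param free character vector of labels, one per endogenous variable.
#' @param pop numeric vector of population residual variances (NA = auto).
#' @param names endogenous variable names.
#' @export
mm_psi <- function(free, pop, names = NULL) {
  k <- max(length(free), length(pop))
  if (is.null(names)) names <- paste0("V", seq_len(k))
  fm <- matrix(NA_character_, k, k, dimnames = list(names, names))
  pm <- matrix(0, k, k, dimnames = list(names, names))
  diag(fm) <- free
  diag(pm) <- pop
  mm_matrix("PS", fm, pm)
}

#' @export
print.mm_matrix <- function(x, ...) {
  cat(sprintf("%s parameter matrix (%d x %d)\n", x$role, nrow(x$pop), ncol(x$pop)))
  shown <- matrix(sprintf("%s%s",
                          ifelse(is.na(x$labels), "", paste0(x$labels, "=")),
                          ifelse(is.na(x$pop), "auto", format(x$pop))),
                  nrow(x$pop), dimnames = dimnames(x$pop))
  print(shown, quote = FALSE)
  invisible(x)
}
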