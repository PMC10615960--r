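#' Build a fully-crossed factorial design matrix of dummy codes
#'
#' Constructs the fixed covariate matrix of an experiment with two-level
#' (0/1 dummy-coded) factors.  Cells are fully crossed and laid out
#' contiguously, with factors varying slowest-to-fastest in declaration
#' order; there is no randomness.  The result is the fixed exogenous data
#' that every simulated replication conditions on.
#'
#' @param factors character vector of factor names (each a two-level,
#'   dummy-coded factor).
#' @param n_per_cell number of observations per design cell; either a single
#'   positive integer (balanced design) or one integer per cell in cell
#'   order, allowing unbalanced designs.
#' @param group optional name of a factor to treat as a grouping variable
#'   for multigroup models.  The group column is recoded to sequential
#'   integers 1..G and moved to the last column.
#' @return an object of class \code{mm_design}: a data frame of 0/1 dummy
#'   columns (plus any interaction columns added later), with attributes
#'   \code{group} (group column name or \code{NULL}) and \code{cells}.
#' @examples
#' factorial_design("X", 50)              # 100 rows, 50 per arm
#' factorial_design(c("X", "W"), 25)      # 2 x 2, N = 100
#' @export
factorial_design <- function(factors, n_per_cell, group = NULL) {
  if (length(factors) < 1L || anyDuplicated(factors))
    stop("'factors' must be a non-empty set of distinct names", call. = FALSE)
  n_cells <- 2L^length(factors)
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, n_cells)
  if (length(n_per_cell) != n_cells || any(n_per_cell < 1) ||
      any(n_per_cell != round(n_per_cell)))
    stop("invalid design: 'n_per_cell' must be positive integers, one per cell",
         call. = FALSE)
  # slowest-to-fastest: first declared factor changes slowest
  cells <- expand.grid(rev(lapply(factors, function(f) 0:1)))[, length(factors):1, drop = FALSE]
  names(cells) <- factors
  rows <- cells[rep(seq_len(n_cells), times = n_per_cell), , drop = FALSE]
  rownames(rows) <- NULL
  d <- structure(rows, class = c("mm_design", "data.frame"),
                 group = NULL, cells = cbind(cells, n = n_per_cell))
  if (!is.null(group)) d <- set_group(d, group)
  d
}

#' Append an interaction (product) column to a design
#'
#' The interaction between two dummy codes is simply their elementwise
#' product; the new column is named \code{<a>:<b>}.
#'
#' @param design an \code{mm_design}.
#' @param a,b names of the parent columns.
#' @param name optional name for the product column.
#' @return the design with the product column appended.
#' @export
add_interaction <- function(design, a, b, name = paste0(a, ":", b)) {
  for (p in c(a, b))
    if (!p %in% names(design))
      stop("missing column: ", p, call. = FALSE)
  design[[name]] <- design[[a]] * design[[b]]
  design
}

#' Mark a design column as the grouping variable
#'
#' Recodes the column to sequential integers 1..G (sorted by original code)
#' and moves it to the last position, the layout multigroup generation and
#' fitting expect.
#'
#' @param design an \code{mm_design}.
#' @param column name of the grouping column.
#' @return the design with attribute \code{group} set.
#' @export
set_group <- function(design, column) {
  if (!column %in% names(design)) stop("missing column: ", column, call. = FALSE)
  codes <- sort(unique(design[[column]]))
  if (any(tabulate(match(design[[column]], codes)) == 0L))
    stop("every group must be nonempty", call. = FALSE)
  g <- match(design[[column]], codes)
  design[[column]] <- NULL
  design[[column]] <- g
  attr(design, "group") <- column
  design
}

group_of <- function(design) attr(design, "group")

covariate_names <- function(design) setdiff(names(design), group_of(design))

#' Means and covariance of the design covariates
#'
#' Computes the first two moments of the covariate columns (the grouping
#' column, if any, is excluded).  The covariance divisor matters: the
#' standardization solver uses the unbiased \eqn{n-1} convention, which is
#' what makes "total variance = 1" reproducible across software that
#' computes sample covariances the usual way.
#'
#' @param design an \code{mm_design} (or plain data frame of covariates).
#' @param divisor \code{"unbiased"} (\eqn{n-1}, default) or
#'   \code{"population"} (\eqn{n}).
#' @return a list of class \code{mm_moments} with elements \code{means},
#'   \code{covariance}, \code{n}, \code{divisor}.
#' @export
covariate_moments <- function(design, divisor = c("unbiased", "population")) {
  divisor <- match.arg(divisor)
  x <- as.matrix(as.data.frame(design)[, covariate_names(design), drop = FALSE])
  n <- nrow(x)
  if (n < 2L && divisor == "unbiased")
    stop("degenerate moments: need at least 2 rows for the unbiased divisor",
         call. = FALSE)
  v <- stats::cov(x)
  if (divisor == "population") v <- v * (n - 1) / n
  structure(list(means = colMeans(x), covariance = v, n = n, divisor = divisor),
            class = "mm_moments")
}

#' @export
print.mm_design <- function(x, ...) {
  g <- group_of(x)
  cat(sprintf("Fixed design: %d observations, covariates [%s]%s\n",
              nrow(x), paste(covariate_names(x), collapse = ", "),
              if (is.null(g)) "" else paste0(", group column '", g, "'")))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}
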