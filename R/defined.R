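#' User-defined parameters (functions of path coefficients)
#'
#' Indirect effects, total effects, conditional indirect effects and the
#' index of moderated mediation are all products/sums of path coefficients.
#' They are declared as \code{"name := expression"} strings, with a grammar
#' restricted to \code{+}, \code{-}, \code{*}, parentheses, numeric literals
#' and parameter labels (or previously defined names).  The restriction keeps
#' delta-method gradients smooth and well-behaved.
#'
#' @param x character vector of definitions, e.g.
#'   \code{c("ab := a*b", "total := c + a*b")}.
#' @return a list of class \code{mm_defined}; each element has \code{name}
#'   and \code{expr} (a parsed R expression).
#' @examples
#' defined_params(c("ind.w0 := a.w0*b", "ind.w1 := (a.w0 + a.mod)*b",
#'                  "index := a.mod*b"))
#' @export
defined_params <- function(x) {
  if (inherits(x, "mm_defined")) return(x)
  out <- lapply(x, function(s) {
    parts <- strsplit(s, ":=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("definition must have the form 'name := expression': ", s, call. = FALSE)
    name <- trimws(parts[1])
    expr <- tryCatch(str2lang(trimws(parts[2])),
                     error = function(e) stop("unparsable expression in: ", s, call. = FALSE))
    check_defined_expr(expr, s)
    list(name = name, expr = expr)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out)))
    stop("duplicate defined-parameter name", call. = FALSE)
  structure(out, class = "mm_defined")
}

#' @export
`[.mm_defined` <- function(x, i) structure(NextMethod(), class = "mm_defined")

check_defined_expr <- function(e, src) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% c("+", "-", "*", "("))
      stop("operator '", op, "' not allowed in defined parameter: ", src,
           call. = FALSE)
    for (a in as.list(e)[-1]) check_defined_expr(a, src)
    return(invisible(TRUE))
  }
  stop("invalid token in defined parameter: ", src, call. = FALSE)
}

# labels referenced by an expression (excluding earlier defined names)
expr_labels <- function(e) all.vars(e)

#' Evaluate defined parameters at a set of label values
#'
#' Definitions may chain (later expressions may use earlier defined names).
#' Values may be scalars or equal-length vectors (the vectorized form is what
#' the Monte Carlo confidence interval uses, evaluating every definition at
#' each sampled parameter vector at once).
#'
#' @param defined an \code{mm_defined} (or character vector of definitions).
#' @param values named numeric list/vector of label values.
#' @return named list of evaluated values (same length as each input value).
#' @export
evaluate_defined <- function(defined, values) {
  defined <- defined_params(defined)
  env <- list2env(as.list(values), parent = baseenv())
  out <- vector("list", length(defined))
  names(out) <- names(defined)
  for (d in defined) {
    missing <- setdiff(expr_labels(d$expr), ls(env))
    if (length(missing))
      stop("unresolved label(s) in '", d$name, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    v <- eval(d$expr, env)
    assign(d$name, v, envir = env)
    out[[d$name]] <- v
  }
  out
}

# all base labels (non-defined names) a set of definitions depends on,
# resolved through chaining
defined_base_labels <- function(defined) {
  defined <- defined_params(defined)
  base <- character(0)
  seen <- character(0)
  for (d in defined) {
    vars <- expr_labels(d$expr)
    base <- union(base, setdiff(vars, seen))
    seen <- c(seen, d$name)
  }
  base
}

# gradient of one defined parameter w.r.t. the labels in `at` (central
# finite differences, step 1e-6 * max(1, |theta|))
defined_gradient <- function(defined, name, at) {
  defined <- defined_params(defined)
  at <- unlist(at)
  g <- numeric(length(at))
  names(g) <- names(at)
  for (k in seq_along(at)) {
    h <- 1e-6 * max(1, abs(at[k]))
    up <- at; up[k] <- up[k] + h
    dn <- at; dn[k] <- dn[k] - h
    g[k] <- (evaluate_defined(defined, up)[[name]] -
             evaluate_defined(defined, dn)[[name]]) / (2 * h)
  }
  g
}
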