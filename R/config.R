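# Declarative study configurations (YAML, JSON accepted).
#
# A config has four sections: design, model, monte_carlo, output.  Matrices
# are nested maps whose cells hold either a number (fixed) or a label string
# (free); labels get their population values from the model's `population`
# map ("auto" on a residual variance requests the standardization solver).
# A `preset:` key selects one of the built-in study builders instead.

config_schema <- list(
  top = c("design", "model", "monte_carlo", "output"),
  design = c("factors", "n_per_cell", "interactions", "group"),
  model = c("preset", "args", "endogenous", "covariates", "meanstructure",
            "groups", "population", "defined", "analysis"),
  group_mats = c("kappa", "beta", "psi", "alpha"),
  monte_carlo = c("nRep", "seed", "alpha", "methods", "mcci_draws"),
  output = c("dir", "formats", "verbosity"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) under '", where, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Load a study configuration file
#'
#' Reads and validates a YAML (or JSON) study configuration and returns a
#' ready-to-run \code{\link{power_study}}.  Residual variances declared
#' \code{"auto"} are solved here, so an infeasible standardization
#' (explained variance at or above the target) fails fast with the
#' offending variable named.
#'
#' @param path path to the config file.
#' @return an \code{mm_study}.
#' @examples
#' cfg <- system.file("extdata", "simple_mediation.yaml", package = "modmedpower")
#' load_config(cfg)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # only the words true/false are booleans; bare Y/N/y/n stay variable names
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no"  = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x))
  check_keys(cfg, config_schema$top, "top level")
  mc <- cfg$monte_carlo %||% list()
  check_keys(mc, config_schema$monte_carlo, "monte_carlo")
  alpha <- mc$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("monte_carlo.alpha must be in (0, 1)", call. = FALSE)
  mcargs <- list(nRep = as.integer(mc$nRep %||% 1000L),
                 seed = as.integer(mc$seed %||% 12345L),
                 alpha = alpha,
                 methods = unlist(mc$methods) %||% c("delta", "mcci"),
                 mcci_draws = as.integer(mc$mcci_draws %||% 20000L))

  model <- cfg$model %||% stop("config needs a 'model' section", call. = FALSE)
  check_keys(model, config_schema$model, "model")
  if (!is.null(model$preset)) {
    fn <- switch(model$preset,
                 simple_mediation = preset_simple_mediation,
                 simple_mediation_multigroup = preset_simple_mediation_multigroup,
                 modmed = preset_modmed,
                 modmed_multigroup = preset_modmed_multigroup,
                 stop("unknown preset: ", model$preset, call. = FALSE))
    return(do.call(fn, c(model$args %||% list(), mcargs)))
  }

  des <- cfg$design %||% stop("config needs a 'design' section", call. = FALSE)
  check_keys(des, config_schema$design, "design")
  build <- function(n_per_cell) {
    design <- factorial_design(unlist(des$factors), n_per_cell)
    for (ia in des$interactions %||% list())
      design <- add_interaction(design, ia[[1]], ia[[2]])
    if (!is.null(des$group)) design <- set_group(design, des$group)
    mod <- parse_model_section(model, design)
    list(population = mod, analysis = mod, design = design)
  }
  parts <- build(des$n_per_cell %||% stop("design.n_per_cell required", call. = FALSE))
  do.call(power_study, c(list(population = parts$population,
                              analysis = parts$analysis,
                              design = parts$design, builder = build), mcargs))
}

parse_model_section <- function(model, design) {
  endo <- unlist(model$endogenous) %||% stop("model.endogenous required", call. = FALSE)
  pop_map <- model$population %||% list()
  covs <- unlist(model$covariates) %||% covariate_names(design)
  cell_value <- function(v, auto_ok = FALSE) {
    # returns list(free_label or NA, population value)
    if (is.numeric(v)) return(list(NA_character_, v))
    if (identical(v, "auto")) {
      if (!auto_ok) stop("'auto' only allowed on psi diagonals", call. = FALSE)
      return(list(NA_character_, NA_real_))
    }
    pv <- pop_map[[v]]
    if (is.null(pv)) stop("no population value for label '", v, "'", call. = FALSE)
    if (identical(pv, "auto")) {
      if (!auto_ok) stop("'auto' only allowed on psi diagonals", call. = FALSE)
      pv <- NA_real_
    }
    list(v, as.numeric(pv))
  }
  mat_from_map <- function(map, rows, cols, role, auto_ok = FALSE) {
    fm <- matrix(NA_character_, length(rows), length(cols),
                 dimnames = list(rows, cols))
    pm <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    if (role == "PS" && auto_ok) diag(pm) <- 0
    for (r in names(map)) {
      if (!r %in% rows) stop("unknown row '", r, "' in ", role, call. = FALSE)
      row <- map[[r]]
      if (role == "AL") row <- stats::setNames(list(row), "value")
      else if (role == "PS" && !is.list(row)) row <- stats::setNames(list(row), r)
      for (cc in names(row)) {
        if (!cc %in% cols) stop("unknown column '", cc, "' in ", role, call. = FALSE)
        cv <- cell_value(row[[cc]], auto_ok = role == "PS" && cc == r)
        fm[r, cc] <- cv[[1]]
        pm[r, cc] <- cv[[2]]
      }
    }
    mm_matrix(role, fm, pm)
  }
  groups <- model$groups %||% stop("model.groups required", call. = FALSE)
  glist <- lapply(groups, function(g) {
    check_keys(g, config_schema$group_mats, "model.groups.<name>")
    list(KA = if (!is.null(g$kappa)) mat_from_map(g$kappa, endo, covs, "KA"),
         BE = mat_from_map(g$beta %||% list(), endo, endo, "BE"),
         PS = {
           ps <- mat_from_map(g$psi %||% stop("each group needs psi", call. = FALSE),
                              endo, endo, "PS", auto_ok = TRUE)
           # unlisted diagonal cells default to auto, not fixed zero
           d <- diag(ps$pop)
           listed <- names(g$psi)
           d[!endo %in% listed & is.na(diag(ps$labels))] <- NA
           diag(ps$pop) <- d
           ps
         },
         AL = if (!is.null(g$alpha)) mat_from_map(g$alpha, endo, "value", "AL"))
  })
  mod <- path_model(groups = glist, endogenous = endo, covariates = covs,
                    defined = if (!is.null(model$defined))
                      defined_params(unlist(model$defined)),
                    meanstructure = isTRUE(model$meanstructure),
                    group_column = group_of(design))
  standardize_model(mod, covariate_moments(design))
}
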