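#' Read / write coefficient catalogs as JSON
#'
#' Catalogs are plain JSON so externally supplied (e.g. published
#' appendix) coefficient sets can be dropped in verbatim: risk-equation
#' catalogs map outcome -> family / coefficients / shape / spline;
#' biomarker catalogs map biomarker -> model type / coefficients /
#' residual sd / bounds; utility and cost catalogs mirror their
#' constructors.
#'
#' @param catalog The catalog object.
#' @param path JSON file path.
#' @return Readers return the rebuilt catalog; writers return `path`
#'   invisibly.
#' @name catalog_io
NULL

#' @rdname catalog_io
#' @export
write_equation_catalog <- function(catalog, path) {
  x <- lapply(catalog, function(eq) {
    list(outcome = eq$outcome, family = eq$family,
         coefficients = as.list(eq$coefficients),
         shape = eq$shape, gamma = eq$gamma, knots = eq$knots)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname catalog_io
#' @export
read_equation_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  out <- lapply(x, function(e) {
    risk_equation(e$outcome, e$family,
                  unlist(e$coefficients) %||% setNames(numeric(0),
                                                       character(0)),
                  shape = if (!is.null(e$shape)) as.numeric(e$shape),
                  gamma = if (!is.null(e$gamma)) as.numeric(unlist(e$gamma)),
                  knots = if (!is.null(e$knots)) as.numeric(unlist(e$knots)))
  })
  names(out) <- vapply(out, function(e) e$outcome, character(1))
  out
}

#' @rdname catalog_io
#' @export
write_biomarker_catalog <- function(catalog, path) {
  x <- lapply(catalog, function(eq) {
    list(biomarker = eq$biomarker, model_type = eq$model_type,
         coefficients = as.list(eq$coefficients),
         residual_sd = eq$residual_sd, bounds = eq$bounds)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname catalog_io
#' @export
read_biomarker_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  out <- lapply(x, function(e)
    biomarker_equation(e$biomarker, e$model_type,
                       unlist(e$coefficients),
                       residual_sd = as.numeric(e$residual_sd),
                       bounds = as.numeric(unlist(e$bounds))))
  names(out) <- vapply(out, function(e) e$biomarker, character(1))
  out
}

#' @rdname catalog_io
#' @export
write_utility_catalog <- function(catalog, path) {
  jsonlite::write_json(unclass(catalog), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname catalog_io
#' @export
read_utility_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  utility_catalog(baseline_utility = as.numeric(x$baseline_utility),
                  decrements = lapply(x$decrements,
                                      function(d) as.numeric(unlist(d))),
                  excess_weight_decrement =
                    as.numeric(x$excess_weight_decrement),
                  bmi_threshold = as.numeric(x$bmi_threshold),
                  bound = "central")  # stored values are already final
}

#' @rdname catalog_io
#' @export
write_cost_catalog <- function(catalog, path) {
  jsonlite::write_json(unclass(catalog), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname catalog_io
#' @export
read_cost_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  cost_catalog(complication_costs = lapply(x$complication_costs,
                                           function(d)
                                             as.numeric(unlist(d))),
               management_cost = as.numeric(x$management_cost),
               inflation_factor = as.numeric(x$inflation_factor),
               discount_rate = as.numeric(x$discount_rate))
}
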