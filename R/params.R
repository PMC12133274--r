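#' Parameter references and registries
#'
#' Model fields that may be differentiated against (turnover numbers,
#' enzyme-pool capacities, fixed-flux values, simple bounds) can hold either
#' a plain scalar or a *parameter reference*: a named handle that is resolved
#' against a parameter registry at LP-build time.  Only referenced parameters
#' appear in the parametric structure of the LP and can be differentiated.
#'
#' @param name Parameter name (single character string).
#' @return `param_ref()` returns an object of class `"param_ref"`.
#' @examples
#' p <- param_ref("kcat_pgi")
#' is_param_ref(p)
#' resolve_value(p, c(kcat_pgi = 126))
#' @export
param_ref <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(param = name), class = "param_ref")
}

#' @rdname param_ref
#' @param x Object to test or resolve.
#' @export
is_param_ref <- function(x) inherits(x, "param_ref")

#' @export
print.param_ref <- function(x, ...) {
  cat("<param:", x$param, ">\n")
  invisible(x)
}

#' @rdname param_ref
#' @export
param_name <- function(x) if (is_param_ref(x)) x$param else NA_character_

#' @rdname param_ref
#' @param params Named numeric vector: the parameter registry.
#' @details `resolve_value()` returns `x` unchanged if it is numeric, or the
#'   registry value if it is a parameter reference; an unresolved reference is
#'   an error naming the missing parameter.
#' @export
resolve_value <- function(x, params) {
  if (is.null(x)) return(NULL)
  if (is_param_ref(x)) {
    if (is.null(params) || !(x$param %in% names(params)))
      stop("unresolved parameter reference: '", x$param, "'", call. = FALSE)
    return(unname(params[[x$param]]))
  }
  if (is.numeric(x)) return(unname(x))
  stop("value is neither numeric nor a parameter reference", call. = FALSE)
}

## collect every parameter name referenced anywhere in a model
referenced_params <- function(model) {
  out <- character(0)
  add <- function(x) if (is_param_ref(x)) out[[length(out) + 1L]] <<- x$param
  for (rxn in model$reactions) {
    add(rxn$lower_bound); add(rxn$upper_bound)
    for (iso in rxn$isozymes) { add(iso$kcat_forward); add(iso$kcat_reverse) }
  }
  for (pl in model$pools) add(pl$capacity)
  for (ff in model$fixed_fluxes) add(ff$value)
  unique(out)
}
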