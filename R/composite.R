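#' Monotone composite endpoint definitions
#'
#' A composite definition is a negation-free Boolean expression tree over
#' named binary components, given as a nested list whose single element is
#' named `"and"` or `"or"` and contains component names or further nested
#' expressions. Monotonicity (no negation) is what makes partial evaluation
#' meaningful: once enough components are observed to fix the value, further
#' observation cannot change it.
#'
#' @param expr A nested list, e.g. `list(or = list("z1", "z2", "z3"))` or
#'   `list(and = list("z1", list(or = list("z2", "z3"))))`. Operand vectors
#'   of component names are also accepted.
#' @return An object of class `composite_definition`.
#' @seealso [composite_simple()], [composite_complex()]
#' @export
composite_definition <- function(expr) {
  validate_expr <- function(e) {
    if (is.character(e)) {
      if (length(e) != 1L || !nzchar(e)) {
        stop("component references must be single non-empty names",
             call. = FALSE)
      }
      return(invisible(NULL))
    }
    if (!is.list(e) || length(e) != 1L || is.null(names(e))) {
      stop("each expression node must be a single named list element",
           call. = FALSE)
    }
    op <- names(e)
    if (!op %in% c("and", "or")) {
      stop("unsupported operator '", op,
           "': only monotone 'and'/'or' composites are supported",
           call. = FALSE)
    }
    operands <- e[[1L]]
    if (is.character(operands)) operands <- as.list(operands)
    if (!is.list(operands) || length(operands) < 1L) {
      stop("operator '", op, "' needs at least one operand", call. = FALSE)
    }
    for (o in operands) validate_expr(o)
  }
  validate_expr(expr)
  structure(list(expr = expr), class = "composite_definition")
}

#' @rdname composite_definition
#' @param components Character vector of component column names.
#' @export
composite_simple <- function(components = c("z1", "z2", "z3")) {
  composite_definition(list(or = as.list(components)))
}

#' @rdname composite_definition
#' @export
composite_complex <- function() {
  composite_definition(list(and = list("z1", list(or = list("z2", "z3")))))
}

#' Component names referenced by a composite definition
#'
#' @param def A [composite_definition()].
#' @return Character vector of unique component names.
#' @export
composite_components <- function(def) {
  stopifnot(inherits(def, "composite_definition"))
  collect <- function(e) {
    if (is.character(e)) return(e)
    operands <- e[[1L]]
    if (is.character(operands)) operands <- as.list(operands)
    unlist(lapply(operands, collect))
  }
  unique(collect(def$expr))
}

#' Three-valued evaluation of a composite definition
#'
#' Evaluates the definition under Kleene logic on tri-state components coded
#' 0 / 1 / `NA`: an OR is 1 as soon as any operand is 1 and 0 only when all
#' operands are 0; an AND is 0 as soon as any operand is 0 and 1 only when
#' all are 1; otherwise the value is unknown (`NA`). With fully observed
#' components this reduces to the ordinary truth table.
#'
#' @param def A [composite_definition()].
#' @param data A data frame (or named list of equal-length vectors) holding
#'   every referenced component, coded 0/1/`NA`.
#' @return An integer vector of 0/1/`NA` values.
#' @export
evaluate_composite <- function(def, data) {
  stopifnot(inherits(def, "composite_definition"))
  comps <- composite_components(def)
  missing_cols <- setdiff(comps, names(data))
  if (length(missing_cols)) {
    stop("composite definition references undeclared component(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in comps) {
    v <- data[[nm]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("component '", nm, "' contains values other than 0/1/NA",
           call. = FALSE)
    }
  }
  eval_node <- function(e) {
    if (is.character(e)) return(as.logical(data[[e]]))
    op <- names(e)
    operands <- e[[1L]]
    if (is.character(operands)) operands <- as.list(operands)
    vals <- lapply(operands, eval_node)
    # base R's `|`/`&` on logicals with NA implement Kleene three-valued logic
    Reduce(if (op == "or") `|` else `&`, vals)
  }
  as.integer(eval_node(def$expr))
}

#' Derive the composite endpoint from observed components
#'
#' Adds `y_deriv` (the three-valued evaluation of the definition) and
#' `r_y_deriv` (1 where the endpoint could be derived, 0 where it remains
#' unknown) to the dataset. Rows with all components missing are retained
#' with an unknown endpoint; excluding them is an analysis decision, not a
#' data-model one.
#'
#' @param data A trial data frame with the referenced component columns.
#' @param def A [composite_definition()].
#' @return `data` with columns `y_deriv` and `r_y_deriv` appended.
#' @export
derive_endpoint <- function(data, def) {
  y <- evaluate_composite(def, data)
  data$y_deriv <- y
  data$r_y_deriv <- as.integer(!is.na(y))
  data
}

#' Complete records with respect to a composite definition
#'
#' Retains exactly the rows in which every component referenced by the
#' definition is observed, and (re)computes `y` from the definition on the
#' retained rows. Note the contrast with [derive_endpoint()]: a row with
#' `z1 = 1` but missing `z2` has a derivable simple composite yet is not a
#' complete record.
#'
#' @inheritParams derive_endpoint
#' @return The complete-record subset of `data`, with `y` set from the
#'   definition.
#' @export
complete_records <- function(data, def) {
  comps <- composite_components(def)
  obs <- Reduce(`&`, lapply(comps, function(nm) !is.na(data[[nm]])))
  out <- data[obs, , drop = FALSE]
  out$y <- evaluate_composite(def, out)
  out
}
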