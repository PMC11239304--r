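#' Define a component of a factorial optimization trial
#'
#' A candidate intervention component operationalized as a two-level factor
#' (On/Off) in a `2^k` factorial optimization randomized controlled trial
#' (ORCT), together with the delivery cost of each level.
#'
#' @param name Single-token component label (e.g. `"A"`). `"Min"` is reserved
#'   for the all-Off condition. Labels are case-sensitive.
#' @param cost_on Delivery cost (money units, `>= 0`) when the component is On.
#' @param cost_off Delivery cost when the component is Off. Defaults to 0,
#'   treating the Off level as costless.
#'
#' @return An object of class `"component_spec"`.
#' @seealso [factorial_design()]
#' @export
component_spec <- function(name, cost_on, cost_off = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (name == "Min") {
    stop("component name 'Min' is reserved for the all-Off condition")
  }
  if (grepl("\\s", name)) stop("component names must not contain whitespace")
  if (!is.numeric(cost_on) || length(cost_on) != 1L || is.na(cost_on) ||
      cost_on < 0) {
    stop("'cost_on' must be a single non-negative number")
  }
  if (!is.numeric(cost_off) || length(cost_off) != 1L || is.na(cost_off)) {
    stop("'cost_off' must be a single number")
  }
  structure(
    list(name = name, cost_on = as.numeric(cost_on),
         cost_off = as.numeric(cost_off)),
    class = "component_spec"
  )
}

#' Define a 2^k factorial design
#'
#' Collects an ordered set of components into a full factorial design whose
#' `2^k` conditions (alternative interventions) are all combinations of the
#' On/Off levels. Conditions are identified by concatenating the labels of the
#' components set to On, with `"Min"` denoting the minimal (all-Off)
#' intervention.
#'
#' @param ... [component_spec()] objects, or a single list of them. Component
#'   order is retained and defines the condition enumeration order.
#'
#' @return An object of class `"factorial_design"` with elements
#'   `components` (data frame of name/cost_on/cost_off) and `k`.
#' @examples
#' design <- factorial_design(
#'   component_spec("A", 100), component_spec("B", 125),
#'   component_spec("C", 200), component_spec("D", 250)
#' )
#' enumerate_conditions(design)
#' intervention_cost("ABD", design)
#' @export
factorial_design <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !inherits(comps[[1L]], "component_spec")) {
    comps <- comps[[1L]]
  }
  if (length(comps) < 1L) stop("a design needs at least one component")
  ok <- vapply(comps, inherits, logical(1L), "component_spec")
  if (!all(ok)) stop("all arguments must be component_spec objects")
  nms <- vapply(comps, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate component names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  components <- data.frame(
    name = nms,
    cost_on = vapply(comps, `[[`, numeric(1L), "cost_on"),
    cost_off = vapply(comps, `[[`, numeric(1L), "cost_off"),
    stringsAsFactors = FALSE
  )
  structure(list(components = components, k = nrow(components)),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("2^%d factorial design (%d conditions)\n", x$k, 2^x$k))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Enumerate the conditions of a factorial design
#'
#' Returns the labels of all `2^k` alternative interventions in binary counting
#' order: the first listed component is the lowest bit, so the sequence starts
#' at `"Min"` (all Off) and ends with all components On.
#'
#' @param design A [factorial_design()].
#' @return Character vector of `2^k` distinct condition labels, `"Min"` first.
#' @export
enumerate_conditions <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  m <- condition_matrix(design)
  rownames(m)
}

#' On/Off indicator matrix for all conditions
#'
#' @param design A [factorial_design()].
#' @return A `2^k` by `k` 0/1 integer matrix; rows are conditions (labelled),
#'   columns are components in design order.
#' @export
condition_matrix <- function(design) {
  stopifnot(inherits(design, "factorial_design"))
  k <- design$k
  nms <- design$components$name
  m <- matrix(0L, nrow = 2^k, ncol = k, dimnames = list(NULL, nms))
  for (j in seq_len(k)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2^(j - 1L)), length.out = 2^k)
  }
  rownames(m) <- apply(m, 1L, function(row) {
    on <- nms[row == 1L]
    if (length(on) == 0L) "Min" else paste(on, collapse = "")
  })
  m
}

#' Parse a condition label into its On-component set
#'
#' The inverse of label construction: `"Min"` maps to the empty set and any
#' permutation of component labels is canonicalized to design order (so
#' `"CBA"` and `"ABC"` denote the same condition).
#'
#' @param text Condition label.
#' @param design A [factorial_design()].
#' @return Character vector of On component names, in design order (possibly
#'   empty), with the canonical label as attribute `"label"`.
#' @export
parse_label <- function(text, design) {
  stopifnot(inherits(design, "factorial_design"),
            is.character(text), length(text) == 1L)
  nms <- design$components$name
  if (text == "Min") {
    return(structure(character(0L), label = "Min"))
  }
  if (!nzchar(text)) stop("empty condition label")
  # tokenize greedily against component names (single characters in the
  # common case, but multi-character labels are allowed)
  rest <- text
  on <- character(0L)
  while (nzchar(rest)) {
    hits <- nms[startsWith(rest, nms)]
    if (length(hits) == 0L) {
      stop(sprintf("cannot parse condition label '%s': no component matches '%s'",
                   text, rest))
    }
    tok <- hits[which.max(nchar(hits))]
    on <- c(on, tok)
    rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
  }
  if (anyDuplicated(on)) {
    stop(sprintf("condition label '%s' repeats a component", text))
  }
  on <- nms[nms %in% on]
  structure(on, label = condition_label(on, design))
}

#' Canonical label for a set of On components
#'
#' @param on_set Character vector of component names set to On.
#' @param design A [factorial_design()].
#' @return The canonical condition label (components in design order; `"Min"`
#'   for the empty set).
#' @export
condition_label <- function(on_set, design) {
  stopifnot(inherits(design, "factorial_design"))
  nms <- design$components$name
  bad <- setdiff(on_set, nms)
  if (length(bad) > 0L) {
    stop("unknown component(s): ", paste(bad, collapse = ", "))
  }
  on <- nms[nms %in% on_set]
  if (length(on) == 0L) "Min" else paste(on, collapse = "")
}

#' Delivery cost of an alternative intervention
#'
#' The cost of a condition is additive in its components: the sum of `cost_on`
#' over components set to On plus `cost_off` over components set to Off.
#'
#' @param code Condition label (or vector of labels).
#' @param design A [factorial_design()].
#' @return Numeric vector of costs, one per label.
#' @export
intervention_cost <- function(code, design) {
  stopifnot(inherits(design, "factorial_design"))
  vapply(code, function(lbl) {
    on <- parse_label(lbl, design)
    comp <- design$components
    is_on <- comp$name %in% on
    sum(comp$cost_on[is_on]) + sum(comp$cost_off[!is_on])
  }, numeric(1L), USE.NAMES = FALSE)
}
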