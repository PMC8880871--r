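#' @title Standard typing and logic operations
#' @description
#' The simplest operations manipulate typing and data topology:
#' [make_constant()], [join_arrays()], [logical_not()], and the composed
#' helper [concatenate_lists()] — which is deliberately implemented *as a
#' fold of join_arrays nodes*, because composability of primitives is the
#' design point, not a convenience.
#' @name ops_std
NULL

const_spec <- function(kind = k_any()) {
  operation_spec(
    "make_constant", inputs = list(),
    outputs = list(port_spec("data", kind)),
    category = "pure",
    runner = function(inputs, member, session, node) {
      list(data = node$extras$value)
    }
  )
}

# Internal: constant node with an explicit kind (bypasses make_constant's
# payload restrictions; used by control flow to re-inject loop state).
const_node <- function(graph, value, kind) {
  add_node(graph, const_spec(kind), list(), extras = list(value = value, kind = kind))
}

#' Constant source node
#'
#' Wraps a payload as a width-1 Future whose kind is inferred from the
#' value: scalars map to their scalar kind, homogeneous vectors and bare
#' lists to `array_of(<elem>)`. Heterogeneous lists are rejected.
#'
#' @param value payload.
#' @param kind optional explicit [wg_kind()] (e.g. `k_file()` for a path,
#'   which would otherwise infer as `text`).
#' @param graph target graph (default: active graph).
#' @return a `wg_future` of width 1; resolving yields the value unchanged.
#' @export
make_constant <- function(value, kind = NULL, graph = active_graph()) {
  k <- if (is.null(kind)) infer_kind(value) else kind
  if (!is.null(kind) && !value_conforms(value, kind)) {
    wg_error("wg_unsupported_payload", "value does not conform to the stated kind")
  }
  ofuture(const_node(graph, value, k))
}

as_array_input <- function(x, graph) {
  if (inherits(x, "wg_future")) {
    if (x$kind$tag != "array" && x$kind$tag != "any") {
      wg_error("wg_kind_mismatch",
               sprintf("expected an array future, got %s", format(x$kind)))
    }
    x
  } else if (inherits(x, "wg_node")) {
    as_array_input(ofuture(x), graph)
  } else {
    k <- infer_kind(x)
    if (k$tag != "array") {
      # promote a length-1 scalar to a one-element array
      k <- k_array(k)
    }
    make_constant(if (is.list(x)) x else as.vector(x), kind = k, graph = graph)
  }
}

elem_kind_of <- function(f) if (f$kind$tag == "array") f$kind$elem else k_any()

logical_not_spec <- function() {
  operation_spec(
    "logical_not",
    inputs = list(port_spec("data", k_boolean())),
    outputs = list(port_spec("data", k_boolean())),
    category = "pure",
    runner = function(inputs, member, session, node) list(data = !inputs$data)
  )
}

join_spec <- function(elem) {
  operation_spec(
    "join_arrays",
    inputs = list(port_spec("front", k_array(elem)), port_spec("back", k_array(elem))),
    outputs = list(port_spec("data", k_array(elem))),
    category = "pure",
    runner = function(inputs, member, session, node) {
      f <- inputs$front; b <- inputs$back
      if (length(f) == 0L) return(list(data = b))  # empty-array identities
      if (length(b) == 0L) return(list(data = f))
      if (is.list(f) || is.list(b)) {
        list(data = c(as.list(f), as.list(b)))
      } else {
        list(data = c(f, b))
      }
    }
  )
}

#' Concatenate two arrays
#'
#' @param front,back array Futures or constants sharing an element kind
#'   (the unknown element kind of an empty array unifies with any).
#' @param graph target graph.
#' @return Future of the concatenated array (`front` elements first).
#' @export
join_arrays <- function(front, back, graph = active_graph()) {
  f <- as_array_input(front, graph)
  b <- as_array_input(back, graph)
  ef <- elem_kind_of(f); eb <- elem_kind_of(b)
  if (!kind_compatible(ef, eb)) {
    wg_error("wg_kind_mismatch",
             sprintf("element kinds differ: %s vs %s", format(ef), format(eb)))
  }
  elem <- if (ef$tag == "any") eb else ef
  ofuture(add_node(graph, join_spec(elem), list(front = f, back = b)))
}

#' Boolean negation
#'
#' Member-wise over ensembles: a width-n boolean input yields a width-n
#' output. Applying twice is the identity.
#'
#' @param value boolean Future or constant (a bare logical vector of
#'   length > 1 fans out into an ensemble).
#' @param graph target graph.
#' @return boolean Future.
#' @export
logical_not <- function(value, graph = active_graph()) {
  spec <- logical_not_spec()
  if (!inherits(value, c("wg_future", "wg_node")) && !is.logical(value)) {
    wg_error("wg_kind_mismatch", "logical_not requires a boolean input")
  }
  if (inherits(value, "wg_node")) value <- ofuture(value)
  ofuture(add_node(graph, spec, list(data = value)))
}

#' Flatten a sequence of arrays into one
#'
#' Built by composition: the result is a left fold of [join_arrays()]
#' nodes over the sequence, starting from an empty-array constant — so a
#' call with k sublists adds k `join_arrays` nodes to the graph. An empty
#' sequence yields an empty array whose element kind is unknown and
#' unifies with any array downstream.
#'
#' @param sublists list of array Futures or constants sharing an element kind.
#' @param graph target graph.
#' @return Future of the flattened array.
#' @export
concatenate_lists <- function(sublists = list(), graph = active_graph()) {
  acc <- make_constant(list(), kind = k_array(k_any()), graph = graph)
  for (x in sublists) {
    acc <- join_arrays(acc, x, graph = graph)
  }
  acc
}

#' Ensemble boolean reductions
#'
#' Plain-value helpers for loop conditions: a boolean of width > 1 is
#' ambiguous as a loop gate, so ensemble-width flags must pass through an
#' explicit any/all reduction first.
#'
#' @param x logical vector or list of logicals (a localized ensemble value).
#' @return logical scalar.
#' @export
ensemble_any <- function(x) any(unlist(x), na.rm = TRUE)

#' @rdname ensemble_any
#' @export
ensemble_all <- function(x) all(unlist(x), na.rm = TRUE)
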