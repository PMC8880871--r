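#' @title Control flow: subgraphs and while loops
#' @description
#' A subgraph fuses a group of operations with named internal state
#' variables; [while_loop()] dynamically extends the work graph as a
#' chain of repeated subgraph instantiations gated by a boolean
#' condition. Semantics are *pre-test* (condition evaluated on the
#' current variable state before each iteration), and `max_iteration` is
#' a required safety guard — exhausting it is not an error, the loop
#' simply stops and `iterations_run` reports the count. Graph growth is
#' literal: every iteration instantiates fresh nodes appended to the
#' executed chain, visible in [execution_log()]. Variable state is
#' isolated per loop instance: two loops over the same subgraph spec do
#' not share state.
#' @name control_flow
NULL

#' Declare a subgraph with state variables
#'
#' @param variables named list of initial values, or named list of
#'   `list(kind = <wg_kind>, initial = <value>)` entries when the kind
#'   should not be inferred.
#' @param body function of one argument (a named list of Futures for the
#'   current variable state); it may instantiate any operation of any
#'   module and must return a named list of variable updates (Futures or
#'   plain values, names a subset of the variable names). A body
#'   returning an empty list is valid (pure side-effect iteration).
#' @param outputs which variables the loop exposes as final Futures;
#'   default all.
#' @param name optional registry name; a named subgraph can be referenced
#'   by serialized `while_loop` nodes and must be re-registered (with
#'   [register_subgraph()]) before such a document is deserialized.
#' @param condition optional default loop condition carried with the
#'   spec (see [while_loop()]); serialized loop nodes rely on it.
#' @return a `wg_subgraph` spec (frozen).
#' @export
subgraph <- function(variables, body, outputs = names(variables), name = NULL,
                     condition = NULL) {
  if (length(variables) == 0L || is.null(names(variables)) ||
      anyDuplicated(names(variables))) {
    wg_error("wg_variable_shadowing", "variables must have unique names")
  }
  vars <- lapply(names(variables), function(vn) {
    v <- variables[[vn]]
    if (is.list(v) && !is.null(v$kind)) {
      # ensemble-valued state (bare list / length-n vector) is allowed
      if (!value_conforms(v$initial, v$kind) && !is_fanout_value(v$initial, v$kind)) {
        wg_error("wg_update_kind_mismatch",
                 sprintf("initial value of '%s' does not conform to its kind", vn))
      }
      list(name = vn, kind = v$kind, initial = v$initial)
    } else {
      list(name = vn, kind = infer_kind(v), initial = v)
    }
  })
  names(vars) <- names(variables)
  stopifnot(is.function(body), all(outputs %in% names(vars)))
  sg <- structure(list(variables = vars, body = body, outputs = outputs,
                       name = name, condition = condition),
                  class = "wg_subgraph")
  if (!is.null(name)) register_subgraph(name, sg)
  sg
}

#' @rdname subgraph
#' @param sg a `wg_subgraph`.
#' @export
register_subgraph <- function(name, sg) {
  stopifnot(is.character(name), inherits(sg, "wg_subgraph"))
  sg$name <- name
  assign(name, sg, envir = .wg_state$subgraphs)
  invisible(sg)
}

get_subgraph <- function(name) {
  if (!exists(name, envir = .wg_state$subgraphs, inherits = FALSE)) {
    wg_error("wg_unknown_operation", sprintf("subgraph '%s' is not registered", name))
  }
  get(name, envir = .wg_state$subgraphs, inherits = FALSE)
}

#' @export
print.wg_subgraph <- function(x, ...) {
  cat(sprintf("<subgraph: variables [%s]>\n", paste(names(x$variables), collapse = ", ")))
  invisible(x)
}

# Inject current state as constant source nodes so the body reads
# variables through ordinary Futures (fresh nodes each iteration: the
# dynamic-extension contract). Ensemble-valued state (bare lists) becomes
# a fan-out constant via a pass-through node.
ensemble_state_spec <- function(kind = k_any()) {
  operation_spec(
    "ensemble_state", inputs = list(port_spec("data", kind, required = FALSE)),
    outputs = list(port_spec("data", kind)),
    runner = function(inputs, member, session, node) list(data = inputs$data)
  )
}

state_futures <- function(graph, sg, state) {
  out <- list()
  for (vn in names(sg$variables)) {
    v <- state[[vn]]
    kind <- sg$variables[[vn]]$kind
    if (is_fanout_value(v, kind)) {
      out[[vn]] <- ofuture(add_node(graph, ensemble_state_spec(kind), list(data = v)))
    } else {
      out[[vn]] <- ofuture(const_node(graph, v, kind))
    }
  }
  out
}

#' Repeat a subgraph while a condition holds
#'
#' Before each iteration the condition is evaluated on the current
#' variable state; while it is true and fewer than `max_iteration`
#' iterations have run, one instantiation of the body is appended to the
#' graph, executed, and its variable updates become the next state.
#'
#' @param operation a `wg_subgraph` (or the registry name of one).
#' @param condition either a function of the current state — a named list
#'   of plain values — returning a logical scalar or a boolean Future
#'   (built from graph operations over the state), or a boolean constant.
#'   Ensemble-width variables must pass through an explicit reduction
#'   ([ensemble_any()] / [ensemble_all()]); a boolean of width > 1 is
#'   rejected as ambiguous.
#' @param max_iteration required non-negative safety guard; reaching it
#'   stops the loop without error.
#' @param graph target graph.
#' @return a `wg_node` handle with one output Future per exposed variable
#'   plus `iterations_run` (integer).
#' @export
while_loop <- function(operation, condition = NULL, max_iteration,
                       graph = active_graph()) {
  if (is.character(operation)) operation <- get_subgraph(operation)
  stopifnot(inherits(operation, "wg_subgraph"))
  if (is.null(condition)) condition <- operation$condition
  if (is.null(condition)) {
    wg_error("wg_non_boolean_condition",
             "no loop condition given and the subgraph spec carries none")
  }
  max_iteration <- as.integer(max_iteration)
  if (is.na(max_iteration) || max_iteration < 0L) {
    wg_error("wg_invalid_spec", "max_iteration must be a non-negative integer")
  }
  sg <- operation
  # variable outputs use kind `any`: a final value may be scalar or an
  # ensemble-valued (per-member) list depending on the body's width
  out_ports <- c(
    lapply(sg$outputs, function(vn) port_spec(vn, k_any())),
    list(port_spec("iterations_run", k_integer()))
  )
  spec <- operation_spec(
    "while_loop", inputs = list(), outputs = out_ports, category = "control",
    deterministic = FALSE,
    runner = function(inputs, member, session, node) {
      sg <- node$extras$subgraph
      cond <- node$extras$condition
      maxit <- node$extras$max_iteration
      # state local to this invocation: loop instances never share it
      state <- lapply(sg$variables, `[[`, "initial")
      iters <- 0L
      repeat {
        cv <- eval_condition(cond, state, session$graph)
        if (!cv || iters >= maxit) break
        n_before <- length(session$graph$node_order)
        vars <- state_futures(session$graph, sg, state)
        updates <- sg$body(vars)
        if (length(updates)) {
          if (is.null(names(updates)) ||
              !all(names(updates) %in% names(sg$variables))) {
            wg_error("wg_update_kind_mismatch",
                     "body updates must be named after declared variables")
          }
          for (un in names(updates)) {
            u <- updates[[un]]
            val <- if (inherits(u, "wg_future") || inherits(u, "wg_node")) {
              result(u)
            } else u
            vk <- sg$variables[[un]]$kind
            if (!is_fanout_value(val, vk) && !value_conforms(val, vk)) {
              wg_error("wg_update_kind_mismatch",
                       sprintf("update of variable '%s' does not conform to kind %s",
                               un, format(vk)))
            }
            state[[un]] <- val
          }
        }
        # force this iteration's instantiation to completion, including
        # pure side-effect bodies with no variable updates
        new_ids <- session$graph$node_order[-seq_len(n_before)]
        for (id in new_ids) resolve_node(session, id)
        iters <- iters + 1L
      }
      c(state[sg$outputs], list(iterations_run = iters))
    }
  )
  add_node(graph, spec, list(),
           extras = list(subgraph = sg, condition = condition,
                         max_iteration = max_iteration,
                         subgraph_ref = sg$name))
}

eval_condition <- function(condition, state, graph) {
  v <- if (is.function(condition)) condition(state) else condition
  if (inherits(v, "wg_node")) v <- ofuture(v)
  if (inherits(v, "wg_future")) {
    if (v$width != 1L) {
      wg_error("wg_non_boolean_condition",
               "loop condition has ensemble width > 1; reduce it with ensemble_any/ensemble_all")
    }
    if (!kind_compatible(v$kind, k_boolean())) {
      wg_error("wg_non_boolean_condition",
               sprintf("loop condition has kind %s, not boolean", format(v$kind)))
    }
    v <- result(v)
  }
  if (!is.logical(v) || length(v) != 1L || is.na(v)) {
    wg_error("wg_non_boolean_condition", "loop condition must yield a single TRUE/FALSE")
  }
  v
}
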