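#' @title The work graph
#' @description
#' A work graph is a directed acyclic graph whose nodes are typed
#' operations and whose edges are data dependencies. It is a specification
#' of work, decoupled from execution: adding a node returns a handle with
#' Future outputs, and nothing runs until [result()] is called on a
#' Future. Every node and edge carries an ensemble width; passing an array
#' of inputs where a scalar is expected fans the operation out into an
#' ensemble.
#' @name workgraph
NULL

.wg_state <- new.env(parent = emptyenv())
.wg_state$active <- NULL
.wg_state$registry <- new.env(parent = emptyenv())
.wg_state$subgraphs <- new.env(parent = emptyenv())

#' Create a new (empty) work graph
#'
#' The new graph becomes the active graph: operation constructors called
#' without an explicit `graph` argument add their nodes here.
#'
#' @param activate set as the active graph (default `TRUE`).
#' @return a `wg_graph` object (an environment; graphs are mutable).
#' @export
work_graph <- function(activate = TRUE) {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()       # node_id -> node record
  g$node_order <- character(0)
  g$edges <- list()       # list(from, from_port, to, to_port, mode)
  g$counters <- list()    # op_name -> integer
  g$session <- NULL
  class(g) <- "wg_graph"
  if (activate) .wg_state$active <- g
  g
}

#' The active work graph
#'
#' @return the graph that operation constructors target by default;
#'   created on first use.
#' @export
active_graph <- function() {
  if (is.null(.wg_state$active)) .wg_state$active <- work_graph(activate = FALSE)
  .wg_state$active
}

#' @rdname active_graph
#' @param graph a `wg_graph` to activate.
#' @export
set_active_graph <- function(graph) {
  stopifnot(inherits(graph, "wg_graph"))
  old <- .wg_state$active
  .wg_state$active <- graph
  invisible(old)
}

#' @export
print.wg_graph <- function(x, ...) {
  cat(sprintf("<work graph: %d nodes, %d edges>\n", length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Declare an operation port
#'
#' @param name identifier, unique within the operation.
#' @param kind a [wg_kind()].
#' @param required must be bound at graph-build time; a required port may
#'   not carry a default.
#' @param default value used when an optional port is unbound.
#' @return a `wg_port` object.
#' @export
port_spec <- function(name, kind, required = TRUE, default = NULL) {
  if (required && !is.null(default)) {
    wg_error("wg_invalid_spec", sprintf("required port '%s' may not have a default", name))
  }
  structure(list(name = name, kind = kind, required = required, default = default),
            class = "wg_port")
}

#' Declare an operation
#'
#' An operation has named, kinded input and output ports, a category
#' (`pure`, `external_process` or `simulation`) and a runner. The runner
#' is invoked once per ensemble member as
#' `runner(inputs, member, session, node)` and must return a named list
#' with one entry per declared output. Simulation-category operations may
#' instead provide `ensemble_runner(inputs_by_member, session, node)`,
#' which advances all members together (the co-execution contract needed
#' for ensemble reductions and ensemble-scope stop signals).
#'
#' @param op_name globally unique operation name (registry key).
#' @param inputs list of [port_spec()]s.
#' @param outputs list of [port_spec()]s; at least one.
#' @param category one of `"pure"`, `"external_process"`, `"simulation"`.
#' @param deterministic logical; documentation only.
#' @param runner per-member runner function.
#' @param ensemble_runner whole-ensemble runner (simulation category).
#' @param variadic accept arbitrary extra input ports of kind `any`
#'   (used by generated fixture operations).
#' @param wrapped marks specs produced by [function_wrapper()].
#' @return a `wg_opspec` object.
#' @export
operation_spec <- function(op_name, inputs = list(), outputs, category = "pure",
                           deterministic = TRUE, runner = NULL,
                           ensemble_runner = NULL, variadic = FALSE,
                           wrapped = FALSE) {
  stopifnot(category %in% c("pure", "external_process", "simulation", "control"))
  if (length(outputs) == 0L) {
    wg_error("wg_invalid_spec", sprintf("operation '%s' declares no outputs", op_name))
  }
  nm <- vapply(inputs, function(p) p$name, character(1))
  if (anyDuplicated(nm)) {
    wg_error("wg_invalid_spec", sprintf("duplicate input port names in '%s'", op_name))
  }
  names(inputs) <- nm
  names(outputs) <- vapply(outputs, function(p) p$name, character(1))
  structure(list(op_name = op_name, inputs = inputs, outputs = outputs,
                 category = category, deterministic = deterministic,
                 runner = runner, ensemble_runner = ensemble_runner,
                 variadic = variadic, wrapped = wrapped),
            class = "wg_opspec")
}

#' Operation registry
#'
#' Specs are registered by `op_name` so that serialized graphs can be
#' reconstructed. Built-in operations register at package load; wrapped
#' operations register when their factory is created and must be
#' re-registered before deserializing a document that uses them.
#'
#' @param spec a `wg_opspec`.
#' @param overwrite replace an existing registration.
#' @export
register_operation <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "wg_opspec"))
  if (!overwrite && exists(spec$op_name, envir = .wg_state$registry, inherits = FALSE)) {
    wg_error("wg_duplicate_operation",
             sprintf("operation '%s' already registered", spec$op_name))
  }
  assign(spec$op_name, spec, envir = .wg_state$registry)
  invisible(spec)
}

#' @rdname register_operation
#' @param op_name registry key.
#' @export
get_operation <- function(op_name) {
  if (!exists(op_name, envir = .wg_state$registry, inherits = FALSE)) {
    wg_error("wg_unknown_operation", sprintf("unknown operation name '%s'", op_name))
  }
  get(op_name, envir = .wg_state$registry, inherits = FALSE)
}

registered_operations <- function() ls(.wg_state$registry)

#' Ensemble width broadcasting
#'
#' The ensemble dimension is the only implicit parallel axis. Widths
#' combine by broadcasting: a width-1 (scalar) input replicates across an
#' ensemble; two distinct widths > 1 have no common broadcast and are an
#' error.
#'
#' @param widths integer vector of member counts (each >= 1).
#' @return the broadcast width (max of the inputs).
#' @export
infer_width <- function(widths) {
  widths <- as.integer(widths)
  if (length(widths) == 0L) wg_error("wg_incompatible_widths", "empty width sequence")
  if (any(widths < 1L)) wg_error("wg_incompatible_widths", "widths must be >= 1")
  w <- max(widths)
  if (!all(widths == 1L | widths == w)) {
    wg_error("wg_incompatible_widths",
             sprintf("incompatible ensemble widths: %s", paste(sort(unique(widths)), collapse = ", ")))
  }
  w
}

#' Mark a Future input for gather-mode binding
#'
#' A gathered Future delivers *all* ensemble members of its source as one
#' array (ordered by 0-based member index) to a single sink input, and
#' contributes width 1 to the sink's width inference.
#'
#' @param future a `wg_future` of any width.
#' @return a gather marker accepted anywhere a bound input is.
#' @export
gather <- function(future) {
  stopifnot(inherits(future, "wg_future"))
  structure(list(future = future), class = "wg_gather")
}

new_future <- function(graph, node_id, port, kind, width) {
  structure(list(graph = graph, node_id = node_id, port = port,
                 kind = kind, width = width),
            class = "wg_future")
}

#' @export
print.wg_future <- function(x, ...) {
  cat(sprintf("<future %s:%s kind=%s width=%d resolved=%s>\n",
              x$node_id, x$port, format(x$kind), x$width, is_resolved(x)))
  invisible(x)
}

#' Has a Future been computed in its graph's session?
#' @param future a `wg_future`.
#' @return logical scalar.
#' @export
is_resolved <- function(future) {
  s <- future$graph$session
  if (is.null(s)) return(FALSE)
  exists(cache_key(future$node_id, future$port), envir = s$cache, inherits = FALSE)
}

#' @export
print.wg_node <- function(x, ...) {
  cat(sprintf("<node %s op=%s width=%d outputs=[%s]>\n", x$node_id,
              x$spec$op_name, x$width, paste(names(x$spec$outputs), collapse = ", ")))
  invisible(x)
}

#' Future for one output port of a node handle
#'
#' @param handle a `wg_node` handle returned by an operation constructor.
#' @param port output port name; defaults to the node's single/first output.
#' @return a `wg_future`.
#' @export
ofuture <- function(handle, port = NULL) {
  if (inherits(handle, "wg_future")) return(handle)
  stopifnot(inherits(handle, "wg_node"))
  if (is.null(port)) port <- names(handle$spec$outputs)[1L]
  if (!port %in% names(handle$spec$outputs)) {
    wg_error("wg_unknown_port", sprintf("node '%s' has no output port '%s'",
                                        handle$node_id, port))
  }
  new_future(handle$graph, handle$node_id, port, handle$spec$outputs[[port]]$kind,
             handle$width)
}

node_handle <- function(graph, node_id) {
  node <- graph$nodes[[node_id]]
  structure(list(graph = graph, node_id = node_id, spec = node$spec,
                 width = node$width),
            class = "wg_node")
}

#' Handle for an existing graph node
#'
#' Useful after [deserialize_graph()], when the original construction
#' handles are gone.
#'
#' @param graph a `wg_graph`.
#' @param node_id node identifier.
#' @return a `wg_node` handle.
#' @export
graph_node <- function(graph, node_id) {
  if (!node_id %in% graph$node_order) {
    wg_error("wg_unknown_port", sprintf("no node '%s' in graph", node_id))
  }
  node_handle(graph, node_id)
}

# Is a constant value a fan-out binding for a scalar-kinded port?
# Rule: a bare list, or an atomic vector of length > 1, bound to a
# non-array port is interpreted as one value per ensemble member. Ports
# of kind `any` (wrapped operations) follow the same rule; to pass a
# whole array as one value, bind a width-1 array Future instead.
is_fanout_value <- function(value, kind) {
  if (kind$tag == "array") return(FALSE)
  if (is.list(value) && is.null(attr(value, "class"))) return(TRUE)
  if (is.atomic(value) && is.null(attr(value, "class")) && length(value) > 1L) return(TRUE)
  FALSE
}

#' Add a node to a work graph
#'
#' Binds constants and Futures to the operation's input ports, infers the
#' node's ensemble width by broadcasting the widths of its inputs, creates
#' one data edge per bound Future (map, broadcast or gather mode), and
#' appends the node under a deterministic id `<op_name>-<k>` with `k` a
#' per-operation counter — so repeated script runs build identical graphs.
#'
#' @param graph a `wg_graph`.
#' @param spec a `wg_opspec`.
#' @param inputs named list: port name -> constant, `wg_future`, or
#'   [gather()] marker.
#' @param extras opaque payload attached to the node (plugins, wrapped
#'   procedure closures, loop bodies); not part of the typed interface.
#' @return a `wg_node` handle.
#' @export
add_node <- function(graph, spec, inputs = list(), extras = NULL) {
  stopifnot(inherits(graph, "wg_graph"), inherits(spec, "wg_opspec"))
  if (length(inputs) && (is.null(names(inputs)) || any(names(inputs) == ""))) {
    wg_error("wg_unknown_port", "all inputs must be named by port")
  }
  ports <- spec$inputs
  for (pn in names(inputs)) {
    if (!pn %in% names(ports)) {
      if (spec$variadic) {
        ports[[pn]] <- port_spec(pn, k_any(), required = FALSE)
      } else {
        wg_error("wg_unknown_port",
                 sprintf("operation '%s' has no input port '%s'", spec$op_name, pn))
      }
    }
  }
  for (pn in names(ports)) {
    if (ports[[pn]]$required && !pn %in% names(inputs)) {
      wg_error("wg_missing_required_input",
               sprintf("required input '%s' of '%s' is not bound", pn, spec$op_name))
    }
  }

  bound <- list()
  widths <- 1L
  for (pn in names(inputs)) {
    v <- inputs[[pn]]
    pk <- ports[[pn]]$kind
    if (inherits(v, "wg_gather")) {
      f <- v$future
      if (!identical(f$graph, graph)) {
        wg_error("wg_foreign_future", "future belongs to a different graph")
      }
      if (!kind_compatible(k_array(f$kind), pk)) {
        wg_error("wg_kind_mismatch",
                 sprintf("gathered %s incompatible with port '%s' (%s)",
                         format(k_array(f$kind)), pn, format(pk)))
      }
      bound[[pn]] <- list(type = "future", node = f$node_id, port = f$port,
                          mode = "gather", width = 1L)
    } else if (inherits(v, "wg_future")) {
      if (!identical(v$graph, graph)) {
        wg_error("wg_foreign_future", "future belongs to a different graph")
      }
      if (!kind_compatible(v$kind, pk)) {
        wg_error("wg_kind_mismatch",
                 sprintf("future of kind %s incompatible with port '%s' (%s)",
                         format(v$kind), pn, format(pk)))
      }
      bound[[pn]] <- list(type = "future", node = v$node_id, port = v$port,
                          mode = NA_character_, width = v$width)
      widths <- c(widths, v$width)
    } else if (is_fanout_value(v, pk)) {
      members <- if (is.list(v)) v else as.list(v)
      ok <- vapply(members, value_conforms, logical(1), kind = pk)
      if (!all(ok)) {
        wg_error("wg_kind_mismatch",
                 sprintf("fan-out member %d does not conform to port '%s' (%s)",
                         which(!ok)[1L], pn, format(pk)))
      }
      bound[[pn]] <- list(type = "fanout", value = members, width = length(members))
      widths <- c(widths, length(members))
    } else {
      if (!value_conforms(v, pk)) {
        wg_error("wg_kind_mismatch",
                 sprintf("constant does not conform to port '%s' (%s)", pn, format(pk)))
      }
      bound[[pn]] <- list(type = "constant", value = v, width = 1L)
    }
  }
  width <- infer_width(widths)
  for (pn in names(bound)) {
    b <- bound[[pn]]
    if (b$type == "future" && is.na(b$mode)) {
      bound[[pn]]$mode <- if (b$width == width) "map" else "broadcast"
    }
    if (b$type == "fanout" && b$width != width) {
      wg_error("wg_incompatible_widths",
               sprintf("fan-out width %d of port '%s' incompatible with node width %d",
                       b$width, pn, width))
    }
  }

  k <- (graph$counters[[spec$op_name]] %||% 0L) + 1L
  graph$counters[[spec$op_name]] <- k
  node_id <- sprintf("%s-%d", spec$op_name, k)
  node <- list(node_id = node_id, spec = spec, inputs = bound, width = width,
               extras = extras, ports = ports)
  graph$nodes[[node_id]] <- node
  graph$node_order <- c(graph$node_order, node_id)
  for (pn in names(bound)) {
    b <- bound[[pn]]
    if (b$type == "future") {
      graph$edges[[length(graph$edges) + 1L]] <-
        list(from = b$node, from_port = b$port, to = node_id, to_port = pn,
             mode = bound[[pn]]$mode)
    }
  }
  node_handle(graph, node_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", length(graph$node_order)), graph$node_order)
  for (e in graph$edges) adj[[e$from]] <- c(adj[[e$from]], e$to)
  adj
}

#' Validate a work graph
#'
#' Checks every structural invariant — edge endpoints and ports exist,
#' kinds along edges are compatible, edge widths obey map/broadcast rules,
#' and the graph is acyclic — returning one diagnostic per violation
#' rather than raising. A valid graph yields `character(0)`.
#'
#' @param graph a `wg_graph`.
#' @return character vector of diagnostics (empty iff valid).
#' @export
validate_graph <- function(graph) {
  diags <- character(0)
  ids <- graph$node_order
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    if (!e$from %in% ids) {
      diags <- c(diags, sprintf("edge %d: unknown source node '%s'", i, e$from)); next
    }
    if (!e$to %in% ids) {
      diags <- c(diags, sprintf("edge %d: unknown sink node '%s'", i, e$to)); next
    }
    src <- graph$nodes[[e$from]]; snk <- graph$nodes[[e$to]]
    if (!e$from_port %in% names(src$spec$outputs)) {
      diags <- c(diags, sprintf("edge %d: node '%s' has no output port '%s'",
                                i, e$from, e$from_port)); next
    }
    if (!e$to_port %in% names(snk$ports)) {
      diags <- c(diags, sprintf("edge %d: node '%s' has no input port '%s'",
                                i, e$to, e$to_port)); next
    }
    sk <- src$spec$outputs[[e$from_port]]$kind
    tk <- snk$ports[[e$to_port]]$kind
    ek <- if (identical(e$mode, "gather")) k_array(sk) else sk
    if (!kind_compatible(ek, tk)) {
      diags <- c(diags, sprintf("edge %d (%s:%s -> %s:%s): kind %s incompatible with %s",
                                i, e$from, e$from_port, e$to, e$to_port,
                                format(ek), format(tk)))
    }
    if (identical(e$mode, "map") && src$width != snk$width &&
        !(src$width == 1L && snk$width == 1L)) {
      diags <- c(diags, sprintf("edge %d: map mode requires equal widths (%d vs %d)",
                                i, src$width, snk$width))
    }
    if (identical(e$mode, "broadcast") && src$width != 1L) {
      diags <- c(diags, sprintf("edge %d: broadcast mode requires width-1 source (got %d)",
                                i, src$width))
    }
  }
  cyc <- find_cycle(graph)
  if (!is.null(cyc)) {
    diags <- c(diags, sprintf("cycle detected: %s", paste(cyc, collapse = " -> ")))
  }
  diags
}

# Iterative DFS cycle finder; returns node ids on a cycle, or NULL.
find_cycle <- function(graph) {
  adj <- adjacency(graph)
  color <- stats::setNames(rep(0L, length(graph$node_order)), graph$node_order)
  for (start in graph$node_order) {
    if (color[[start]] != 0L) next
    stack <- list(list(id = start, nxt = 1L))
    color[[start]] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      kids <- adj[[top$id]]
      if (top$nxt <= length(kids)) {
        child <- kids[[top$nxt]]
        stack[[length(stack)]]$nxt <- top$nxt + 1L
        if (color[[child]] == 1L) {
          i <- match(child, path)
          return(c(path[i:length(path)], child))
        }
        if (color[[child]] == 0L) {
          color[[child]] <- 1L
          stack[[length(stack) + 1L]] <- list(id = child, nxt = 1L)
          path <- c(path, child)
        }
      } else {
        color[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

#' Topological order of a work graph
#'
#' Kahn's algorithm with a stable tie-break: among ready nodes, insertion
#' order decides — so execution logs are deterministic and reproducible.
#'
#' @param graph a `wg_graph`.
#' @return character vector of node ids, every edge's source before its sink.
#' @export
topological_order <- function(graph) {
  ids <- graph$node_order
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (e in graph$edges) {
    # parallel edges between the same pair still count once each
    indeg[[e$to]] <- indeg[[e$to]] + 1L
    adj[[e$from]] <- c(adj[[e$from]], e$to)
  }
  out <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0L) {
      wg_error("wg_cyclic_graph", "graph contains a cycle; no topological order exists")
    }
    nxt <- ready[[1L]]   # insertion-order tie-break: remaining preserves it
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    for (child in adj[[nxt]]) indeg[[child]] <- indeg[[child]] - 1L
  }
  out
}

# All ancestors of node_id (nodes it transitively depends on), plus itself.
ancestor_set <- function(graph, node_id) {
  parents <- stats::setNames(vector("list", length(graph$node_order)), graph$node_order)
  for (e in graph$edges) parents[[e$to]] <- c(parents[[e$to]], e$from)
  seen <- character(0)
  queue <- node_id
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, unlist(parents[[cur]]))
  }
  seen
}

#' Export a work graph to Graphviz DOT
#'
#' @param graph a `wg_graph`.
#' @return a length-1 character DOT document (node label = node id, edge
#'   label = `source_port->sink_port`).
#' @export
graph_to_dot <- function(graph) {
  lines <- c("digraph workgraph {")
  for (id in graph$node_order) {
    lines <- c(lines, sprintf('  "%s" [label="%s"];', id, id))
  }
  for (e in graph$edges) {
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s->%s"];',
                              e$from, e$to, e$from_port, e$to_port))
  }
  paste(c(lines, "}"), collapse = "\n")
}
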