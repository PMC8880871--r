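#' @title Graph serialization
#' @description
#' Work graphs serialize to a JSON document with top-level keys
#' `schema_version`, `nodes` and `edges`. Node entries carry the
#' operation name, bound constants (with their kinds, so integer/real
#' distinctions survive the trip), fan-out member values, Future
#' references, and ensemble width; `while_loop` nodes additionally carry
#' their declarative subgraph part (variables with kinds and initial
#' values, `max_iteration`) plus the registry name of the subgraph.
#' Deserialization rebuilds nodes through [add_node()] in insertion
#' order, so node ids regenerate identically and
#' `deserialize_graph(serialize_graph(g))` is graph-isomorphic to `g`.
#'
#' Procedure bodies (wrapped operations, subgraph bodies, loop
#' conditions) are R closures and are *not* serialized: documents record
#' the operation or subgraph name only, and the same name must be
#' registered again before deserializing.
#' @name serialization
NULL

SCHEMA_VERSION <- 1L

encode_value <- function(v) {
  if (inherits(v, "toy_input")) {
    list(`_class` = "toy_input",
         system = list(masses = v$system$masses,
                       positions = apply(v$system$positions, 1L, identity, simplify = FALSE),
                       velocities = apply(v$system$velocities, 1L, identity, simplify = FALSE),
                       bonds = v$system$bonds),
         params = unclass(v$params))
  } else if (inherits(v, "toy_overrides")) {
    list(`_class` = "toy_overrides", entries = unclass(v))
  } else if (inherits(v, "toy_plugin")) {
    c(list(`_class` = "toy_plugin"), unclass(v))
  } else if (is.null(attr(v, "class")) && (is.atomic(v) || is.list(v))) {
    v
  } else {
    wg_error("wg_malformed_document",
             sprintf("value of class '%s' cannot be serialized",
                     paste(class(v), collapse = "/")))
  }
}

decode_value <- function(x, kind = NULL) {
  if (is.list(x) && !is.null(x$`_class`)) {
    switch(x$`_class`,
      toy_input = {
        sys <- toy_system(as.numeric(unlist(x$system$masses)),
                          matrix(as.numeric(unlist(x$system$positions)), ncol = 3, byrow = TRUE),
                          matrix(as.numeric(unlist(x$system$velocities)), ncol = 3, byrow = TRUE),
                          if (length(x$system$bonds)) {
                            do.call(rbind, lapply(x$system$bonds, as.data.frame))
                          } else NULL)
        p <- x$params
        simulation_input(sys, sim_params(p$dt, p$nsteps, p$friction_gamma,
                                         p$output_interval, p$seed))
      },
      toy_overrides = structure(x$entries, class = "toy_overrides"),
      toy_plugin = restraint_plugin(unlist(x$pair), unlist(x$k_restraint),
                                    unlist(x$target), unlist(x$stop_tolerance),
                                    unlist(x$stop_scope)[1L], unlist(x$reduce_mode)[1L]),
      wg_error("wg_malformed_document",
               sprintf("unknown serialized class '%s'", x$`_class`))
    )
  } else if (!is.null(kind)) {
    coerce_to_kind(x, kind)
  } else x
}

#' Serialize a work graph to JSON
#'
#' @param graph a `wg_graph`.
#' @param path optional file; when given the document is written there.
#' @return the JSON text (invisibly when `path` is given).
#' @export
serialize_graph <- function(graph, path = NULL) {
  nodes <- lapply(graph$node_order, function(id) {
    node <- graph$nodes[[id]]
    entry <- list(node_id = id, op_name = node$spec$op_name, width = node$width)
    ins <- list()
    for (pn in names(node$inputs)) {
      b <- node$inputs[[pn]]
      ins[[pn]] <- switch(b$type,
        constant = list(type = "constant",
                        kind = kind_to_list(infer_kind_or_null(b$value)),
                        value = encode_value(b$value)),
        fanout = list(type = "fanout", value = lapply(b$value, encode_value)),
        future = list(type = "future", node = b$node, port = b$port, mode = b$mode)
      )
    }
    if (length(ins)) entry$inputs <- ins
    ex <- node$extras
    if (node$spec$op_name == "make_constant") {
      entry$value <- encode_value(ex$value)
      entry$kind <- kind_to_list(ex$kind)
    } else if (node$spec$op_name == "while_loop") {
      sg <- ex$subgraph
      entry$while_loop <- list(
        subgraph_ref = ex$subgraph_ref,
        max_iteration = ex$max_iteration,
        variables = lapply(sg$variables, function(v) {
          list(name = v$name, kind = kind_to_list(v$kind),
               initial = encode_value(v$initial))
        }),
        outputs = sg$outputs
      )
    } else if (node$spec$op_name == "mdrun") {
      entry$plugins <- lapply(ex$plugins, encode_value)
    }
    entry
  })
  edges <- lapply(graph$edges, function(e) {
    list(source = list(node = e$from, port = e$from_port),
         sink = list(node = e$to, port = e$to_port), mode = e$mode)
  })
  doc <- list(schema_version = SCHEMA_VERSION, nodes = nodes, edges = edges)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

infer_kind_or_null <- function(v) {
  tryCatch(infer_kind(v), error = function(e) NULL)
}

#' Deserialize a work graph from JSON
#'
#' Every operation name in the document must be registered (built-in
#' operations always are; wrapped operations and named subgraphs must be
#' re-registered first).
#'
#' @param text JSON text, or the path of a file containing it.
#' @return a fresh `wg_graph` (not activated).
#' @export
deserialize_graph <- function(text) {
  if (length(text) == 1L && !grepl("^\\s*\\{", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) wg_error("wg_malformed_document",
                                               sprintf("not valid JSON: %s",
                                                       conditionMessage(e))))
  if (is.null(doc$schema_version) || doc$schema_version != SCHEMA_VERSION) {
    wg_error("wg_schema_version_mismatch",
             sprintf("unsupported schema version: %s",
                     doc$schema_version %||% "<missing>"))
  }
  g <- work_graph(activate = FALSE)
  handles <- list()
  for (entry in doc$nodes) {
    op <- entry$op_name
    if (op == "make_constant") {
      kind <- kind_from_list(entry$kind)
      h <- const_node(g, decode_value(entry$value, kind), kind)
    } else if (op == "while_loop") {
      wl <- entry$while_loop
      ref <- wl$subgraph_ref
      if (is.null(ref)) {
        wg_error("wg_unknown_operation",
                 "serialized while_loop has no subgraph registry reference; register the subgraph with a name before serializing")
      }
      sg <- get_subgraph(ref)
      h <- while_loop(sg, max_iteration = wl$max_iteration, graph = g)
    } else {
      spec <- get_operation(op)
      inputs <- list()
      for (pn in names(entry$inputs)) {
        b <- entry$inputs[[pn]]
        pk <- if (pn %in% names(spec$inputs)) spec$inputs[[pn]]$kind else k_any()
        inputs[[pn]] <- switch(b$type,
          constant = decode_value(b$value, kind_from_list(b$kind) %||% pk),
          fanout = lapply(b$value, decode_value),
          future = {
            f <- ofuture(handles[[b$node]], b$port)
            if (identical(b$mode, "gather")) gather(f) else f
          }
        )
      }
      extras <- if (op == "mdrun") {
        list(plugins = lapply(entry$plugins, decode_value))
      } else NULL
      h <- add_node(g, spec, inputs, extras = extras)
    }
    if (!identical(h$node_id, entry$node_id)) {
      wg_error("wg_malformed_document",
               sprintf("node id mismatch on rebuild: document '%s' vs '%s'",
                       entry$node_id, h$node_id))
    }
    handles[[h$node_id]] <- h
  }
  g
}
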