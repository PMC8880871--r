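#' @title Deferred execution
#' @description
#' Execution is deferred until a Future is localized with [result()].
#' Resolution runs exactly the ancestor subgraph of the requested node —
#' never more — in an order consistent with [topological_order()], caches
#' every output per (node, member), and records a structured log entry per
#' executed (node, member). A (node, member) pair executes at most once
#' per session lifetime, so repeated `result()` calls, diamond
#' topologies, and forked chains never re-run completed work.
#' @name executor
NULL

cache_key <- function(node_id, port) paste0(node_id, "\r", port)

#' Create an execution session for a graph
#'
#' A session owns the output cache, the executed-node log, the working
#' directory root for external processes and simulations, and the master
#' seed from which per-(node, member) seeds are derived. Creating a new
#' session discards previous results (each session resolves every node at
#' most once).
#'
#' @param graph a `wg_graph`.
#' @param workdir root directory for per-task working directories
#'   (`<workdir>/<node_id>/<member>/`).
#' @param seed integer master seed; per-(node, member) streams are derived
#'   from it so members are reproducible but uncorrelated.
#' @param log_path optional path; when set, one JSON line is appended per
#'   executed (node, member).
#' @return the session object (also stored on the graph).
#' @export
new_session <- function(graph, workdir = tempfile("flowmd-work-"), seed = 0L,
                        log_path = NULL) {
  stopifnot(inherits(graph, "wg_graph"))
  s <- new.env(parent = emptyenv())
  s$graph <- graph
  s$cache <- new.env(parent = emptyenv())   # key -> list of per-member values
  s$done <- new.env(parent = emptyenv())    # node_id -> TRUE
  s$records <- list()
  s$order_counter <- 0L
  s$workdir <- workdir
  s$seed <- as.integer(seed)
  s$log_path <- log_path
  class(s) <- "wg_session"
  graph$session <- s
  s
}

#' @export
print.wg_session <- function(x, ...) {
  cat(sprintf("<session: %d records, seed %d, workdir %s>\n",
              length(x$records), x$seed, x$workdir))
  invisible(x)
}

session_of <- function(graph) {
  if (is.null(graph$session)) new_session(graph) else graph$session
}

# Deterministic per-(node, member) seed: master seed xor a small hash of
# the node id and member index, kept inside 31 bits.
member_seed <- function(session, node_id, member) {
  h <- 0
  for (ch in utf8ToInt(node_id)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + member) %% 2147483647
  as.integer(bitwAnd(bitwXor(as.integer(h), session$seed), 2147483647L))
}

task_dir <- function(session, node_id, member) {
  d <- file.path(session$workdir, node_id, sprintf("%d", member - 1L))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

record_execution <- function(session, node_id, member, op_name, wall, argv = NULL) {
  session$order_counter <- session$order_counter + 1L
  rec <- list(node_id = node_id, member = member - 1L,
              order_index = session$order_counter, op_name = op_name,
              status = "done", wall_time = wall)
  if (!is.null(argv)) rec$argv <- argv
  session$records[[length(session$records) + 1L]] <- rec
  if (!is.null(session$log_path)) {
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        sep = "", file = session$log_path, append = TRUE)
  }
  invisible(rec)
}

#' Executed-node log of a session
#'
#' @param x a `wg_session` or a `wg_graph` (its current session).
#' @return data frame with one row per executed (node, member):
#'   `node_id`, `member` (0-based), `order_index`, `op_name`.
#' @export
execution_log <- function(x) {
  s <- if (inherits(x, "wg_graph")) x$session else x
  if (is.null(s) || length(s$records) == 0L) {
    return(data.frame(node_id = character(0), member = integer(0),
                      order_index = integer(0), op_name = character(0)))
  }
  data.frame(
    node_id = vapply(s$records, `[[`, character(1), "node_id"),
    member = vapply(s$records, `[[`, integer(1), "member"),
    order_index = vapply(s$records, `[[`, integer(1), "order_index"),
    op_name = vapply(s$records, `[[`, character(1), "op_name")
  )
}

# Localize the inputs of `node` for ensemble member m (1-based).
localize_inputs <- function(session, node, m) {
  graph <- session$graph
  out <- list()
  for (pn in names(node$ports)) {
    b <- node$inputs[[pn]]
    if (is.null(b)) {
      if (!is.null(node$ports[[pn]]$default)) out[[pn]] <- node$ports[[pn]]$default
      next
    }
    out[[pn]] <- switch(b$type,
      constant = b$value,
      fanout = b$value[[m]],
      future = {
        vals <- get(cache_key(b$node, b$port), envir = session$cache, inherits = FALSE)
        switch(b$mode,
          map = if (length(vals) == 1L) vals[[1L]] else vals[[m]],
          broadcast = vals[[1L]],
          gather = simplify_members(vals)
        )
      }
    )
  }
  out
}

simplify_members <- function(vals) {
  if (all(vapply(vals, function(v) is.atomic(v) && length(v) == 1L &&
                 is.null(attr(v, "class")), logical(1))) &&
      length(unique(vapply(vals, typeof, character(1)))) <= 1L) {
    unlist(vals, use.names = FALSE)
  } else vals
}

check_outputs <- function(node, member, res) {
  decl <- node$spec$outputs
  if (!is.list(res) || is.null(names(res))) {
    wg_error("wg_output_kind_violation",
             sprintf("node '%s' runner must return a named list", node$node_id))
  }
  undeclared <- setdiff(names(res), names(decl))
  if (length(undeclared)) {
    wg_error("wg_undeclared_output_written",
             sprintf("node '%s' wrote undeclared output(s): %s", node$node_id,
                     paste(undeclared, collapse = ", ")))
  }
  missing <- setdiff(names(decl), names(res))
  if (length(missing)) {
    wg_error("wg_declared_output_never_assigned",
             sprintf("node '%s' (member %d) never assigned declared output(s): %s",
                     node$node_id, member - 1L, paste(missing, collapse = ", ")))
  }
  for (pn in names(decl)) {
    if (!value_conforms(res[[pn]], decl[[pn]]$kind)) {
      wg_error("wg_output_kind_violation",
               sprintf("node '%s' output '%s' does not conform to kind %s",
                       node$node_id, pn, format(decl[[pn]]$kind)))
    }
  }
  res
}

execute_node <- function(session, node_id) {
  if (exists(node_id, envir = session$done, inherits = FALSE)) return(invisible())
  node <- session$graph$nodes[[node_id]]
  spec <- node$spec
  n <- node$width
  per_member <- lapply(seq_len(n), function(m) localize_inputs(session, node, m))
  t0 <- proc.time()[["elapsed"]]
  results <- withCallingHandlers(
    {
      if (!is.null(spec$ensemble_runner)) {
        res <- spec$ensemble_runner(per_member, session, node)
        lapply(seq_len(n), function(m) check_outputs(node, m, res[[m]]))
      } else {
        lapply(seq_len(n), function(m) {
          check_outputs(node, m, spec$runner(per_member[[m]], m, session, node))
        })
      }
    },
    error = function(e) {
      if (!inherits(e, "wg_located")) {
        keep <- setdiff(class(e), c("simpleError", "error", "condition",
                                    "wg_error", "rlang_error"))
        wg_error(c("wg_upstream_failure", keep, "wg_located"),
                 sprintf("node '%s' failed: %s", node_id, conditionMessage(e)),
                 node_id = node_id)
      }
    }
  )
  wall <- proc.time()[["elapsed"]] - t0
  for (pn in names(spec$outputs)) {
    assign(cache_key(node_id, pn),
           lapply(results, `[[`, pn), envir = session$cache)
  }
  for (m in seq_len(n)) {
    record_execution(session, node_id, m, spec$op_name, wall / n,
                     argv = attr(results[[m]], "argv", exact = TRUE))
  }
  assign(node_id, TRUE, envir = session$done)
  invisible()
}

resolve_node <- function(session, node_id) {
  graph <- session$graph
  need <- ancestor_set(graph, node_id)
  order <- topological_order(graph)
  for (id in order[order %in% need]) {
    execute_node(session, id)
  }
  invisible()
}

#' Localize the value of a Future
#'
#' Forces dependency resolution: exactly the ancestors of the Future's
#' node execute (nodes outside that set stay pending), results are cached,
#' and the value is returned — a single value for width 1, a per-member
#' list (simplified to a vector for scalar kinds) for ensembles.
#'
#' @param future a `wg_future`, or a `wg_node` handle with a single output.
#' @return the localized value.
#' @export
result <- function(future) {
  if (inherits(future, "wg_node")) future <- ofuture(future)
  stopifnot(inherits(future, "wg_future"))
  session <- session_of(future$graph)
  key <- cache_key(future$node_id, future$port)
  if (!exists(key, envir = session$cache, inherits = FALSE)) {
    resolve_node(session, future$node_id)
  }
  vals <- get(key, envir = session$cache, inherits = FALSE)
  if (future$width == 1L) vals[[1L]] else simplify_members(vals)
}

#' Resolve every output of a node
#'
#' Convenience wrapper over [result()] applied to each output port.
#'
#' @param handle a `wg_node` handle.
#' @return named list of localized outputs (invisibly also marks the node
#'   done in the session log).
#' @export
run <- function(handle) {
  if (inherits(handle, "wg_future")) {
    handle <- node_handle(handle$graph, handle$node_id)
  }
  stopifnot(inherits(handle, "wg_node"))
  out <- lapply(names(handle$spec$outputs), function(p) result(ofuture(handle, p)))
  stats::setNames(out, names(handle$spec$outputs))
}
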