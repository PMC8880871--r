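#' @title User-defined operations
#' @description
#' [function_wrapper()] transforms an arbitrary user procedure into a
#' graph operation with declared outputs. Input ports are inferred from
#' the procedure's named parameters (parameters with defaults become
#' optional ports); input kinds are inferred from the values bound at
#' graph-build time. Wrapped procedures are assumed uncoupled across
#' ensemble members and are invoked exactly once per (node, member); the
#' executor caches results, so repeated resolution never re-invokes.
#'
#' Two assignment styles are supported: a single-output procedure may
#' simply return the value; a multi-output procedure receives an
#' assignment handle as a parameter named `output` and sets
#' `output$name <- value` for each declared output. Writing an undeclared
#' name, or never assigning a declared one, is an error at resolution
#' time.
#'
#' Reserved parameter name: `.session` — a wrapped procedure declaring it
#' receives per-task execution context (`workdir`, `member` 0-based,
#' `node_id`, `seed`) instead of a data port. This is how factory-made
#' operations (including the command-line wrapper) manage per-task
#' working directories.
#' @name operation_factory
NULL

.wrap_counter <- new.env(parent = emptyenv())
.wrap_counter$n <- 0L

#' Create an operation factory from a user procedure
#'
#' @param output_decl named list: output name -> [wg_kind()]. Must be
#'   non-empty.
#' @param name operation name for the registry and for node ids; defaults
#'   to a generated `wrapped_fn-<k>`.
#' @return a factory: `factory(procedure)` returns an operation
#'   constructor; calling the constructor with input bindings (constants,
#'   Futures, or bare lists/vectors for ensemble fan-out) adds a node to
#'   the active graph and returns its handle. Use [ofuture()] (or
#'   [result()] on the handle for single-output operations) to access
#'   outputs.
#' @examples
#' \dontrun{
#' plus_one <- function_wrapper(list(sum = k_integer()))(
#'   function(x) x + 1L
#' )
#' h <- plus_one(x = 1L)
#' result(h)  # 2
#' }
#' @export
function_wrapper <- function(output_decl, name = NULL) {
  if (length(output_decl) == 0L || is.null(names(output_decl))) {
    wg_error("wg_invalid_spec", "output_decl must be a non-empty named list of kinds")
  }
  for (k in output_decl) stopifnot(inherits(k, "wg_kind"))
  function(procedure) {
    stopifnot(is.function(procedure))
    fmls <- names(formals(procedure))
    if ("output" %in% fmls && length(output_decl) == 1L) {
      # allowed: explicit handle style even for one output
    }
    data_ports <- setdiff(fmls, c("output", ".session"))
    if (any(data_ports == "...")) {
      wg_error("wg_invalid_spec", "wrapped procedures may not use '...'")
    }
    op_name <- name
    if (is.null(op_name)) {
      .wrap_counter$n <- .wrap_counter$n + 1L
      op_name <- sprintf("wrapped_fn-%d", .wrap_counter$n)
    }
    inputs <- lapply(data_ports, function(pn) {
      has_default <- !identical(formals(procedure)[[pn]], quote(expr = ))
      port_spec(pn, k_any(), required = !has_default,
                default = if (has_default) eval(formals(procedure)[[pn]]) else NULL)
    })
    outputs <- lapply(names(output_decl), function(on) port_spec(on, output_decl[[on]]))
    uses_handle <- "output" %in% fmls
    uses_session <- ".session" %in% fmls
    spec <- operation_spec(
      op_name, inputs = inputs, outputs = outputs,
      category = "external_process", deterministic = FALSE, wrapped = TRUE,
      runner = function(inputs, member, session, node) {
        args <- inputs[names(inputs) %in% data_ports]
        handle_env <- new.env(parent = emptyenv())
        if (uses_handle) args$output <- handle_env
        if (uses_session) {
          args$.session <- list(
            workdir = task_dir(session, node$node_id, member),
            member = member - 1L, node_id = node$node_id,
            seed = member_seed(session, node$node_id, member)
          )
        }
        ret <- tryCatch(do.call(procedure, args), error = function(e) {
          if (inherits(e, "wg_located")) stop(e)
          keep <- setdiff(class(e), c("simpleError", "error", "condition",
                                      "wg_error", "rlang_error"))
          wg_error(c("wg_procedure_raised", keep, "wg_located"),
                   sprintf("procedure of node '%s' (member %d) raised: %s",
                           node$node_id, member - 1L, conditionMessage(e)),
                   node_id = node$node_id, member = member - 1L)
        })
        res <- as.list(handle_env)
        if (!uses_handle || (length(output_decl) == 1L && length(res) == 0L)) {
          res <- stats::setNames(list(ret), names(output_decl)[1L])
        }
        res
      }
    )
    register_operation(spec, overwrite = TRUE)
    function(..., graph = active_graph()) {
      add_node(graph, spec, list(...))
    }
  }
}
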