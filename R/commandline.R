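#' @title Wrapping external command-line tools
#' @description
#' Legacy tools become graph operations in two layers. [cli()] is the raw
#' primitive: it runs one child process to completion in a fresh working
#' directory and captures return code, stdout and stderr — a nonzero exit
#' status is *data* (downstream logic may branch on it), not an error.
#' [commandline_operation()] builds a graph node around `cli` (through
#' the [function_wrapper()] factory): declared input files become
#' dependencies so tool chains sequence correctly, declared outputs are
#' resolved inside the task's working directory and exposed as
#' `file.<flag>` Futures, and passing a list of values for an input fans
#' the command out into an ensemble.
#' @name commandline
NULL

#' Run a child process (raw primitive)
#'
#' No shell interpretation: `command` is an argument vector, not a shell
#' line. The process runs in `workdir` (fresh temporary directory by
#' default). If `command[1]` names a file that exists but is not
#' executable, it is run through `/bin/sh` (install steps do not reliably
#' preserve execute bits on bundled scripts).
#'
#' @param command character vector; `command[1]` is the executable.
#' @param stdin optional text fed to the child's standard input.
#' @param workdir working directory for the child.
#' @return a `CommandResult`: list with `returncode`, `stdout`, `stderr`,
#'   `file` (named list, filled by [commandline_operation()]).
#' @export
cli <- function(command, stdin = NULL, workdir = tempfile("cli-")) {
  command <- as.character(command)
  if (length(command) == 0L || !nzchar(command[1L])) {
    wg_error("wg_executable_not_found", "empty command")
  }
  exe <- command[1L]
  args <- command[-1L]
  resolved <- Sys.which(exe)
  if (!nzchar(resolved)) {
    if (file.exists(exe)) {
      args <- c(normalizePath(exe), args)
      resolved <- Sys.which("sh")
    } else {
      wg_error("wg_executable_not_found",
               sprintf("executable not found: '%s'", exe))
    }
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- file.path(workdir, ".stdout")
  errfile <- file.path(workdir, ".stderr")
  old <- setwd(workdir)
  on.exit(setwd(old), add = TRUE)
  status <- tryCatch(
    suppressWarnings(system2(resolved, args = shQuote(args),
                             stdout = outfile, stderr = errfile,
                             input = stdin)),
    error = function(e) wg_error("wg_spawn_failure",
                                 sprintf("failed to spawn '%s': %s", exe,
                                         conditionMessage(e)))
  )
  read_txt <- function(p) {
    if (!file.exists(p)) return("")
    # decoded as UTF-8 with replacement: robustness over fidelity
    raw <- readBin(p, "raw", file.info(p)$size)
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
    iconv(txt, "UTF-8", "UTF-8", sub = "�")
  }
  list(returncode = as.integer(status), stdout = read_txt(outfile),
       stderr = read_txt(errfile), file = list())
}

render_file_args <- function(files, values) {
  # flags rendered in insertion order; an entry with a NULL value renders
  # as the bare flag
  out <- character(0)
  for (flag in names(files)) {
    v <- values[[flag]]
    out <- c(out, flag, if (!is.null(v)) as.character(v))
  }
  out
}

#' Wrap a command-line tool as a graph operation
#'
#' The rendered argument list is `executable + arguments + input flags +
#' output flags`, each flag followed by its (resolved) path. Input file
#' values may be paths, `file_path` Futures (creating dependencies on the
#' producing nodes), or bare lists of either for ensemble fan-out.
#' Declared output paths must be relative; they are created inside the
#' per-(node, member) working directory `<workdir>/<node_id>/<member>/`.
#' A declared output missing after a zero return code is an error
#' (fail-fast data-flow integrity); a nonzero return code is data.
#'
#' @param executable program name or path.
#' @param arguments extra fixed arguments (character vector).
#' @param input_files named list: flag -> path, Future, or list (fan-out).
#' @param output_files named list: flag -> relative output path.
#' @param stdin optional text (or text Future) for standard input.
#' @param name operation name used for node ids (default
#'   `"commandline_operation"`).
#' @param graph target graph.
#' @return `wg_node` handle with outputs `returncode`, `stdout`,
#'   `stderr`, and one `file.<flag>` per declared output.
#' @export
commandline_operation <- function(executable, arguments = character(),
                                  input_files = list(), output_files = list(),
                                  stdin = NULL, name = "commandline_operation",
                                  graph = active_graph()) {
  for (p in unlist(output_files)) {
    if (grepl("^/", p)) {
      wg_error("wg_invalid_spec",
               sprintf("declared output path must be relative: '%s'", p))
    }
  }
  in_flags <- names(input_files)
  out_flags <- names(output_files)
  port_of_flag <- function(flag) gsub("[^A-Za-z0-9]", "_", flag)
  in_ports <- vapply(in_flags, function(f) paste0("infile_", port_of_flag(f)),
                     character(1))
  output_decl <- c(
    list(returncode = k_integer(), stdout = k_text(), stderr = k_text()),
    stats::setNames(lapply(out_flags, function(f) k_file()),
                    paste0("file.", out_flags))
  )

  # the wrapped procedure: built dynamically so each declared input file
  # is a named parameter (hence a typed input port / dependency edge)
  arg_names <- c(in_ports, if (!is.null(stdin)) "stdin_text", ".session", "output")
  proc_body <- function(bound, session_ctx, output) {
    wd <- session_ctx$workdir
    in_vals <- stats::setNames(lapply(seq_along(in_flags), function(i) {
      normalizePath(as.character(bound[[in_ports[[i]]]]), mustWork = FALSE)
    }), in_flags)
    out_vals <- stats::setNames(lapply(out_flags, function(f) {
      file.path(wd, output_files[[f]])
    }), out_flags)
    argv <- c(executable, as.character(arguments),
              render_file_args(input_files, in_vals),
              render_file_args(output_files, out_vals))
    res <- cli(argv, stdin = bound$stdin_text, workdir = wd)
    if (res$returncode == 0L) {
      for (f in out_flags) {
        if (!file.exists(out_vals[[f]])) {
          wg_error("wg_missing_declared_output",
                   sprintf("command succeeded but declared output '%s' (%s) was not created",
                           f, out_vals[[f]]))
        }
      }
    }
    output$returncode <- res$returncode
    output$stdout <- res$stdout
    output$stderr <- res$stderr
    for (f in out_flags) {
      assign(paste0("file.", f), out_vals[[f]], envir = output)
    }
    invisible(NULL)
  }
  fml <- c(stats::setNames(rep(list(quote(expr = )), length(arg_names)), arg_names))
  procedure <- as.function(c(fml, quote({})))
  body(procedure) <- bquote({
    bound <- mget(.(in_ports), ifnotfound = list(NULL))
    if (.(!is.null(stdin))) bound$stdin_text <- stdin_text
    proc_body(bound, .session, output)
  })
  environment(procedure) <- environment()

  factory <- function_wrapper(output_decl, name = name)
  op <- factory(procedure)
  bindings <- stats::setNames(lapply(seq_along(in_flags), function(i) {
    v <- input_files[[i]]
    if (inherits(v, "wg_node")) ofuture(v) else v
  }), in_ports)
  if (!is.null(stdin)) bindings$stdin_text <- stdin
  do.call(op, c(bindings, list(graph = graph)))
}

#' Future for a declared output file of a command node
#'
#' @param handle handle from [commandline_operation()].
#' @param flag the output flag used in `output_files`.
#' @return `file_path` Future.
#' @export
output_file <- function(handle, flag) ofuture(handle, paste0("file.", flag))

#' Bundled fixture scripts
#'
#' Portable POSIX `sh` shims shipped with the package so tests and demos
#' never depend on platform tool behaviour:
#' \describe{
#'   \item{emit}{prints its first argument to stdout; exits 0.}
#'   \item{copy}{`-i SRC -o DST`: copies SRC to DST byte-for-byte.}
#'   \item{fail}{exits with status 3 after printing a message to stderr.}
#'   \item{concat}{`-a A -b B -o OUT`: concatenates files A and B into OUT.}
#' }
#'
#' @param which one of `"emit"`, `"copy"`, `"fail"`, `"concat"`.
#' @return path to the installed script.
#' @export
fixture_script <- function(which = c("emit", "copy", "fail", "concat")) {
  which <- match.arg(which)
  p <- system.file("exec", which, package = "flowmd")
  if (!nzchar(p)) wg_error("wg_executable_not_found",
                           sprintf("fixture script '%s' not installed", which))
  p
}
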