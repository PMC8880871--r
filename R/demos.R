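#' @title Executable demo workflows
#' @description
#' Desk-scale, seeded workflows that double as documentation and
#' integration tests: ensemble fan-out over an array of inputs, adaptive
#' iteration with a while loop over an ensemble simulation, a
#' command-line tool chain feeding a simulation, and a restrained-
#' ensemble refinement in which members sample their restraint targets
#' from a distance distribution. Each demo is deterministic under its
#' seed and completes in seconds on one CPU.
#' @name demos
NULL

demo_base_input <- function(nsteps = 200L) {
  make_dimer(1.2, 1, 1,
             params = sim_params(dt = 0.005, nsteps = nsteps,
                                 friction_gamma = 0, output_interval = 10L))
}

#' Ensemble fan-out demo
#'
#' Builds `read_input -> modify_input(seed array) -> mdrun`: one chain of
#' three nodes whose seed array fans the simulation out into
#' `n_members` trajectories.
#'
#' @param n_members ensemble width.
#' @param seeds integer vector of member seeds (default `1..n_members`).
#' @param workdir session working-directory root.
#' @return list with `trajectories` (file paths), `graph`, `session`,
#'   and the `mdrun` handle.
#' @export
demo_ensemble_fanout <- function(n_members, seeds = seq_len(n_members),
                                 workdir = tempfile("demo-fanout-")) {
  stopifnot(length(seeds) == n_members)
  g <- work_graph(activate = FALSE)
  input_file <- tempfile(fileext = ".json")
  write_input(demo_base_input(), input_file)
  h_read <- read_input(input_file, graph = g)
  h_mod <- modify_input(h_read, list("params.seed" = as.integer(seeds)), graph = g)
  h_md <- mdrun(h_mod, graph = g)
  s <- new_session(g, workdir = workdir)
  trajs <- result(ofuture(h_md, "trajectory_file"))
  if (n_members == 1L) trajs <- list(trajs)
  stopifnot(all(file.exists(unlist(trajs))))
  list(trajectories = unlist(trajs), graph = g, session = s, mdrun = h_md)
}

#' Adaptive while-loop demo
#'
#' An ensemble simulation segment runs inside a [while_loop()] whose
#' condition is the negation of "any member converged": iteration
#' continues, propagating each member's final coordinates into the next
#' segment, until at least one member's restraint stop signal fires or
#' `max_iteration` is reached.
#'
#' @param n_members ensemble width.
#' @param stop_tolerance restraint stop window (reduced units).
#' @param target restraint target distance.
#' @param max_iteration loop guard.
#' @param nsteps_segment steps per loop iteration.
#' @param workdir session working-directory root.
#' @return list with `iterations_run`, `converged` (per member),
#'   `final_inputs`, `graph`, `session`.
#' @export
demo_adaptive_loop <- function(n_members = 2L, stop_tolerance = 0.1,
                               target = 1.5, max_iteration = 10L,
                               nsteps_segment = 200L,
                               workdir = tempfile("demo-loop-")) {
  g <- work_graph(activate = FALSE)
  base <- make_dimer(1.0, 1, 1,
                     params = sim_params(dt = 0.005, nsteps = nsteps_segment,
                                         friction_gamma = 1,
                                         output_interval = 20L))
  inputs0 <- lapply(seq_len(n_members), function(m) {
    modified <- base
    modified$params$seed <- m
    modified
  })
  plugin <- restraint_plugin(c(1L, 2L), k_restraint = 5, target = target,
                             stop_tolerance = stop_tolerance,
                             stop_scope = "member")
  sg <- subgraph(
    variables = list(
      input = list(kind = k_data(), initial = inputs0),
      converged = list(kind = k_boolean(), initial = rep(FALSE, n_members))
    ),
    body = function(v) {
      gg <- v$input$graph
      h <- mdrun(v$input, plugins = list(plugin), graph = gg)
      list(input = ofuture(h, "final_input"), converged = ofuture(h, "converged"))
    }
  )
  loop <- while_loop(sg, condition = function(state) !ensemble_any(state$converged),
                     max_iteration = max_iteration, graph = g)
  s <- new_session(g, workdir = workdir)
  iters <- result(ofuture(loop, "iterations_run"))
  conv <- result(ofuture(loop, "converged"))
  finals <- result(ofuture(loop, "input"))
  list(iterations_run = iters, converged = unlist(conv),
       final_inputs = finals, graph = g, session = s)
}

#' Command-line tool-chain demo
#'
#' A run-input file is split into two fragments; a chain of wrapped
#' fixture tools (`concat` then `copy`) reassembles it, the result feeds
#' `read_input -> mdrun`, and the file Futures force the tools to execute
#' in dependency order.
#'
#' @param workdir session working-directory root.
#' @param nsteps simulation length.
#' @return list with `trajectory`, `log` (executed-node data frame),
#'   `graph`, `session`.
#' @export
demo_tool_chain <- function(workdir = tempfile("demo-chain-"), nsteps = 100L) {
  g <- work_graph(activate = FALSE)
  full <- tempfile(fileext = ".json")
  write_input(demo_base_input(nsteps = nsteps), full)
  txt <- readChar(full, file.info(full)$size)
  cut <- nchar(txt) %/% 2L
  frag_a <- tempfile(fileext = ".a"); frag_b <- tempfile(fileext = ".b")
  writeChar(substr(txt, 1L, cut), frag_a, eos = NULL)
  writeChar(substr(txt, cut + 1L, nchar(txt)), frag_b, eos = NULL)
  h_concat <- commandline_operation(
    fixture_script("concat"),
    input_files = list("-a" = frag_a, "-b" = frag_b),
    output_files = list("-o" = "joined.json"),
    name = "concat_fragments", graph = g
  )
  h_copy <- commandline_operation(
    fixture_script("copy"),
    input_files = list("-i" = output_file(h_concat, "-o")),
    output_files = list("-o" = "input.json"),
    name = "copy_into_place", graph = g
  )
  h_read <- read_input(output_file(h_copy, "-o"), graph = g)
  h_md <- mdrun(h_read, graph = g)
  s <- new_session(g, workdir = workdir)
  traj <- result(ofuture(h_md, "trajectory_file"))
  list(trajectory = traj, log = execution_log(s), graph = g, session = s,
       nodes = list(concat = h_concat, copy = h_copy, read = h_read, md = h_md))
}

#' Restrained-ensemble refinement demo
#'
#' Each ensemble member draws a restraint target from a Gaussian-mixture
#' distance distribution and runs damped dynamics under a stiff pair
#' restraint until its distance enters the stop window around its
#' target. The summary reports the final restrained distances and the
#' Kolmogorov-Smirnov distance between their empirical distribution and
#' the target mixture — small KS distance means the ensemble reproduces
#' the measured distribution.
#'
#' @param mixture a [mixture_spec()]; default two components at 3.0 and
#'   5.0 (sd 0.3, equal weight), a typical bimodal pair-distance shape.
#' @param n_members ensemble size.
#' @param base_input starting `toy_input` (default: a unit dimer with
#'   damped-dynamics parameters).
#' @param seed integer seed for target sampling and member velocity
#'   streams.
#' @param k_restraint restraint stiffness (default 100; stiff relative to
#'   the bond so the restrained minimum sits within the stop window).
#' @param stop_tolerance stop window half-width (default 0.02).
#' @param workdir session working-directory root.
#' @return list with `final_distances`, `targets`, `ks_distance`,
#'   `ks_critical_5pct` (asymptotic, `1.3581/sqrt(n)`), `converged`,
#'   `session`.
#' @export
restrained_ensemble_demo <- function(mixture = mixture_spec(c(0.5, 0.5), c(3, 5), c(0.3, 0.3)),
                                     n_members = 64L,
                                     base_input = NULL, seed = 1L,
                                     k_restraint = 100, stop_tolerance = 0.02,
                                     workdir = tempfile("demo-re-")) {
  stopifnot(n_members >= 1L)
  if (is.null(base_input)) {
    base_input <- make_dimer(1.0, 1, 1,
                             params = sim_params(dt = 0.005, nsteps = 4000L,
                                                 friction_gamma = 1,
                                                 output_interval = 20L))
  }
  targets <- sample_mixture(mixture, n_members, seed = seed)
  targets <- pmax(targets, 0.1)  # distances are positive
  g <- work_graph(activate = FALSE)
  h0 <- const_node(g, base_input, k_data())
  seeds <- as.integer((as.integer(seed) + seq_len(n_members)) %% 2147483L + 1L)
  h_mod <- modify_input(ofuture(h0), list("params.seed" = seeds), graph = g)
  plugin <- restraint_plugin(c(1L, 2L), k_restraint = k_restraint,
                             target = targets, stop_tolerance = stop_tolerance,
                             stop_scope = "member", reduce_mode = "none")
  h_md <- mdrun(h_mod, plugins = list(plugin), graph = g)
  s <- new_session(g, workdir = workdir, seed = as.integer(seed))
  finals <- result(ofuture(h_md, "final_system"))
  if (n_members == 1L) finals <- list(finals)
  d <- vapply(finals, function(sys) pair_distance(sys$positions, c(1L, 2L)), numeric(1))
  conv <- unlist(result(ofuture(h_md, "converged")))
  ks <- suppressWarnings(stats::ks.test(d, function(q) pmixture(q, mixture)))
  list(final_distances = d, targets = targets,
       ks_distance = unname(ks$statistic),
       ks_critical_5pct = 1.3581 / sqrt(n_members),
       converged = conv, session = s)
}
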