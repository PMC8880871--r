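#' @title Toy molecular-dynamics engine
#' @description
#' A deliberately minimal MD engine standing in for a production
#' simulation code: particles with harmonic bonds integrated by velocity
#' Verlet in reduced units (mass, length and time dimensionless). It
#' exists to exercise the workflow engine's runtime extension contract —
#' restraint plugins evaluated inside the integration loop, stop signals
#' with member or ensemble scope, and barrier-style ensemble reductions —
#' not to do chemistry: there are no nonbonded interactions, neighbour
#' lists, periodic boundaries or constraints.
#'
#' Friction (`friction_gamma`) is a deterministic damping force
#' `-gamma * m * v`, not a Langevin thermostat: there are no random
#' kicks, so the relaxed state of a bonded+restrained pair sits exactly
#' at the minimum of the summed quadratic potentials, which keeps
#' closed-form checks exact.
#' @name toymd
NULL

#' Construct a toy particle system
#'
#' @param masses numeric vector (> 0), one per particle.
#' @param positions n x 3 numeric matrix.
#' @param velocities n x 3 numeric matrix (default zeros).
#' @param bonds data frame with columns `i`, `j` (1-based particle
#'   indices, `i != j`), `k` (force constant >= 0) and `r0` (rest
#'   length > 0). Harmonic: V = k/2 (|r_ij| - r0)^2.
#' @return a `toy_system`.
#' @export
toy_system <- function(masses, positions, velocities = NULL, bonds = NULL) {
  positions <- as.matrix(positions)
  n <- length(masses)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          k = numeric(0), r0 = numeric(0))
  sys <- structure(list(n_particles = n, masses = as.numeric(masses),
                        positions = positions, velocities = velocities,
                        bonds = as.data.frame(bonds)),
                   class = "toy_system")
  validate_system(sys)
  sys
}

validate_system <- function(sys) {
  n <- sys$n_particles
  if (n < 1L) wg_error("wg_invariant_violation", "system.masses: at least one particle required")
  bad <- which(!is.finite(sys$masses) | sys$masses <= 0)
  if (length(bad)) {
    wg_error("wg_invariant_violation",
             sprintf("system.masses[%d]: mass must be > 0", bad[1L]))
  }
  if (!identical(dim(sys$positions), c(n, 3L)) && !identical(dim(sys$positions), as.integer(c(n, 3)))) {
    wg_error("wg_invariant_violation", "system.positions: must be n_particles x 3")
  }
  if (!all(dim(sys$velocities) == c(n, 3))) {
    wg_error("wg_invariant_violation", "system.velocities: must be n_particles x 3")
  }
  b <- sys$bonds
  req <- c("i", "j", "k", "r0")
  if (!all(req %in% names(b))) {
    wg_error("wg_invariant_violation", "system.bonds: columns i, j, k, r0 required")
  }
  for (r in seq_len(nrow(b))) {
    if (b$i[r] == b$j[r]) {
      wg_error("wg_invariant_violation", sprintf("system.bonds[%d]: i must differ from j", r))
    }
    if (b$i[r] < 1 || b$i[r] > n || b$j[r] < 1 || b$j[r] > n) {
      wg_error("wg_invariant_violation", sprintf("system.bonds[%d]: index out of range", r))
    }
    if (b$k[r] < 0) {
      wg_error("wg_invariant_violation", sprintf("system.bonds[%d].k: must be >= 0", r))
    }
    if (b$r0[r] <= 0) {
      wg_error("wg_invariant_violation", sprintf("system.bonds[%d].r0: must be > 0", r))
    }
  }
  invisible(sys)
}

#' Integrator parameters
#'
#' @param dt time step (> 0, reduced units).
#' @param nsteps number of steps (>= 0).
#' @param friction_gamma deterministic damping coefficient (>= 0).
#' @param output_interval frames/reduce epochs every this many steps (>= 1).
#' @param seed integer; 0 keeps the input velocities, > 0 draws small
#'   Gaussian initial velocities (sd 0.05) so ensemble members fanned out
#'   over seeds follow distinct trajectories.
#' @return a `toy_params`.
#' @export
sim_params <- function(dt = 0.001, nsteps = 10000L, friction_gamma = 0,
                       output_interval = 10L, seed = 0L) {
  p <- structure(list(dt = as.numeric(dt), nsteps = as.integer(nsteps),
                      friction_gamma = as.numeric(friction_gamma),
                      output_interval = as.integer(output_interval),
                      seed = as.integer(seed)),
                 class = "toy_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!is.finite(p$dt) || p$dt <= 0) {
    wg_error("wg_invariant_violation", "params.dt: must be > 0")
  }
  if (is.na(p$nsteps) || p$nsteps < 0L) {
    wg_error("wg_invariant_violation", "params.nsteps: must be >= 0")
  }
  if (!is.finite(p$friction_gamma) || p$friction_gamma < 0) {
    wg_error("wg_invariant_violation", "params.friction_gamma: must be >= 0")
  }
  if (is.na(p$output_interval) || p$output_interval < 1L) {
    wg_error("wg_invariant_violation", "params.output_interval: must be >= 1")
  }
  invisible(p)
}

#' Bundle a system and parameters as one run input
#'
#' The analog of a prepared run-input file: everything a single
#' simulation needs.
#'
#' @param system a [toy_system()].
#' @param params a [sim_params()].
#' @return a `toy_input`.
#' @export
simulation_input <- function(system, params = sim_params()) {
  stopifnot(inherits(system, "toy_system"), inherits(params, "toy_params"))
  structure(list(system = system, params = params), class = "toy_input")
}

#' @export
print.toy_input <- function(x, ...) {
  cat(sprintf("<simulation input: %d particles, %d bonds, %d steps @ dt=%g>\n",
              x$system$n_particles, nrow(x$system$bonds),
              x$params$nsteps, x$params$dt))
  invisible(x)
}

#' Read / write run-input files
#'
#' JSON schema: top-level `system` (`masses`, `positions`, `velocities`,
#' `bonds` as a list of `{i, j, k, r0}` rows) and `params` (`dt`,
#' `nsteps`, `friction_gamma`, `output_interval`, `seed`). Writing then
#' reading is the identity.
#'
#' @param path file path.
#' @return [read_input_file()]: a `toy_input`; [write_input()]: the path,
#'   invisibly.
#' @export
read_input_file <- function(path) {
  if (!file.exists(path)) {
    wg_error("wg_malformed_input", sprintf("input file does not exist: '%s'", path))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) wg_error("wg_malformed_input",
                                               sprintf("not valid JSON: %s", conditionMessage(e))))
  if (is.null(doc$system) || is.null(doc$params)) {
    wg_error("wg_malformed_input", "document must have 'system' and 'params' keys")
  }
  sysd <- doc$system
  as_coords <- function(x) {
    # jsonlite may simplify a list of 3-vectors to a matrix already
    if (is.matrix(x)) matrix(as.numeric(x), nrow = nrow(x))
    else matrix(as.numeric(unlist(x)), ncol = 3, byrow = TRUE)
  }
  pos <- as_coords(sysd$positions)
  vel <- if (is.null(sysd$velocities)) NULL else as_coords(sysd$velocities)
  bonds <- if (is.null(sysd$bonds) || length(sysd$bonds) == 0L) NULL else {
    as.data.frame(sysd$bonds)
  }
  sys <- toy_system(as.numeric(sysd$masses), pos, vel, bonds)
  p <- doc$params
  params <- sim_params(p$dt, p$nsteps, p$friction_gamma %||% 0,
                       p$output_interval %||% 10L, p$seed %||% 0L)
  simulation_input(sys, params)
}

#' @rdname read_input_file
#' @param input a `toy_input`.
#' @export
write_input <- function(input, path) {
  stopifnot(inherits(input, "toy_input"))
  sys <- input$system
  doc <- list(
    system = list(
      masses = sys$masses,
      positions = lapply(seq_len(sys$n_particles), function(i) unname(sys$positions[i, ])),
      velocities = lapply(seq_len(sys$n_particles), function(i) unname(sys$velocities[i, ])),
      bonds = lapply(seq_len(nrow(sys$bonds)), function(r) {
        list(i = sys$bonds$i[r], j = sys$bonds$j[r],
             k = sys$bonds$k[r], r0 = sys$bonds$r0[r])
      })
    ),
    params = unclass(input$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Graph operation: read a run-input file
#'
#' Pure and cached; the path may be a `file_path` Future (e.g. the
#' declared output of a wrapped command-line tool), which makes the file
#' producer an upstream dependency.
#'
#' @param path file path or Future.
#' @param graph target graph.
#' @return `wg_node` handle with output `simulation_input`.
#' @export
read_input <- function(path, graph = active_graph()) {
  if (inherits(path, "wg_node")) path <- ofuture(path)
  add_node(graph, read_input_spec(), list(path = path))
}

read_input_spec <- function() {
  operation_spec(
    "read_input",
    inputs = list(port_spec("path", k_file())),
    outputs = list(port_spec("simulation_input", k_data())),
    category = "pure",
    runner = function(inputs, member, session, node) {
      list(simulation_input = read_input_file(inputs$path))
    }
  )
}

input_paths <- c("params.dt", "params.nsteps", "params.friction_gamma",
                 "params.output_interval", "params.seed")

apply_overrides <- function(input, overrides) {
  sys <- input$system
  par <- unclass(input$params)
  for (pth in names(overrides)) {
    v <- overrides[[pth]]
    if (pth %in% input_paths) {
      key <- sub("^params\\.", "", pth)
      par[[key]] <- v
    } else if (pth == "system.positions") {
      sys$positions <- as.matrix(v)
    } else if (pth == "system.velocities") {
      sys$velocities <- as.matrix(v)
    } else if (pth == "system.masses") {
      sys$masses <- as.numeric(v)
    } else {
      wg_error("wg_unknown_parameter_path",
               sprintf("unknown parameter path '%s'", pth))
    }
  }
  params <- tryCatch(
    sim_params(par$dt, par$nsteps, par$friction_gamma, par$output_interval, par$seed),
    error = function(e) {
      if (inherits(e, "wg_invariant_violation")) stop(e)
      wg_error("wg_kind_mismatch", conditionMessage(e))
    }
  )
  sys2 <- toy_system(sys$masses, sys$positions, sys$velocities, sys$bonds)
  simulation_input(sys2, params)
}

#' Graph operation: derive a modified run input
#'
#' Produces a new input differing only at the overridden parameter paths;
#' the original is untouched, which is what makes forked trajectories
#' safe. Passing a vector of values for a scalar `params.*` path fans the
#' node out into an ensemble of inputs (one per value).
#'
#' @param input `toy_input`, or Future of one.
#' @param overrides named list, parameter path -> value, e.g.
#'   `list("params.nsteps" = 100L)` or `list("params.seed" = c(1L, 2L, 3L))`.
#' @param graph target graph.
#' @return `wg_node` handle with output `simulation_input` (width = the
#'   fan-out length when any override is a vector).
#' @export
modify_input <- function(input, overrides, graph = active_graph()) {
  stopifnot(is.list(overrides), !is.null(names(overrides)))
  for (pth in names(overrides)) {
    if (!pth %in% c(input_paths, "system.positions", "system.velocities", "system.masses")) {
      wg_error("wg_unknown_parameter_path", sprintf("unknown parameter path '%s'", pth))
    }
  }
  lens <- vapply(names(overrides), function(pth) {
    if (pth %in% input_paths) length(overrides[[pth]]) else 1L
  }, integer(1))
  n <- infer_width(lens)
  per_member <- lapply(seq_len(n), function(m) {
    ov <- overrides
    for (pth in names(ov)) {
      if (pth %in% input_paths && length(ov[[pth]]) > 1L) ov[[pth]] <- ov[[pth]][[m]]
    }
    ov
  })
  spec <- modify_input_spec()
  if (inherits(input, "wg_node")) input <- ofuture(input)
  ov_value <- lapply(per_member, function(o) structure(o, class = "toy_overrides"))
  add_node(graph, spec, list(input = input, overrides = ov_value))
}

modify_input_spec <- function() {
  operation_spec(
    "modify_input",
    inputs = list(port_spec("input", k_data()),
                  port_spec("overrides", k_data(), required = FALSE)),
    outputs = list(port_spec("simulation_input", k_data())),
    category = "pure",
    runner = function(inputs, member, session, node) {
      list(simulation_input = apply_overrides(inputs$input, unclass(inputs$overrides)))
    }
  )
}

#' Bonded forces and potential energy
#'
#' Pairwise harmonic forces, equal and opposite per bond (so the total
#' force over all particles is exactly zero), with potential
#' `sum k/2 (|r| - r0)^2`. Coincident bonded particles are degenerate
#' (the force direction is undefined) and raise an error.
#'
#' @param system a `toy_system`.
#' @return list with `forces` (n x 3 matrix) and `potential` (scalar).
#' @export
bonded_forces <- function(system) {
  x <- system$positions
  f <- matrix(0, nrow(x), 3)
  pot <- 0
  b <- system$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- x[j, ] - x[i, ]
    rlen <- sqrt(sum(d * d))
    if (rlen == 0) {
      wg_error("wg_degenerate_geometry",
               sprintf("bond %d: particles %d and %d are coincident", r, i, j))
    }
    mag <- b$k[r] * (rlen - b$r0[r])
    fij <- mag * d / rlen   # force on i, toward j when stretched
    f[i, ] <- f[i, ] + fij
    f[j, ] <- f[j, ] - fij
    pot <- pot + 0.5 * b$k[r] * (rlen - b$r0[r])^2
  }
  list(forces = f, potential = pot)
}

#' Restraint plugin
#'
#' The runtime extension contract: plugin code evaluated inside the MD
#' integration loop. The built-in plugin applies a harmonic pair
#' restraint of magnitude `k_restraint * (d - target)`, may signal a stop
#' when `|d - target| < stop_tolerance` (0 disables stopping) with
#' `member` or `ensemble` scope, and may contribute the pair distance to
#' a barrier-style ensemble mean reduction every output interval
#' (`reduce_mode = "mean_distance"`). Honoured at the next step boundary:
#' stop latency is at most one step.
#'
#' Any field may be a vector of one value per ensemble member (e.g.
#' per-member targets drawn from a distance distribution).
#'
#' @param pair length-2 integer vector of particle indices.
#' @param k_restraint force constant (>= 0).
#' @param target target distance (> 0).
#' @param stop_tolerance see above; >= 0.
#' @param stop_scope `"member"` or `"ensemble"`.
#' @param reduce_mode `"none"` or `"mean_distance"`.
#' @return a `toy_plugin`.
#' @export
restraint_plugin <- function(pair, k_restraint, target, stop_tolerance = 0,
                             stop_scope = c("member", "ensemble"),
                             reduce_mode = c("none", "mean_distance")) {
  stop_scope <- if (length(stop_scope) > 2L || missing(stop_scope)) {
    match.arg(stop_scope)
  } else stop_scope
  if (!all(stop_scope %in% c("member", "ensemble"))) {
    wg_error("wg_invalid_spec", "stop_scope must be 'member' or 'ensemble'")
  }
  reduce_mode <- if (missing(reduce_mode)) match.arg(reduce_mode) else reduce_mode
  if (!all(reduce_mode %in% c("none", "mean_distance"))) {
    wg_error("wg_invalid_spec", "reduce_mode must be 'none' or 'mean_distance'")
  }
  stopifnot(length(pair) == 2L, all(k_restraint >= 0), all(target > 0),
            all(stop_tolerance >= 0))
  structure(list(pair = as.integer(pair), k_restraint = as.numeric(k_restraint),
                 target = as.numeric(target),
                 stop_tolerance = as.numeric(stop_tolerance),
                 stop_scope = stop_scope, reduce_mode = reduce_mode),
            class = "toy_plugin")
}

plugin_for_member <- function(p, m) {
  pick <- function(v) if (length(v) > 1L) v[[min(m, length(v))]] else v
  list(pair = p$pair, k_restraint = pick(p$k_restraint),
       target = pick(p$target), stop_tolerance = pick(p$stop_tolerance),
       stop_scope = pick(p$stop_scope), reduce_mode = pick(p$reduce_mode))
}

pair_distance <- function(x, pair) {
  d <- x[pair[2L], ] - x[pair[1L], ]
  sqrt(sum(d * d))
}

# Plugin force/potential contribution for one member at one step.
plugin_forces <- function(x, plugins) {
  f <- matrix(0, nrow(x), 3)
  pot <- 0
  for (p in plugins) {
    i <- p$pair[1L]; j <- p$pair[2L]
    d <- x[j, ] - x[i, ]
    rlen <- sqrt(sum(d * d))
    if (!is.finite(rlen)) {
      wg_error("wg_numeric_overflow",
               "non-finite restrained distance (time step too large?)")
    }
    if (rlen == 0) {
      wg_error("wg_degenerate_geometry", "restrained pair is coincident")
    }
    mag <- p$k_restraint * (rlen - p$target)
    fij <- mag * d / rlen
    f[i, ] <- f[i, ] + fij
    f[j, ] <- f[j, ] - fij
    pot <- pot + 0.5 * p$k_restraint * (rlen - p$target)^2
  }
  list(forces = f, potential = pot)
}

#' Graph operation: run toy molecular dynamics
#'
#' Velocity-Verlet integration: positions advance by
#' `v dt + f/(2m) dt^2`, velocities by the mean of old and new forces
#' times `dt/(2m)`; a damping force `-gamma m v` is added when
#' `friction_gamma > 0`. Plugin forces are evaluated inside the loop each
#' step. Ensemble inputs (width n) are co-executed: all members advance
#' in an interleaved (round-robin) stepping regime, every mean reduction
#' completes only when all members have contributed their value for the
#' same epoch, and an ensemble-scope stop raised by any member halts all
#' members at their next step boundary. A member calling reduce in a
#' different epoch pattern than the others (including a member that has
#' stopped while others still reduce) is an error.
#'
#' Outputs per member: `trajectory_file` (XYZ frames, with an
#' `energies.jsonl` side file in the same directory), `final_system`,
#' `final_input` (for seamless continuation/forking), `steps_run`,
#' `converged` (did *this member* signal a stop), `frames` (data frame:
#' step, time, potential_energy, kinetic_energy), and `reduce_trace`
#' (data frame: epoch, value, reduced).
#'
#' @param input `toy_input` or Future of one (ensemble fan-out upstream
#'   yields an ensemble of simulations).
#' @param plugins list of [restraint_plugin()]s.
#' @param graph target graph.
#' @return `wg_node` handle.
#' @export
mdrun <- function(input, plugins = list(), graph = active_graph()) {
  if (inherits(plugins, "toy_plugin")) plugins <- list(plugins)
  if (inherits(input, "wg_node")) input <- ofuture(input, "simulation_input")
  add_node(graph, mdrun_spec(), list(input = input),
           extras = list(plugins = plugins))
}

mdrun_spec <- function() {
  operation_spec(
    "mdrun",
    inputs = list(port_spec("input", k_data())),
    outputs = list(
      port_spec("trajectory_file", k_file()),
      port_spec("final_system", k_data()),
      port_spec("final_input", k_data()),
      port_spec("steps_run", k_integer()),
      port_spec("converged", k_boolean()),
      port_spec("frames", k_data()),
      port_spec("reduce_trace", k_data())
    ),
    category = "simulation", deterministic = TRUE,
    ensemble_runner = function(per_member, session, node) {
      run_md_ensemble(lapply(per_member, `[[`, "input"),
                      node$extras$plugins, session, node)
    }
  )
}

run_md_ensemble <- function(inputs, plugins, session, node) {
  n <- length(inputs)
  members <- vector("list", n)
  for (m in seq_len(n)) {
    inp <- inputs[[m]]
    if (!inherits(inp, "toy_input")) {
      wg_error("wg_invariant_violation",
               sprintf("mdrun input of member %d is not a simulation input", m - 1L))
    }
    validate_system(inp$system); validate_params(inp$params)
    plg <- lapply(plugins, plugin_for_member, m = m)
    for (p in plg) {
      if (any(p$pair < 1L) || any(p$pair > inp$system$n_particles)) {
        wg_error("wg_invariant_violation",
                 sprintf("plugin pair indices out of range for member %d", m - 1L))
      }
    }
    x <- inp$system$positions
    v <- inp$system$velocities
    if (inp$params$seed > 0L) {
      set.seed(inp$params$seed)
      v <- matrix(stats::rnorm(length(x), sd = 0.05), nrow(x), 3)
    }
    members[[m]] <- list(
      input = inp, plugins = plg, x = x, v = v,
      masses = inp$system$masses, dt = inp$params$dt,
      gamma = inp$params$friction_gamma,
      nsteps = inp$params$nsteps, interval = inp$params$output_interval,
      running = TRUE, converged = FALSE, steps_run = 0L,
      frames = list(), reduce_trace = list()
    )
  }
  reducing <- vapply(members, function(mb) {
    any(vapply(mb$plugins, function(p) identical(p$reduce_mode, "mean_distance"),
               logical(1)))
  }, logical(1))
  if (any(reducing) && !all(reducing)) {
    wg_error("wg_reduce_epoch_mismatch",
             "some ensemble members reduce and others do not")
  }

  total_force <- function(mb) {
    bf <- bonded_forces_xv(mb$x, mb$input$system$bonds)
    pf <- plugin_forces(mb$x, mb$plugins)
    f <- bf$forces + pf$forces
    if (mb$gamma > 0) f <- f - mb$gamma * mb$masses * mb$v
    list(forces = f, potential = bf$potential + pf$potential)
  }
  record_frame <- function(mb, step) {
    fp <- total_force(mb)
    ke <- 0.5 * sum(mb$masses * rowSums(mb$v^2))
    mb$frames[[length(mb$frames) + 1L]] <-
      list(step = step, time = step * mb$dt, potential_energy = fp$potential,
           kinetic_energy = ke, positions = mb$x)
    mb
  }
  for (m in seq_len(n)) members[[m]] <- record_frame(members[[m]], 0L)

  # co-execution: one global step loop, round-robin over running members
  max_steps <- max(vapply(members, function(mb) mb$nsteps, integer(1)))
  forces <- lapply(members, total_force)
  epoch <- 0L
  ensemble_stop <- FALSE
  step <- 0L
  while (step < max_steps && any(vapply(members, `[[`, logical(1), "running"))) {
    step <- step + 1L
    for (m in seq_len(n)) {
      mb <- members[[m]]
      if (!mb$running || step > mb$nsteps) next
      f <- forces[[m]]$forces
      a <- f / mb$masses
      x_new <- mb$x + mb$v * mb$dt + 0.5 * a * mb$dt^2
      mb$x <- x_new
      # new conservative forces at x_new; friction uses the pre-step velocity
      bf <- bonded_forces_xv(mb$x, mb$input$system$bonds)
      pf <- plugin_forces(mb$x, mb$plugins)
      f_cons_new <- bf$forces + pf$forces
      f_new <- if (mb$gamma > 0) f_cons_new - mb$gamma * mb$masses * mb$v else f_cons_new
      mb$v <- mb$v + 0.5 * (f + f_new) / mb$masses * mb$dt
      mb$steps_run <- step
      if (!all(is.finite(mb$x))) {
        wg_error("wg_numeric_overflow",
                 sprintf("member %d diverged at step %d (time step too large?)",
                         m - 1L, step))
      }
      # next-step forces with friction at the updated velocity
      f_next <- if (mb$gamma > 0) f_cons_new - mb$gamma * mb$masses * mb$v else f_cons_new
      forces[[m]] <- list(forces = f_next, potential = bf$potential + pf$potential)
      # stop signals, honoured at this step boundary
      for (p in mb$plugins) {
        if (p$stop_tolerance > 0) {
          d <- pair_distance(mb$x, p$pair)
          if (abs(d - p$target) < p$stop_tolerance) {
            mb$converged <- TRUE
            mb$running <- FALSE
            if (identical(p$stop_scope, "ensemble")) ensemble_stop <- TRUE
          }
        }
      }
      if (step >= mb$nsteps) mb$running <- FALSE
      if (mb$running && step %% mb$interval == 0L) mb <- record_frame(mb, step)
      members[[m]] <- mb
    }
    if (ensemble_stop) {
      for (m in seq_len(n)) {
        if (members[[m]]$running) {
          members[[m]]$running <- FALSE
          members[[m]]$steps_run <- step
        }
      }
    }
    # reduce epoch barrier: all members contribute for the same epoch
    if (any(reducing) && step %% members[[1L]]$interval == 0L) {
      running_now <- vapply(members, `[[`, logical(1), "running")
      if (any(running_now) && !all(running_now)) {
        wg_error("wg_reduce_epoch_mismatch",
                 sprintf("epoch at step %d: %d of %d members have left the ensemble",
                         step, sum(!running_now), n))
      }
      if (all(running_now)) {
        epoch <- epoch + 1L
        vals <- vapply(seq_len(n), function(m) {
          p <- Filter(function(p) identical(p$reduce_mode, "mean_distance"),
                      members[[m]]$plugins)[[1L]]
          pair_distance(members[[m]]$x, p$pair)
        }, numeric(1))
        mu <- mean(vals)  # identical reduced value delivered to every member
        for (m in seq_len(n)) {
          members[[m]]$reduce_trace[[epoch]] <-
            list(epoch = epoch, value = vals[[m]], reduced = mu)
        }
      }
    }
  }

  lapply(seq_len(n), function(m) {
    mb <- members[[m]]
    mb <- record_frame(mb, mb$steps_run)  # final frame
    dir <- task_dir(session, node$node_id, m)
    traj <- file.path(dir, "traj.xyz")
    write_xyz(mb$frames, traj)
    write_energies(mb$frames, file.path(dir, "energies.jsonl"))
    final_sys <- toy_system(mb$masses, mb$x, mb$v, mb$input$system$bonds)
    frames_df <- data.frame(
      step = vapply(mb$frames, `[[`, numeric(1), "step"),
      time = vapply(mb$frames, `[[`, numeric(1), "time"),
      potential_energy = vapply(mb$frames, `[[`, numeric(1), "potential_energy"),
      kinetic_energy = vapply(mb$frames, `[[`, numeric(1), "kinetic_energy")
    )
    rt <- mb$reduce_trace
    reduce_df <- if (length(rt)) data.frame(
      epoch = vapply(rt, `[[`, numeric(1), "epoch"),
      value = vapply(rt, `[[`, numeric(1), "value"),
      reduced = vapply(rt, `[[`, numeric(1), "reduced")
    ) else data.frame(epoch = numeric(0), value = numeric(0), reduced = numeric(0))
    list(trajectory_file = traj, final_system = final_sys,
         final_input = simulation_input(final_sys, mb$input$params),
         steps_run = mb$steps_run, converged = mb$converged,
         frames = frames_df, reduce_trace = reduce_df)
  })
}

# bonded_forces on raw position matrix + bond table (hot path)
bonded_forces_xv <- function(x, bonds) {
  f <- matrix(0, nrow(x), 3)
  pot <- 0
  nb <- nrow(bonds)
  if (nb) {
    bi <- bonds$i; bj <- bonds$j; bk <- bonds$k; br0 <- bonds$r0
    for (r in seq_len(nb)) {
      d <- x[bj[r], ] - x[bi[r], ]
      rlen <- sqrt(d[1L]^2 + d[2L]^2 + d[3L]^2)
      if (!is.finite(rlen)) {
        wg_error("wg_numeric_overflow",
                 "non-finite bond length (time step too large?)")
      }
      if (rlen == 0) wg_error("wg_degenerate_geometry", "coincident bonded particles")
      mag <- bk[r] * (rlen - br0[r]) / rlen
      fij <- mag * d
      f[bi[r], ] <- f[bi[r], ] + fij
      f[bj[r], ] <- f[bj[r], ] - fij
      pot <- pot + 0.5 * bk[r] * (rlen - br0[r])^2
    }
  }
  list(forces = f, potential = pot)
}

write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    cat(n, "\n", sprintf("step=%d time=%.6f", fr$step, fr$time), "\n",
        sep = "", file = con)
    for (i in seq_len(n)) {
      cat(sprintf("P %.9f %.9f %.9f\n", fr$positions[i, 1], fr$positions[i, 2],
                  fr$positions[i, 3]), file = con)
    }
  }
  invisible(path)
}

write_energies <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    cat(jsonlite::toJSON(list(step = fr$step, time = fr$time,
                              potential_energy = fr$potential_energy,
                              kinetic_energy = fr$kinetic_energy),
                         auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = con)
  }
  invisible(path)
}
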