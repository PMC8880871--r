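#' @title Synthetic fixtures
#' @description
#' Seeded generators for test surfaces: random valid work graphs of no-op
#' operations, a harmonic dimer run input, and Gaussian-mixture distance
#' distributions emulating experimentally measured pair-distance data
#' (the shape of DEER-style distributions).
#' @name fixtures
NULL

noop_spec <- function() {
  operation_spec(
    "noop", inputs = list(), outputs = list(port_spec("out", k_integer())),
    category = "pure", variadic = TRUE,
    runner = function(inputs, member, session, node) list(out = 0L)
  )
}

#' Generate a random valid work graph
#'
#' Nodes are pure no-op operations; candidate edges run only from lower
#' to higher construction index, which guarantees acyclicity by
#' construction. Deterministic under `seed`.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_probability probability of each lower->higher dependency.
#' @param seed integer seed.
#' @return a fresh `wg_graph` (not activated).
#' @export
generate_random_dag <- function(n_nodes, edge_probability = 0.3, seed = 1L) {
  stopifnot(n_nodes >= 1L, edge_probability > 0, edge_probability < 1)
  g <- work_graph(activate = FALSE)
  spec <- noop_spec()
  handles <- vector("list", n_nodes)
  set.seed(as.integer(seed))
  for (i in seq_len(n_nodes)) {
    parents <- if (i > 1L) which(stats::runif(i - 1L) < edge_probability) else integer(0)
    inputs <- stats::setNames(
      lapply(parents, function(p) ofuture(handles[[p]])),
      if (length(parents)) sprintf("dep%d", seq_along(parents)) else character(0)
    )
    handles[[i]] <- add_node(g, spec, inputs)
  }
  g
}

#' Harmonic dimer run input
#'
#' Two unit-mass particles on the x axis at `+/- separation/2`, zero
#' velocities, one harmonic bond. Default integrator settings: dt 0.001,
#' 10000 steps, no friction, a frame every 10 steps, seed 0 (keep the
#' zero velocities).
#'
#' @param separation initial distance (> 0).
#' @param k_bond bond force constant.
#' @param r0 bond rest length (> 0).
#' @param params optional [sim_params()] overriding the defaults.
#' @return a `toy_input`.
#' @export
make_dimer <- function(separation = 1.2, k_bond = 1, r0 = 1, params = NULL) {
  if (separation <= 0 || r0 <= 0) {
    wg_error("wg_invariant_violation", "separation and r0 must be > 0")
  }
  sys <- toy_system(
    masses = c(1, 1),
    positions = rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0)),
    bonds = data.frame(i = 1L, j = 2L, k = k_bond, r0 = r0)
  )
  simulation_input(sys, params %||% sim_params())
}

#' Gaussian mixture of target distances
#'
#' A mixture of Gaussian components emulating a measured pair-distance
#' distribution; members of a restrained ensemble draw their individual
#' restraint targets from it.
#'
#' @param weights positive, summing to 1.
#' @param centers component means (> 0).
#' @param widths component standard deviations (> 0).
#' @return a `mixture_spec`.
#' @export
mixture_spec <- function(weights, centers, widths) {
  stopifnot(length(weights) == length(centers), length(centers) == length(widths))
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-9) {
    wg_error("wg_invalid_spec", "mixture weights must be positive and sum to 1")
  }
  if (any(widths <= 0)) wg_error("wg_invalid_spec", "mixture widths must be > 0")
  structure(list(weights = as.numeric(weights), centers = as.numeric(centers),
                 widths = as.numeric(widths)),
            class = "mixture_spec")
}

#' @rdname mixture_spec
#' @param spec a `mixture_spec`.
#' @param n sample count.
#' @param seed integer seed.
#' @export
sample_mixture <- function(spec, n, seed) {
  set.seed(as.integer(seed))
  comp <- sample.int(length(spec$weights), n, replace = TRUE, prob = spec$weights)
  stats::rnorm(n, mean = spec$centers[comp], sd = spec$widths[comp])
}

#' @rdname mixture_spec
#' @param q quantiles.
#' @export
pmixture <- function(q, spec) {
  out <- 0
  for (c_ in seq_along(spec$weights)) {
    out <- out + spec$weights[c_] *
      stats::pnorm(q, spec$centers[c_], spec$widths[c_])
  }
  out
}
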