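# Brute-force oracles, independent of the engine's own bookkeeping.

# Ancestors of `node_id` (including itself) by naive repeated edge scans.
brute_ancestors <- function(graph, node_id) {
  parents_of <- function(id) {
    unique(vapply(Filter(function(e) e$to == id, graph$edges),
                  function(e) e$from, character(1)))
  }
  seen <- character(0)
  frontier <- node_id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents_of))), seen)
  }
  sort(seen)
}

# Does `ord` respect every edge of `graph`? Exhaustive edge scan.
respects_edges <- function(graph, ord) {
  pos <- stats::setNames(seq_along(ord), ord)
  all(vapply(graph$edges, function(e) pos[[e$from]] < pos[[e$to]], logical(1)))
}

# Tiny wrapped increment used across control-flow tests.
make_increment <- function(name = "test_inc") {
  function_wrapper(list(out = k_integer()), name = name)(function(x) x + 1L)
}

short_dimer <- function(nsteps = 100L, dt = 0.005, gamma = 0,
                        interval = 10L, separation = 1.2) {
  make_dimer(separation, 1, 1,
             params = sim_params(dt = dt, nsteps = nsteps,
                                 friction_gamma = gamma,
                                 output_interval = interval))
}
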