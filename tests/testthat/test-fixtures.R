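test_that("the random DAG generator is seeded, valid and deterministic", {
  g1 <- generate_random_dag(1, 0.3, seed = 1)
  expect_length(g1$nodes, 1L)
  expect_length(g1$edges, 0L)
  a <- serialize_graph(generate_random_dag(8, 0.4, seed = 42))
  b <- serialize_graph(generate_random_dag(8, 0.4, seed = 42))
  expect_identical(as.character(a), as.character(b))
  for (seed in 1:40) {
    g <- generate_random_dag(2L + seed %% 10L, 0.3, seed = seed)
    expect_identical(validate_graph(g), character(0))
  }
})

test_that("make_dimer builds schema-valid inputs with the stated geometry", {
  d0 <- make_dimer(1.0, 1.0, 1.0)
  expect_equal(bonded_forces(d0$system)$forces, matrix(0, 2, 3))
  d <- make_dimer(1.2, 1.0, 1.0)
  expect_equal(bonded_forces(d$system)$potential, 0.5 * 0.2^2)
  expect_identical(d$params$dt, 0.001)
  expect_identical(d$params$nsteps, 10000L)
  # validates against the run-input schema after a file round-trip
  tmp <- tempfile(fileext = ".json")
  write_input(d, tmp)
  expect_s3_class(read_input_file(tmp), "toy_input")
  expect_error(make_dimer(-1), class = "wg_invariant_violation")
})

test_that("mixture specs validate, sample reproducibly and integrate to 1", {
  expect_error(mixture_spec(c(0.5, 0.4), c(1, 2), c(0.1, 0.1)),
               class = "wg_invalid_spec")
  expect_error(mixture_spec(c(0.5, 0.5), c(1, 2), c(0.1, -0.1)),
               class = "wg_invalid_spec")
  mx <- mixture_spec(c(0.3, 0.7), c(3, 5), c(0.2, 0.4))
  expect_identical(sample_mixture(mx, 10, seed = 4), sample_mixture(mx, 10, seed = 4))
  expect_equal(pmixture(-Inf, mx), 0)
  expect_equal(pmixture(Inf, mx), 1)
  expect_gt(pmixture(4, mx), pmixture(3, mx))
  # empirical CDF of a big sample tracks pmixture
  x <- sample_mixture(mx, 5000, seed = 9)
  expect_lt(max(abs(stats::ecdf(x)(seq(2, 7, 0.25)) -
                    pmixture(seq(2, 7, 0.25), mx))), 0.03)
})

test_that("ensemble fan-out demo produces one trajectory per member", {
  for (n in c(1L, 2L, 4L)) {
    d <- demo_ensemble_fanout(n)
    expect_length(d$trajectories, n)
    expect_true(all(file.exists(d$trajectories)))
  }
  # identical seeds -> identical member trajectories
  d_same <- demo_ensemble_fanout(2L, seeds = c(7L, 7L))
  b1 <- readBin(d_same$trajectories[1], "raw", file.size(d_same$trajectories[1]))
  b2 <- readBin(d_same$trajectories[2], "raw", file.size(d_same$trajectories[2]))
  expect_identical(b1, b2)
  # distinct seeds -> at least one differing frame
  d_diff <- demo_ensemble_fanout(2L, seeds = c(1L, 2L))
  c1 <- readBin(d_diff$trajectories[1], "raw", file.size(d_diff$trajectories[1]))
  c2 <- readBin(d_diff$trajectories[2], "raw", file.size(d_diff$trajectories[2]))
  expect_false(identical(c1, c2))
})

test_that("the adaptive loop demo terminates by convergence or by its guard", {
  # huge tolerance: converges in the very first segment
  d1 <- demo_adaptive_loop(stop_tolerance = 10)
  expect_identical(d1$iterations_run, 1L)
  # unreachable tolerance: the guard stops the loop after exactly 3 rounds
  d2 <- demo_adaptive_loop(stop_tolerance = 1e-12, max_iteration = 3L,
                           nsteps_segment = 50L)
  expect_identical(d2$iterations_run, 3L)
  expect_false(any(d2$converged))
  # defaults: terminates with at least one converged member
  d3 <- demo_adaptive_loop()
  expect_true(any(d3$converged))
  expect_lte(d3$iterations_run, 10L)
})

test_that("the tool-chain demo orders file operations by dependency", {
  d <- demo_tool_chain()
  expect_true(file.exists(d$trajectory))
  log <- d$log
  idx <- function(id) log$order_index[log$node_id == id]
  expect_lt(idx("concat_fragments-1"), idx("copy_into_place-1"))
  expect_lt(idx("copy_into_place-1"), idx("read_input-1"))
  expect_lt(idx("read_input-1"), idx("mdrun-1"))
  # re-resolving the chain executes zero new nodes
  n1 <- nrow(execution_log(d$session))
  result(ofuture(d$nodes$md, "trajectory_file"))
  expect_identical(nrow(execution_log(d$session)), n1)
})

test_that("demos jointly exercise the public operation surface", {
  d <- demo_tool_chain()
  ops <- unique(d$log$op_name)
  expect_true(all(c("concat_fragments", "copy_into_place", "read_input", "mdrun")
                  %in% ops))
  g <- work_graph(activate = FALSE)
  concatenate_lists(list(c(1L), c(2L)), graph = g)
  logical_not(TRUE, graph = g)
  expect_setequal(unique(vapply(g$nodes, function(n) n$spec$op_name, character(1))),
                  c("make_constant", "join_arrays", "logical_not"))
})

test_that("restrained-ensemble members end within tolerance of a point target", {
  # degenerate single-component mixture, tiny width
  mx <- mixture_spec(1, 2.0, 1e-4)
  d <- restrained_ensemble_demo(mixture = mx, n_members = 4L, seed = 3L,
                                stop_tolerance = 0.05)
  expect_length(d$final_distances, 4L)
  expect_true(all(abs(d$final_distances - 2.0) < 0.05 + 1e-3))
  expect_true(all(d$converged))
})
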