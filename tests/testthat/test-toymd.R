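test_that("run-input files round-trip and invariants are enforced with field paths", {
  p <- system.file("extdata", "dimer.json", package = "flowmd")
  inp <- read_input_file(p)
  expect_identical(inp$system$n_particles, 2L)
  expect_identical(nrow(inp$system$bonds), 1L)
  # write -> read is the identity
  tmp <- tempfile(fileext = ".json")
  write_input(inp, tmp)
  inp2 <- read_input_file(tmp)
  expect_equal(inp2$system$positions, inp$system$positions)
  expect_equal(inp2$system$bonds, inp$system$bonds)
  expect_identical(unclass(inp2$params), unclass(inp$params))
  # invariant violations name the offending field
  bad <- inp; bad$system$masses[2] <- -1
  err <- tryCatch(write_input(bad, tmp) |> read_input_file(),
                  error = function(e) e)
  expect_s3_class(err, "wg_invariant_violation")
  expect_match(conditionMessage(err), "masses\\[2\\]")
  expect_error(read_input_file(tempfile()), class = "wg_malformed_input")
})

test_that("modify_input overrides single paths and fans out over arrays", {
  base <- short_dimer()
  g <- work_graph(activate = FALSE)
  h0 <- make_constant(base, kind = k_data(), graph = g)
  h <- modify_input(h0, list("params.nsteps" = 100L), graph = g)
  out <- result(ofuture(h))
  expect_identical(out$params$nsteps, 100L)
  expect_identical(out$params$dt, base$params$dt)           # all else equal
  expect_equal(out$system$positions, base$system$positions)
  # fan-out over a seed array
  h3 <- modify_input(h0, list("params.seed" = c(1L, 2L, 3L)), graph = g)
  expect_identical(h3$width, 3L)
  outs <- result(ofuture(h3))
  expect_identical(vapply(outs, function(o) o$params$seed, integer(1)), 1:3)
  expect_error(modify_input(h0, list("params.foo" = 1), graph = g),
               class = "wg_unknown_parameter_path")
})

test_that("bonded forces obey Newton's third law and match a scalar oracle", {
  sys <- make_dimer(1.0, 1.0, 1.0)$system
  bf <- bonded_forces(sys)
  expect_equal(bf$forces, matrix(0, 2, 3))  # at rest length: no force
  expect_identical(bf$potential, 0)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    pos <- matrix(stats::rnorm(n * 3), n, 3)
    nb <- sample(1:4, 1)
    ij <- t(replicate(nb, sample(n, 2)))
    bonds <- data.frame(i = ij[, 1], j = ij[, 2],
                        k = stats::runif(nb, 0.1, 3), r0 = stats::runif(nb, 0.5, 2))
    sysr <- toy_system(rep(1, n), pos, bonds = bonds)
    bf <- bonded_forces(sysr)
    expect_equal(colSums(bf$forces), c(0, 0, 0), tolerance = 1e-12)
    # independent scalar potential evaluation
    pot <- sum(vapply(seq_len(nb), function(r) {
      d <- sqrt(sum((pos[bonds$j[r], ] - pos[bonds$i[r], ])^2))
      0.5 * bonds$k[r] * (d - bonds$r0[r])^2
    }, numeric(1)))
    expect_equal(bf$potential, pot, tolerance = 1e-12)
  }
  sys0 <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(0, 0, 0)),
                     bonds = data.frame(i = 1L, j = 2L, k = 1, r0 = 1))
  expect_error(bonded_forces(sys0), class = "wg_degenerate_geometry")
})

test_that("the integrator conserves energy and momentum without friction", {
  g <- work_graph(activate = FALSE)
  res <- run(mdrun(make_dimer(1.2, 1, 1), graph = g))
  fr <- res$frames
  E <- fr$potential_energy + fr$kinetic_energy
  expect_lte(max(abs(E - E[1])) / E[1], 1e-6)
  # total momentum stays zero to round-off
  expect_equal(colSums(res$final_system$masses * res$final_system$velocities),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("conservation improves at least 2x when dt is halved (order-2 integrator)", {
  drift_at <- function(dt, nsteps) {
    g <- work_graph(activate = FALSE)
    inp <- make_dimer(1.2, 1, 1,
                      params = sim_params(dt = dt, nsteps = nsteps,
                                          output_interval = 10L))
    fr <- run(mdrun(inp, graph = g))$frames
    E <- fr$potential_energy + fr$kinetic_energy
    max(abs(E - E[1])) / E[1]
  }
  d1 <- drift_at(0.002, 2500L)
  d2 <- drift_at(0.001, 5000L)
  expect_gte(d1 / d2, 2)
})

test_that("dimer oscillation period matches the reduced-mass closed form within 1%", {
  g <- work_graph(activate = FALSE)
  inp <- make_dimer(1.2, 1, 1,
                    params = sim_params(dt = 0.001, nsteps = 20000L,
                                        output_interval = 1L))
  fr <- run(mdrun(inp, graph = g))$frames
  # kinetic energy oscillates at twice the bond frequency: the spacing of
  # its minima is half the period of the separation coordinate
  ke <- fr$kinetic_energy
  mins <- which(diff(sign(diff(ke))) == 2) + 1L
  period <- 2 * mean(diff(fr$time[mins]))
  expect_lt(abs(period - 2 * pi / sqrt(2)) / (2 * pi / sqrt(2)), 0.01)
})

test_that("bond plus restraint relaxes to the closed-form minimum within 2%", {
  g <- work_graph(activate = FALSE)
  inp <- make_dimer(1.2, 1, 1,
                    params = sim_params(dt = 0.005, nsteps = 6000L,
                                        friction_gamma = 1, output_interval = 10L))
  plugin <- restraint_plugin(c(1L, 2L), k_restraint = 4, target = 2)
  res <- run(mdrun(inp, plugins = list(plugin), graph = g))
  # time-averaged late-time separation
  d_final <- sqrt(sum((res$final_system$positions[2, ] -
                       res$final_system$positions[1, ])^2))
  want <- (1 * 1 + 4 * 2) / (1 + 4)  # (kb r0 + kr target)/(kb + kr)
  expect_lt(abs(d_final - want) / want, 0.02)
})

test_that("member-scope stop halts early with the distance inside the window", {
  g <- work_graph(activate = FALSE)
  inp <- make_dimer(1.0, 1, 1,
                    params = sim_params(dt = 0.005, nsteps = 5000L,
                                        friction_gamma = 1, output_interval = 10L))
  plugin <- restraint_plugin(c(1L, 2L), k_restraint = 10, target = 1.5,
                             stop_tolerance = 0.05, stop_scope = "member")
  res <- run(mdrun(inp, plugins = list(plugin), graph = g))
  expect_true(res$converged)
  expect_lt(res$steps_run, 5000L)
  d <- sqrt(sum((res$final_system$positions[2, ] -
                 res$final_system$positions[1, ])^2))
  expect_lt(abs(d - 1.5), 0.05)
})

test_that("a too-large time step raises numeric overflow, not garbage", {
  g <- work_graph(activate = FALSE)
  inp <- make_dimer(1.2, 1000, 1,
                    params = sim_params(dt = 10, nsteps = 1000L))
  expect_error(run(mdrun(inp, graph = g)), class = "wg_numeric_overflow")
})
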