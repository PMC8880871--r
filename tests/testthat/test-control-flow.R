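test_that("subgraph declarations validate variables and freeze the spec", {
  inc <- make_increment("cf_inc")
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  expect_s3_class(sg, "wg_subgraph")
  expect_identical(sg$variables$n$initial, 0L)
  expect_error(subgraph(variables = list(n = 0L, n = 1L), body = identity),
               class = "wg_variable_shadowing")
  expect_error(subgraph(variables = list(n = list(kind = k_integer(), initial = "x")),
                        body = identity),
               class = "wg_update_kind_mismatch")
})

test_that("update kind mismatches and bad conditions are rejected", {
  txt <- function_wrapper(list(out = k_text()), name = "cf_txt")(function(x) "oops")
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list(n = txt(x = v$n, graph = v$n$graph)))
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = function(s) s$n < 2L, max_iteration = 5L, graph = g)
  expect_error(result(ofuture(wl, "n")), class = "wg_update_kind_mismatch")

  g2 <- work_graph(activate = FALSE)
  inc <- make_increment("cf_inc2")
  sg2 <- subgraph(variables = list(n = 0L),
                  body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  wl2 <- while_loop(sg2, condition = function(s) "not boolean",
                    max_iteration = 3L, graph = g2)
  expect_error(result(ofuture(wl2, "n")), class = "wg_non_boolean_condition")
})

test_that("counter loops run exactly min(K, max_iteration) iterations", {
  inc <- make_increment("cf_inc3")
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  for (K in 0:10) {
    for (maxit in c(0L, 1L, 5L, 100L)) {
      g <- work_graph(activate = FALSE)
      wl <- while_loop(sg, condition = local({
        KK <- K
        function(s) s$n < KK
      }), max_iteration = maxit, graph = g)
      expect_identical(result(ofuture(wl, "iterations_run")), min(K, maxit),
                       info = sprintf("K=%d maxit=%d", K, maxit))
      expect_identical(result(ofuture(wl, "n")), min(K, maxit))
    }
  }
})

test_that("pre-test semantics: a false condition means zero iterations", {
  inc <- make_increment("cf_inc4")
  sg <- subgraph(variables = list(n = 5L),
                 body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = function(s) FALSE, max_iteration = 100L, graph = g)
  expect_identical(result(ofuture(wl, "iterations_run")), 0L)
  expect_identical(result(ofuture(wl, "n")), 5L)  # finals equal initials
})

test_that("graph growth is literal: each iteration appends fresh executed nodes", {
  inc <- make_increment("cf_inc5")
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = function(s) s$n < 3L, max_iteration = 10L, graph = g)
  result(ofuture(wl, "n"))
  log <- execution_log(g)
  expect_identical(sum(log$op_name == "cf_inc5"), 3L)
  expect_identical(sum(log$op_name == "make_constant"), 3L)  # state re-injection
})

test_that("loop instances never share state", {
  inc <- make_increment("cf_inc6")
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list(n = inc(x = v$n, graph = v$n$graph)))
  g <- work_graph(activate = FALSE)
  wl1 <- while_loop(sg, condition = function(s) s$n < 2L, max_iteration = 10L, graph = g)
  wl2 <- while_loop(sg, condition = function(s) s$n < 2L, max_iteration = 10L, graph = g)
  expect_identical(result(ofuture(wl1, "n")), 2L)
  expect_identical(result(ofuture(wl2, "n")), 2L)  # not 4: fresh state
})

test_that("a body with no updates is valid and still executes its nodes", {
  poke <- function_wrapper(list(out = k_integer()), name = "cf_poke")(
    function(x) x
  )
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) { poke(x = 1L, graph = v$n$graph); list() })
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = local({
    count <- 0L
    function(s) { count <<- count + 1L; count <= 3L }
  }), max_iteration = 100L, graph = g)
  expect_identical(result(ofuture(wl, "iterations_run")), 3L)
  expect_identical(sum(execution_log(g)$op_name == "cf_poke"), 3L)
})

test_that("loop execution equals the explicitly unrolled chain (dynamic-extension oracle)", {
  # simulation body under fixed seeds: the while_loop must reproduce the
  # exact final coordinates of a scripted loop calling the body K times
  scripted <- function(K, input0) {
    cur <- input0
    for (i in seq_len(K)) {
      g <- work_graph(activate = FALSE)
      h <- mdrun(cur, graph = g)
      cur <- result(ofuture(h, "final_input"))
    }
    cur
  }
  input0 <- short_dimer(nsteps = 50L)
  K <- 3L
  want <- scripted(K, input0)

  sg <- subgraph(
    variables = list(input = list(kind = k_data(), initial = input0),
                     i = 0L),
    body = function(v) {
      gg <- v$i$graph
      h <- mdrun(v$input, graph = gg)
      inc <- make_increment("cf_inc7")
      list(input = ofuture(h, "final_input"),
           i = inc(x = v$i, graph = gg))
    }
  )
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = function(s) s$i < K, max_iteration = 100L, graph = g)
  got <- result(ofuture(wl, "input"))
  expect_identical(result(ofuture(wl, "iterations_run")), K)
  expect_equal(got$system$positions, want$system$positions, tolerance = 1e-12)
  expect_equal(got$system$velocities, want$system$velocities, tolerance = 1e-12)
})

test_that("ensemble-width conditions must pass through explicit reductions", {
  flags <- function_wrapper(list(out = k_boolean()), name = "cf_flags")(
    function(x) x > 1L
  )
  sg <- subgraph(variables = list(n = 0L),
                 body = function(v) list())
  g <- work_graph(activate = FALSE)
  wl <- while_loop(sg, condition = function(s) {
    h <- flags(x = list(1L, 2L), graph = g)
    ofuture(h)   # width-2 boolean: ambiguous as a gate
  }, max_iteration = 3L, graph = g)
  expect_error(result(ofuture(wl, "iterations_run")),
               class = "wg_non_boolean_condition")
  expect_true(ensemble_any(list(FALSE, TRUE)))
  expect_false(ensemble_all(list(FALSE, TRUE)))
})
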