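test_that("kinds are nominal and arrays nest at most twice", {
  expect_true(kind_compatible(k_integer(), k_integer()))
  expect_false(kind_compatible(k_integer(), k_real()))
  expect_true(kind_compatible(k_array(k_integer()), k_array(k_integer())))
  expect_false(kind_compatible(k_array(k_integer()), k_array(k_real())))
  expect_true(kind_compatible(k_any(), k_boolean()))
  expect_true(kind_compatible(k_array(k_any()), k_array(k_text())))
  expect_error(k_array(k_array(k_array(k_integer()))), class = "wg_unknown_kind")
  expect_identical(infer_kind(TRUE)$tag, "boolean")
  expect_identical(format(infer_kind(c(1L, 2L))), "array_of(integer)")
  expect_error(infer_kind(list(1L, "a")), class = "wg_unsupported_payload")
})

test_that("infer_width broadcasts scalars and rejects mismatched ensembles", {
  expect_identical(infer_width(c(1L, 1L)), 1L)
  expect_identical(infer_width(c(1L, 3L)), 3L)
  expect_identical(infer_width(c(3L, 3L, 1L)), 3L)
  expect_error(infer_width(c(2L, 3L)), class = "wg_incompatible_widths")
  # commutative and associative over the argument multiset
  set.seed(11)
  for (i in 1:25) {
    w <- sample(2:6, 1)
    ws <- c(rep(1L, sample(0:3, 1)), rep(w, sample(1:3, 1)))
    ws <- ws[sample.int(length(ws), length(ws))]
    expect_identical(infer_width(ws), infer_width(rev(ws)))
    expect_identical(infer_width(ws), infer_width(c(infer_width(ws[1]), ws[-1])))
  }
})

test_that("add_node binds inputs, creates edges and keeps ids deterministic", {
  g <- work_graph(activate = FALSE)
  f <- make_constant(42L, graph = g)
  expect_identical(f$width, 1L)
  expect_length(g$edges, 0L)
  h <- logical_not(TRUE, graph = g)
  expect_identical(h$node_id, "logical_not-1")
  h2 <- logical_not(h, graph = g)
  expect_identical(h2$node_id, "logical_not-2")
  expect_length(g$edges, 1L)
  ord <- topological_order(g)
  expect_lt(match("logical_not-1", ord), match("logical_not-2", ord))
  # unknown port / missing required / kind mismatch
  spec <- operation_spec("adder",
                         inputs = list(port_spec("a", k_integer()),
                                       port_spec("b", k_integer())),
                         outputs = list(port_spec("out", k_integer())),
                         runner = function(i, m, s, n) list(out = i$a + i$b))
  expect_error(add_node(g, spec, list(a = 1L, c = 2L)), class = "wg_unknown_port")
  expect_error(add_node(g, spec, list(a = 1L)), class = "wg_missing_required_input")
  expect_error(add_node(g, spec, list(a = 1L, b = ofuture(h2))),
               class = "wg_kind_mismatch")
  # width broadcasting through futures: 1 against 3 is fine, 2 against 3 is not
  ens3 <- logical_not(c(TRUE, FALSE, TRUE), graph = g)
  expect_identical(ens3$width, 3L)
  both <- add_node(g, operation_spec("and2",
                                     inputs = list(port_spec("a", k_boolean()),
                                                   port_spec("b", k_boolean())),
                                     outputs = list(port_spec("out", k_boolean())),
                                     runner = function(i, m, s, n) list(out = i$a && i$b)),
                   list(a = ofuture(ens3), b = ofuture(h2)))
  expect_identical(both$width, 3L)
  ens2 <- logical_not(c(TRUE, FALSE), graph = g)
  expect_error(add_node(g, operation_spec("and3",
                                          inputs = list(port_spec("a", k_boolean()),
                                                        port_spec("b", k_boolean())),
                                          outputs = list(port_spec("out", k_boolean())),
                                          runner = function(i, m, s, n) list(out = TRUE)),
                        list(a = ofuture(ens3), b = ofuture(ens2))),
               class = "wg_incompatible_widths")
})

test_that("validate_graph reports violations as diagnostics, not errors", {
  g <- work_graph(activate = FALSE)
  expect_identical(validate_graph(g), character(0))
  a <- logical_not(TRUE, graph = g)
  b <- logical_not(a, graph = g)
  expect_identical(validate_graph(g), character(0))
  # manually injected back-edge creates a cycle named in the diagnostic
  g$edges[[length(g$edges) + 1L]] <-
    list(from = b$node_id, from_port = "data", to = a$node_id, to_port = "data",
         mode = "map")
  d <- validate_graph(g)
  expect_length(d, 1L)
  expect_match(d, "cycle")
  expect_match(d, "logical_not-1")
  # dangling endpoint
  g2 <- work_graph(activate = FALSE)
  logical_not(TRUE, graph = g2)
  g2$edges[[1L]] <- list(from = "ghost-1", from_port = "data",
                         to = "logical_not-1", to_port = "data", mode = "map")
  expect_match(validate_graph(g2), "unknown source")
})

test_that("random valid DAGs validate cleanly and order respects every edge", {
  has_igraph <- requireNamespace("igraph", quietly = TRUE)
  for (seed in 1:50) {
    n <- 1L + (seed %% 12L)
    g <- generate_random_dag(n, 0.35, seed = seed)
    expect_identical(validate_graph(g), character(0))
    ord <- topological_order(g)
    expect_setequal(ord, g$node_order)
    expect_true(respects_edges(g, ord))
    if (has_igraph && length(g$edges)) {
      # independent cycle check: igraph must also see a DAG
      el <- do.call(rbind, lapply(g$edges, function(e) c(e$from, e$to)))
      ig <- igraph::graph_from_edgelist(el, directed = TRUE)
      expect_true(igraph::is_dag(ig))
    }
  }
})

test_that("topological order breaks ties by insertion order", {
  g <- work_graph(activate = FALSE)
  spec <- operation_spec("src", inputs = list(),
                         outputs = list(port_spec("out", k_integer())),
                         variadic = TRUE,
                         runner = function(i, m, s, n) list(out = 0L))
  a <- add_node(g, spec, list())
  b <- add_node(g, spec, list(d1 = ofuture(a)))
  c_ <- add_node(g, spec, list(d1 = ofuture(a)))
  d <- add_node(g, spec, list(d1 = ofuture(b), d2 = ofuture(c_)))
  expect_identical(topological_order(g), c("src-1", "src-2", "src-3", "src-4"))
})

test_that("acyclicity is preserved across randomized construction sequences", {
  for (seed in 1:20) {
    g <- work_graph(activate = FALSE)
    spec <- operation_spec("gen", inputs = list(),
                           outputs = list(port_spec("out", k_integer())),
                           variadic = TRUE,
                           runner = function(i, m, s, n) list(out = 0L))
    hs <- list()
    set.seed(seed)
    for (i in 1:8) {
      k <- if (i > 1) sample(0:min(3, i - 1), 1) else 0
      parents <- if (k > 0) sample(seq_len(i - 1), k) else integer(0)
      ins <- stats::setNames(lapply(parents, function(p) ofuture(hs[[p]])),
                             if (k > 0) sprintf("d%d", seq_len(k)) else character(0))
      hs[[i]] <- add_node(g, spec, ins)
      expect_identical(validate_graph(g), character(0))
    }
  }
})
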