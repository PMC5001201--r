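test_that("edge cost is the inverse geometric mean of endpoint weights", {
  expect_equal(edge_cost(4, 9), 1 / 6)
  expect_equal(edge_cost(1, 1), 1)
  expect_equal(edge_cost(100, 100), 0.01)
  # vectorized and symmetric
  a <- c(0.5, 3, 700); b <- c(12, 0.01, 700)
  expect_equal(edge_cost(a, b), edge_cost(b, a))
  expect_equal(edge_cost(2, 8), edge_cost(8, 2))
  # strictly decreasing in each argument
  expect_true(all(diff(edge_cost(c(1, 2, 4, 8), 5)) < 0))
  expect_error(edge_cost(0, 1), "positive")
  expect_error(edge_cost(4, -2), "positive")
  expect_error(edge_cost(Inf, 1), "positive|finite")
})

test_that("expression profiles validate and optionally floor intensities", {
  p <- expression_profile(c(A = 1.5, B = 2), "control")
  expect_s3_class(p, "expression_profile")
  expect_identical(attr(p, "condition"), "control")
  expect_error(expression_profile(c(A = 0, B = 1), "c"), "non-positive")
  expect_error(expression_profile(c(1, 2), "c"), "named")
  expect_error(expression_profile(c(A = 1, A = 2), "c"), "duplicate")
  fl <- expression_profile(c(A = -3, B = 10, C = 0.5), "c",
                           floor_nonpositive = TRUE)
  expect_equal(unname(fl["A"]), 0.5 * 1e-3)  # smallest positive * 1e-3
})

test_that("expression reader collapses replicates and can unlog", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3", "G1\t1\t3\t5", "G2\t2\t2\t2"), f)
  p <- read_expression(f, "control")
  expect_equal(unname(p[c("G1", "G2")]), c(3, 2))
  p2 <- read_expression(f, "control", columns = c("s1", "s2"))
  expect_equal(unname(p2["G1"]), 2)
  lg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "G1\t3"), lg)
  expect_equal(unname(read_expression(lg, "c", unlog2 = TRUE)["G1"]), 8)
})

test_that("base network drops self-loops and duplicate edges with counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("A\tA", "A\tB"), f)
  expect_message(g2 <- read_edge_list(f), "1 self-loop")
  expect_true("A" %in% igraph::V(g2)$name)  # node retained
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::graph_attr(g2, "dropped_self_loops"), 1)

  writeLines(c("A\tB", "A\tB", "B\tA"), f)
  expect_message(g3 <- read_edge_list(f), "1 duplicate")
  expect_equal(igraph::ecount(g3), 2)  # A->B once plus B->A
  expect_equal(igraph::graph_attr(g3, "dropped_duplicate_edges"), 1)

  writeLines("A", f)
  expect_error(read_edge_list(f), "malformed line 1")
  writeLines(character(0), f)
  expect_error(read_edge_list(f), "empty")
})

test_that("SIF reader maps relation to the edge type", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tactivates\tB", "B\tinhibits\tC"), f)
  g <- read_edge_list(f, format = "sif")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$type, c("activates", "inhibits"))
})

test_that("condition networks carry inverse-sqrt costs and drop rules", {
  net <- base_network(data.frame(from = "A", to = "B"))
  cn <- build_condition_network(net, expression_profile(c(A = 4, B = 9),
                                                        "x"))
  expect_equal(igraph::E(cn)$cost, 1 / 6)
  expect_identical(igraph::graph_attr(cn, "condition"), "x")

  # unmapped node dropped with incident edges
  net2 <- base_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_message(
    cn2 <- build_condition_network(net2,
                                   expression_profile(c(A = 1, C = 1),
                                                      "x")),
    "dropped 1 node")
  expect_setequal(igraph::V(cn2)$name, c("A", "C"))
  expect_equal(igraph::ecount(cn2), 0)

  # uniform weights give unit costs
  set.seed(1)
  nodes <- sprintf("v%02d", 1:50)
  e <- data.frame(from = sample(nodes, 120, TRUE),
                  to = sample(nodes, 120, TRUE))
  e <- e[e$from != e$to, ]
  net3 <- suppressMessages(base_network(e))
  cn3 <- suppressMessages(build_condition_network(
    net3, expression_profile(stats::setNames(rep(1, 50), nodes), "x")))
  expect_true(all(igraph::E(cn3)$cost == 1))

  expect_error(
    build_condition_network(net, expression_profile(c(Z = 1), "x")),
    "no overlap")
})

test_that("rebuilding a condition network from its own weights is exact", {
  set.seed(7)
  cn <- random_condition_network(20, 0.2)
  w <- stats::setNames(igraph::V(cn)$weight, igraph::V(cn)$name)
  cn2 <- suppressMessages(build_condition_network(
    cn, expression_profile(w, "x")))
  el1 <- igraph::as_edgelist(cn); el2 <- igraph::as_edgelist(cn2)
  o1 <- order(el1[, 1], el1[, 2]); o2 <- order(el2[, 1], el2[, 2])
  expect_identical(el1[o1, ], el2[o2, ])
  expect_identical(igraph::E(cn)$cost[o1], igraph::E(cn2)$cost[o2])
})

test_that("global intensity rescaling scales every cost by 1/k", {
  set.seed(11)
  nodes <- sprintf("v%d", 1:15)
  e <- data.frame(from = sample(nodes, 40, TRUE),
                  to = sample(nodes, 40, TRUE))
  e <- unique(e[e$from != e$to, ])
  net <- suppressMessages(base_network(e))
  w <- stats::setNames(rlnorm(15, 4, 1), nodes)
  for (k in c(0.01, 37)) {
    c1 <- suppressMessages(build_condition_network(
      net, expression_profile(w, "x")))
    c2 <- suppressMessages(build_condition_network(
      net, expression_profile(w * k, "x")))
    expect_equal(igraph::E(c2)$cost, igraph::E(c1)$cost / k,
                 tolerance = 1e-12)
  }
})

test_that("fold changes flag symmetric up/down dysregulation", {
  ctrl <- expression_profile(c(G1 = 2, G2 = 5, G3 = 8), "control")
  pert <- expression_profile(c(G1 = 8, G2 = 5, G3 = 2), "perturbed")
  fc <- fold_changes(ctrl, pert, cutoff = 2)
  expect_equal(fc$fold_change, c(4, 1, 0.25))
  expect_equal(fc$direction, c("up", "up", "down"))
  expect_equal(fc$significant, c(TRUE, FALSE, TRUE))
  expect_error(fold_changes(ctrl, pert, cutoff = 1), "> 1")
  expect_error(fold_changes(ctrl, pert, cutoff = 0.5), "> 1")
  expect_true(significant_fc(0.25, 2))   # 0.25 <= 1/2
  expect_false(significant_fc(0.6, 2))
})
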