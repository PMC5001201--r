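# directed graph with explicit edge costs, standing in for a CSHAN
cost_graph <- function(from, to, cost) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, cost = cost,
               stringsAsFactors = FALSE), directed = TRUE)
  igraph::set_graph_attr(g, "condition", "perturbed")
}

test_that("raw closeness is the reciprocal summed cost from each source", {
  chain <- cost_graph(c("A", "B"), c("B", "C"), c(1, 1))
  raw <- closeness_out(chain, normalized = FALSE)
  expect_equal(unname(raw["A"]), 1 / 3)  # distances 1 and 2
  expect_equal(unname(raw["B"]), 1)
  expect_equal(unname(raw["C"]), 0)      # sink

  star <- cost_graph(rep("S", 3), c("L1", "L2", "L3"), rep(1, 3))
  raws <- closeness_out(star, normalized = FALSE)
  expect_equal(unname(raws["S"]), 1 / 3)
  expect_equal(unname(raws[c("L1", "L2", "L3")]), rep(0, 3))
  expect_equal(unname(closeness_out(star)["S"]), 1)  # normalized max
})

test_that("outward reachability counts reachable nodes over N - 1", {
  chain <- cost_graph(c("A", "B"), c("B", "C"), c(1, 1))
  raw <- outward_reachability(chain, normalized = FALSE)
  expect_equal(unname(raw), c(2, 1, 0))  # A, B, C in lex order
  expect_equal(unname(outward_reachability(chain)["A"]), 1)
  cyc <- cost_graph(c("a", "b", "c", "d", "e"),
                    c("b", "c", "d", "e", "a"), rep(1, 5))
  expect_true(all(outward_reachability(cyc, normalized = FALSE) == 4))
  expect_true(all(outward_reachability(cyc) == 1))
})

test_that("ripple is an AND: zero factors kill it, both raise it", {
  chain <- cost_graph(c("A", "B"), c("B", "C"), c(1, 1))
  rp <- ripple_centrality(chain)
  expect_equal(rp$ripple, rp$closeness * rp$reachability)
  expect_equal(rp$ripple[rp$gene == "C"], 0)
  full <- stats::setNames(oracle_ripple(chain), NULL)
  expect_equal(rp$ripple, full, tolerance = 1e-12)

  # raising reachability with normalized closeness held fixed raises it
  wide <- cost_graph(rep("S", 4), paste0("L", 1:4), rep(0.5, 4))
  narrow <- igraph::add_vertices(
    cost_graph(rep("S", 2), paste0("L", 1:2), rep(0.5, 2)), 2,
    name = c("L3", "L4"))  # same N, S reaches only 2
  rw <- ripple_centrality(wide); rn <- ripple_centrality(narrow)
  cw <- rw[rw$gene == "S", ]; cn_ <- rn[rn$gene == "S", ]
  expect_equal(cw$closeness, cn_$closeness)  # both are the max, i.e. 1
  expect_gt(cw$ripple, cn_$ripple)
})

test_that("a wide source of active paths out-ranks pure closeness or reach", {
  # three candidate sources: Acl has very active paths to only 2 nodes;
  # Aor reaches 14 nodes through weak paths; Arc reaches 7 through strong
  # ones and must score highest
  from <- c("Acl", "Acl",
            "Aor", paste0("t", 1:13),
            rep("Arc", 7))
  to <- c("b1", "b2",
          "t1", paste0("t", 2:14),
          paste0("r", 1:7))
  cost <- c(rep(0.2, 2), rep(1, 14), rep(0.3, 7))
  g <- cost_graph(from, to, cost)
  rp <- ripple_centrality(g)
  best <- rp$gene[which.max(rp$ripple)]
  expect_identical(best, "Arc")
  scores <- stats::setNames(rp$ripple, rp$gene)
  expect_gt(scores["Arc"], scores["Acl"])
  expect_gt(scores["Arc"], scores["Aor"])
})

test_that("ripple vectors match the relaxation + closure oracle", {
  set.seed(99)
  for (i in 1:30) {
    cn <- random_condition_network(sample(4:8, 1), 0.3)
    rp <- ripple_centrality(cn)
    expect_equal(rp$ripple, unname(oracle_ripple(cn)[rp$gene]),
                 tolerance = 1e-12)
  }
})

test_that("epicenter lists split by membership with competition ranks", {
  g <- cost_graph(c("A", "B", "X"), c("B", "C", "B"), c(1, 1, 1))
  empty <- igraph::set_graph_attr(igraph::make_empty_graph(directed = TRUE),
                                  "condition", "control")
  ep <- get_epicenters(g, empty, top_k = 10)
  expect_equal(nrow(ep$global), 0)              # vacuous overlap
  expect_setequal(ep$specific$gene, c("A", "B", "C", "X"))

  # bit-identical scores share a rank and the next rank skips
  sym <- cost_graph(c("A", "B", "u", "v"), c("u", "v", "w", "w"),
                    c(0.5, 0.5, 1, 1))
  eps <- get_epicenters(sym, empty, top_k = 10)
  sp <- eps$specific
  expect_equal(sp$rank[sp$gene %in% c("A", "B")], c(1, 1))
  expect_equal(sort(unique(sp$rank)), c(1, 3, 5))

  other <- cost_graph("A", "B", 1)
  epo <- get_epicenters(g, other, top_k = 10)
  expect_setequal(epo$global$gene, c("A", "B"))
  expect_setequal(epo$specific$gene, c("C", "X"))

  expect_error(get_epicenters(empty, g), "percentile|empty")
})

test_that("tie groups straddling top_k are kept whole", {
  # 5 equal-score sources tie at rank 2; with top_k = 3 all five stay
  from <- c("Z", "Z", paste0("S", 1:5))
  to <- c("q1", "q2", rep("q1", 5))
  g <- cost_graph(from, to, c(0.1, 0.1, rep(1, 5)))
  ep <- get_epicenters(
    g, igraph::set_graph_attr(igraph::make_empty_graph(directed = TRUE),
                              "condition", "control"), top_k = 3)
  sp <- ep$specific
  expect_true(all(paste0("S", 1:5) %in% sp$gene))
  expect_equal(length(unique(sp$rank[sp$gene %in% paste0("S", 1:5)])), 1)
})

test_that("the LSCC report flags strongly connected membership", {
  cyc <- cost_graph(c("a", "b", "c"), c("b", "c", "a"), rep(1, 3))
  r1 <- lscc_report(cyc)
  expect_true(all(r1$in_lscc))
  expect_equal(attr(r1, "lscc_size"), 3)

  dag <- cost_graph(c("a", "b"), c("b", "c"), c(1, 1))
  r2 <- lscc_report(dag)
  expect_false(any(r2$in_lscc))
  expect_equal(attr(r2, "lscc_size"), 1)

  pend <- cost_graph(c("a", "b", "c", "a"), c("b", "c", "a", "p"),
                     rep(1, 4))
  r3 <- lscc_report(pend)
  expect_false(r3$in_lscc[r3$gene == "p"])
  expect_true(all(r3$in_lscc[r3$gene != "p"]))
})

test_that("rankings are invariant under global intensity rescaling", {
  case <- default_case()
  fit <- default_fit()
  scale_profile <- function(p, k)
    expression_profile(stats::setNames(as.numeric(p) * k, names(p)),
                       attr(p, "condition"))
  fit2 <- epitracer(case$network, scale_profile(case$control, 37),
                    scale_profile(case$perturbed, 37))
  for (side in c("specific", "global")) {
    expect_identical(fit$rankings$perturbed[[side]][, c("rank", "gene")],
                     fit2$rankings$perturbed[[side]][, c("rank", "gene")])
    expect_equal(fit$rankings$perturbed[[side]]$ripple,
                 fit2$rankings$perturbed[[side]]$ripple,
                 tolerance = 1e-9)
  }
})
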