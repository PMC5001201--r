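# base fixture: E -> M -> X plus Y -> E, all genes expressed
zone_fit <- function(control = c(E = 2, M = 5, X = 8, Y = 3),
                     perturbed = c(E = 2, M = 6, X = 2, Y = 12),
                     edges = data.frame(from = c("E", "M", "Y"),
                                        to = c("M", "X", "E"))) {
  fake_fit(edges, control, perturbed,
           cshan_perturbed_paths = list(c("E", "M", "X")),
           cshan_control_paths = list(c("Y", "E", "M")))
}

test_that("an isolated epicenter yields only the input row", {
  # A has no expression, so E keeps no neighbors in the condition network
  fit <- fake_fit(data.frame(from = c("E", "A"), to = c("A", "B")),
                  c(E = 1, B = 1), c(E = 1, B = 4),
                  cshan_perturbed_paths = list(),
                  cshan_control_paths = list())
  rep <- influence_zone(fit, "E", graph = "full")
  expect_equal(nrow(rep$table), 1)
  expect_identical(rep$table$Direction, "input_node")
  expect_identical(rep$table$Num_hops, 0L)
})

test_that("direct and two-hop neighbors are reported with intermediates", {
  fit <- zone_fit()
  rep <- influence_zone(fit, "E", graph = "full", hops = 2,
                        fc_cutoff = 2, augment_from_full = "none")
  tab <- rep$table
  expect_identical(tab$Node[1], "E")
  expect_identical(tab$Num_hops[1], 0L)

  # X: fc 0.25, two hops downstream through M (fc 1.2, not significant)
  rx <- tab[tab$Node == "X" & tab$Direction == "down_E", ]
  expect_equal(nrow(rx), 1)
  expect_identical(rx$Num_hops, 2L)
  expect_equal(rx$Fold_change, 0.25)
  expect_identical(rx$Intermediate_node_1, "M")
  expect_equal(rx$Intermediate_fold_change_1, 1.2)
  expect_false(rx$Intermediate_significant_fc_1)

  # Y: fc 4, one hop upstream, no intermediates
  ry <- tab[tab$Node == "Y", ]
  expect_identical(ry$Direction, "up_E")
  expect_identical(ry$Num_hops, 1L)
  expect_true(is.na(ry$Intermediate_node_1))

  # M (fc 1.2) fails the cutoff and gets no row of its own
  expect_false("M" %in% tab$Node)

  # which-network labels reflect CSHAN membership
  expect_identical(rx$Which_network, "unique to perturbed CSHAN")
  expect_identical(tab$Which_network[1], "common to both CSHANs")
})

test_that("a gene upstream and downstream within range gets two rows", {
  edges <- data.frame(from = c("E", "X"), to = c("X", "E"))
  fit <- fake_fit(edges, c(E = 1, X = 1), c(E = 1, X = 5))
  tab <- influence_zone(fit, "E", graph = "full",
                        augment_from_full = "none")$table
  expect_setequal(tab$Direction[tab$Node == "X"], c("down_E", "up_E"))
})

test_that("augmentation pulls dysregulated genes from the full network", {
  # Z is downregulated and reachable only in the full network
  edges <- data.frame(from = c("E", "M", "E"), to = c("M", "X", "Z"))
  fit <- fake_fit(edges,
                  c(E = 2, M = 5, X = 8, Z = 8),
                  c(E = 2, M = 6, X = 2, Z = 2),
                  cshan_perturbed_paths = list(c("E", "M", "X")),
                  cshan_control_paths = list())
  with_aug <- influence_zone(fit, "E", graph = "perturbed-cshan",
                             augment_from_full = "down")$table
  without <- influence_zone(fit, "E", graph = "perturbed-cshan",
                            augment_from_full = "none")$table
  expect_true("Z" %in% with_aug$Node)
  expect_false("Z" %in% without$Node)
  expect_identical(with_aug$Which_network[with_aug$Node == "Z"],
                   "not in any CSHAN")
})

test_that("zones are monotone in hops and in the fold-change cutoff", {
  fit <- default_fit()
  case <- default_case()
  ep <- case$manifest$planted
  z1 <- influence_zone(fit, ep, graph = "full", hops = 1,
                       augment_from_full = "none")
  z2 <- influence_zone(fit, ep, graph = "full", hops = 2,
                       augment_from_full = "none")
  expect_true(all(igraph::V(z1$zone)$name %in% igraph::V(z2$zone)$name))
  loose <- influence_zone(fit, ep, graph = "full", hops = 2,
                          fc_cutoff = 1.2, augment_from_full = "none")
  key <- function(t) paste(t$Node, t$Direction)
  expect_true(all(key(z2$table) %in% key(loose$table)))
})

test_that("reported hop counts equal brute-force BFS distances", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    e <- unique(data.frame(from = sample(nodes, 3 * n, TRUE),
                           to = sample(nodes, 3 * n, TRUE)))
    e <- e[e$from != e$to, ]
    w1 <- stats::setNames(runif(n, 1, 10), nodes)
    w2 <- stats::setNames(runif(n, 1, 10), nodes)
    fit <- fake_fit(e, w1, w2)
    ep <- sample(nodes, 1)
    rep <- influence_zone(fit, ep, graph = "full", hops = 3,
                          fc_cutoff = 1.01, augment_from_full = "none")
    dd <- oracle_bfs_dist(fit$networks$perturbed, ep, "out")
    du <- oracle_bfs_dist(fit$networks$perturbed, ep, "in")
    for (j in seq_len(nrow(rep$table))) {
      row <- rep$table[j, ]
      ref <- if (row$Direction == paste0("down_", ep)) dd[row$Node]
             else if (row$Direction == paste0("up_", ep)) du[row$Node]
             else 0L
      expect_equal(row$Num_hops, unname(as.integer(ref)))
    }
  }
})

test_that("the summary table round-trips through TSV exactly", {
  rep <- influence_zone(zone_fit(), "E", graph = "full", hops = 2,
                        augment_from_full = "none")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_influence_zone(rep, f)
  back <- read_influence_zone(f)
  expect_identical(names(back), names(rep$table))
  expect_equal(back, rep$table, tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("a missing epicenter names the graphs that do contain it", {
  fit <- zone_fit()
  err <- tryCatch(influence_zone(fit, "Y", graph = "perturbed-cshan"),
                  error = conditionMessage)
  expect_match(err, "control-cshan")
  expect_match(err, "full")
  expect_error(influence_zone(fit, "nope", graph = "full"), "no available")
})

test_that("combined zones union provenance and keep connectors", {
  fit <- zone_fit()
  single <- combined_influence_zone(fit, "E", graph = "full",
                                    augment_from_full = "none")
  expect_identical(single$reports[["E"]]$table,
                   influence_zone(fit, "E", graph = "full",
                                  augment_from_full = "none")$table)

  # disjoint zones stay disjoint with singleton provenance
  e2 <- data.frame(from = c("A", "C"), to = c("B", "D"))
  fit2 <- fake_fit(e2, c(A = 1, B = 1, C = 1, D = 1),
                   c(A = 1, B = 4, C = 1, D = 4))
  comb <- combined_influence_zone(fit2, c("A", "C"), graph = "full",
                                  hops = 1, augment_from_full = "none")
  expect_setequal(comb$provenance$epicenters[
    comb$provenance$node %in% c("A", "B")], "A")
  expect_setequal(comb$provenance$epicenters[
    comb$provenance$node %in% c("C", "D")], "C")

  # pruning to {E, T} keeps the connector a on E -> a -> T
  e3 <- data.frame(from = c("E", "a", "E"), to = c("a", "T", "junk"))
  fit3 <- fake_fit(e3, c(E = 1, a = 1, T = 1, junk = 1),
                   c(E = 1, a = 1, T = 4, junk = 1))
  pruned <- combined_influence_zone(fit3, "E", graph = "full", hops = 2,
                                    augment_from_full = "none",
                                    keep = c("E", "T"))
  expect_setequal(igraph::V(pruned$zone)$name, c("E", "a", "T"))
})
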