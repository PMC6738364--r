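# The selection and direction rules are exercised against the printed
# statistics of one N = 25 simulation draw (see helper-fixtures.R), for
# which the correct walk-through is known step by step.

test_that("seed-pair selection picks the most significant candidate and orients it", {
  eng <- replay_engine()
  edge <- select_first_target("A11", c("A21", "A22", "A31", "A32", "B"),
                              engine = eng)
  expect_equal(edge$source, "A11")
  expect_equal(edge$target, "A21")
  expect_equal(edge$value, 0.2146)       # tie on p = 0.0010, larger CID wins
  expect_equal(edge$p_value, 0.0010)
  expect_equal(edge$reverse_p, 0.0010)
  tab <- attr(edge, "all_results")
  expect_equal(nrow(tab), 5L)
})

test_that("seed selection returns discarded when nothing is significant", {
  eng <- replay_engine()
  expect_null(select_first_target("B", c("A11", "A21", "A22", "A31", "A32"),
                                  engine = eng))
  df <- data.frame(response = "S", predictor = c("T1", "T2"),
                   conditioning = "", value = c(0.5, 0.4), p_value = 1)
  expect_null(select_first_target("S", c("T1", "T2"),
                                  engine = cidnet:::.table_engine(df)))
})

test_that("ties on p-value and statistic fall back to lexicographic probe id", {
  df <- data.frame(response = c("S", "S", "T2", "T1"),
                   predictor = c("T2", "T1", "S", "S"),
                   conditioning = "", value = 0.3, p_value = 0.01)
  edge <- select_first_target("S", c("T2", "T1"),
                              engine = cidnet:::.table_engine(df))
  expect_equal(edge$target, "T1")        # candidate tie-break
  expect_equal(edge$source, "S")         # direction tie-break: S < T1
})

test_that("elongation follows the printed pCID walk-through step by step", {
  eng <- replay_engine()
  cand <- c("A22", "A31", "A32", "B")
  e1 <- elongation_step(c("A11", "A21"), cand, engine = eng, step = 1L)
  expect_equal(c(e1$source, e1$target), c("A11", "A22"))
  expect_equal(e1$value, 0.1679)         # p-tie 0.0010, 0.1679 > 0.1460
  e2 <- elongation_step(c("A11", "A21", "A22"), c("A31", "A32", "B"),
                        engine = eng, step = 2L)
  expect_equal(c(e2$source, e2$target), c("A21", "A31"))
  expect_equal(e2$value, 0.1751)         # p-tie 0.0020, 0.1751 > 0.1707
  e3 <- elongation_step(c("A11", "A21", "A22", "A31"), c("A32", "B"),
                        engine = eng, step = 3L)
  expect_equal(c(e3$source, e3$target), c("A21", "A32"))
  expect_equal(e3$p_value, 0.0070)       # 0.0070 < reverse 0.8392
  expect_equal(e3$reverse_p, 0.8392)
  # all remaining pCID(.|B; .) values insignificant -> stop
  expect_null(elongation_step(c("A11", "A21", "A22", "A31", "A32"), "B",
                              engine = eng, step = 4L))
})

test_that("the full walk-through reconstructs the generating topology and excludes B", {
  eng <- replay_engine()
  net <- build_subnetwork("A11", candidates = c("A21", "A22", "A31", "A32", "B"),
                          engine = eng)
  expect_false(net$discarded)
  expect_setequal(net$nodes, c("A11", "A21", "A22", "A31", "A32"))
  got <- net$edges[order(net$edges$step), c("source", "target")]
  expect_equal(got$source, c("A11", "A11", "A21", "A21"))
  expect_equal(got$target, c("A21", "A22", "A31", "A32"))
  expect_equal(length(net$nodes), nrow(net$edges) + 1L)  # e + 1 nodes
  netB <- build_subnetwork("B", candidates = c("A11", "A21", "A22", "A31", "A32"),
                           engine = eng)
  expect_true(netB$discarded)
})

test_that("supervised mode only allows designated sources to extend the path", {
  df <- rbind(
    data.frame(response = "S1", predictor = c("T1", "T2", "T3"),
               conditioning = "", value = c(0.5, 0.1, 0.1),
               p_value = c(0.001, 0.5, 0.5)),
    data.frame(response = "T1", predictor = "S1", conditioning = "",
               value = 0.2, p_value = 0.01),
    data.frame(response = "S1", predictor = c("T2", "T3"),
               conditioning = "T1", value = c(0.3, 0.2),
               p_value = c(0.01, 0.02)),
    data.frame(response = c("T2", "T3"), predictor = "S1",
               conditioning = "T1", value = c(0.1, 0.1), p_value = 0.5),
    data.frame(response = "T1", predictor = c("T2", "T3"),
               conditioning = "S1", value = 0.9, p_value = 0.0001),
    data.frame(response = c("T2", "T3"), predictor = "T1",
               conditioning = "S1", value = 0.1, p_value = 0.9),
    data.frame(response = "S1", predictor = "T3",
               conditioning = "T1,T2", value = 0.1, p_value = 0.5),
    data.frame(response = "T3", predictor = "S1",
               conditioning = "T1,T2", value = 0.1, p_value = 0.5),
    data.frame(response = "T1", predictor = "T3",
               conditioning = "S1,T2", value = 0.1, p_value = 0.5),
    data.frame(response = "T2", predictor = "T3",
               conditioning = "S1,T1", value = 0.1, p_value = 0.5))
  eng <- cidnet:::.table_engine(df)
  # unsupervised: T1 (on the path) wins step 1 with p 0.0001
  net_u <- build_subnetwork("S1", candidates = c("T1", "T2", "T3"), engine = eng)
  expect_true(any(net_u$edges$source == "T1"))
  # supervised: only S1 may act as source; its best (T2, p 0.01) wins instead
  net_s <- build_subnetwork("S1", candidates = c("T1", "T2", "T3"), engine = eng,
                            mode = "supervised", sources = "S1")
  expect_true(all(net_s$edges$source == "S1"))
  expect_setequal(net_s$nodes, c("S1", "T1", "T2"))
})

test_that("elongation halts after adding a target-only gene when requested", {
  df <- rbind(
    data.frame(response = "S1", predictor = c("X", "T9"), conditioning = "",
               value = c(0.6, 0.2), p_value = c(0.001, 0.01)),
    data.frame(response = "X", predictor = "S1", conditioning = "",
               value = 0.3, p_value = 0.01))
  rt <- role_table(c("S1", "X", "T9"), source_capable = c(TRUE, FALSE, FALSE),
                   target_capable = c(FALSE, TRUE, TRUE))
  net <- build_subnetwork("S1", candidates = c("X", "T9"),
                          engine = cidnet:::.table_engine(df),
                          role_table = rt, stop_on_target_only = TRUE)
  expect_equal(net$nodes, c("S1", "X"))
  expect_equal(nrow(net$edges), 1L)
  # a seed without source capability is refused outright
  expect_error(build_subnetwork("T9", candidates = "X",
                                engine = cidnet:::.table_engine(df),
                                role_table = rt), "not source-capable")
})

test_that("assembly merges duplicates, keeps conflicts, and drops isolated nodes", {
  e1 <- cidnet:::.edge_row("A", "M", 0L, "CID", 0.5, 0.001, 0.001, 0.01)
  e2 <- cidnet:::.edge_row("M", "B", 1L, "pCID", 0.3, 0.02, 0.02, 0.5)
  n1 <- cidnet:::.new_network(c("A", "M"), e1, "A")
  n2 <- cidnet:::.new_network(c("M", "B"), e2, "M")
  out <- assemble_networks(list(n1, n2))
  expect_setequal(out$nodes, c("A", "M", "B"))
  expect_equal(nrow(out$edges), 2L)

  # duplicate edge: smallest p wins
  e3 <- cidnet:::.edge_row("A", "M", 0L, "CID", 0.4, 0.02, 0.02, 0.3)
  out2 <- assemble_networks(list(n1, cidnet:::.new_network(c("A", "M"), e3, "A")))
  expect_equal(nrow(out2$edges), 1L)
  expect_equal(out2$edges$p_value, 0.001)

  # opposite directions are both retained and flagged
  e4 <- cidnet:::.edge_row("M", "A", 0L, "CID", 0.4, 0.02, 0.02, 0.3)
  expect_message(
    out3 <- assemble_networks(list(n1, cidnet:::.new_network(c("M", "A"), e4, "M"))),
    "conflicting directions")
  expect_equal(nrow(out3$edges), 2L)

  # discarded sub-networks contribute nothing
  disc <- cidnet:::.new_network("Z", cidnet:::.empty_edges(), "Z", discarded = TRUE)
  expect_equal(nrow(assemble_networks(list(n1, disc))$edges), 1L)
})

test_that("degree summaries and the power-law diagnostic are computed correctly", {
  hub <- do.call(rbind, lapply(paste0("t", 1:8), function(t)
    cidnet:::.edge_row("hub", t, 0L, "CID", 0.5, 0.001, 0.001, 0.01)))
  net <- cidnet:::.new_network(c("hub", paste0("t", 1:8)), hub, "hub")
  s <- network_summaries(net)
  expect_equal(s$degrees$out.degree[s$degrees$probe_id == "hub"], 8L)
  expect_equal(s$average_degree, 2 * 8 / 9)
  expect_lt(s$power_law_slope, 0)      # many leaves, one hub
  # single edge A -> B
  one <- cidnet:::.new_network(c("A", "B"),
                               cidnet:::.edge_row("A", "B", 0L, "CID", .5, .01, .01, .2),
                               "A")
  s1 <- network_summaries(one)
  expect_equal(s1$average_degree, 1.0)
  expect_equal(s1$degrees$in.degree[s1$degrees$probe_id == "B"], 1L)
  expect_error(network_summaries(cidnet:::.new_network("A", cidnet:::.empty_edges(), "A")),
               "empty")
})

test_that("average degree reproduces 2|E|/|V| at the published network size", {
  # 83 nodes, 107 edges -> 2 * 107 / 83 = 2.58
  expect_equal(round(2 * 107 / 83, 2), 2.58)
  set.seed(17)
  src <- paste0("g", sample(1:83, 107, replace = TRUE))
  tgt <- paste0("g", ((as.integer(sub("g", "", src)) + sample(1:82, 107, TRUE) - 1) %% 83) + 1)
  edges <- cidnet:::.edge_row(src, tgt, 0L, "CID", 0.5, 0.001, 0.001, 0.01)
  edges <- edges[!duplicated(edges[, 1:2]), ][1:90, ]
  net <- cidnet:::.new_network(unique(c(edges$source, edges$target)), edges, "assembled")
  s <- network_summaries(net)
  expect_equal(s$average_degree, 2 * nrow(net$edges) / length(net$nodes))
})

test_that("network construction is deterministic end to end", {
  d <- simulate_dataset(fig_network_spec(), 30, seed = 8)
  plan <- permutation_plan(60, seed = 77)
  n1 <- build_subnetwork("A11", d, plan)
  n2 <- build_subnetwork("A11", d, plan)
  expect_identical(n1$edges, n2$edges)
})
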