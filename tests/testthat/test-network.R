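test_that("the DE rule uses strict fold change > 2 and exact p thresholds", {
  # noiseless block at log2FC 2: always flagged
  sim <- gen_expression_matrix(
    50, 8, rep(c("stress", "ctrl"), each = 4),
    modules = list(list(genes = 1:10, condition = "stress", effect = 2)),
    noise_sd = 0, seed = 1)
  de <- call_de(sim, contrast = c("stress", "ctrl"))
  expect_true(all(de$de[1:10]))
  expect_false(any(de$de[11:50]))
  expect_equal(de$log2fc[1:10], rep(2, 10))

  # block at exactly log2FC 1: |FC| > 2 is strict, never flagged
  sim1 <- gen_expression_matrix(
    50, 8, rep(c("stress", "ctrl"), each = 4),
    modules = list(list(genes = 1:10, condition = "stress", effect = 1)),
    noise_sd = 0, seed = 2)
  de1 <- call_de(sim1, contrast = c("stress", "ctrl"))
  expect_equal(de1$log2fc[1:10], rep(1, 10))
  expect_false(any(de1$de))

  # down-regulation is symmetric
  simd <- gen_expression_matrix(
    20, 8, rep(c("stress", "ctrl"), each = 4),
    modules = list(list(genes = 1:5, condition = "ctrl", effect = 3)),
    noise_sd = 0, seed = 3)
  ded <- call_de(simd, contrast = c("stress", "ctrl"))
  expect_true(all(ded$de[1:5]))
  expect_true(all(ded$log2fc[1:5] == -3))
})

test_that("null expression matrices stay near the nominal false-call rate", {
  rates <- vapply(1:10, function(s) {
    sim <- gen_expression_matrix(2000, 10, rep(c("a", "b"), each = 5),
                                 noise_sd = 0.5, seed = 100 + s)
    mean(call_de(sim, contrast = c("a", "b"))$de)
  }, double(1))
  expect_lte(mean(rates), 0.05)
  expect_error(call_de(matrix(0, 5, 3), rep(c("a", "b"), c(1, 2)),
                       contrast = c("a", "b")),
               class = "promotif_input_error")
})

test_that("correlation networks connect identical profiles with weight 1", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = c(2, 3, 4, 5, 6, 7),
                g3 = c(6, 4, 2, 1, 3, 5))
  net <- build_network(expr, min_similarity = 0.9)
  e <- net$edges
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 1)
  expect_setequal(c(e$from, e$to), c("g1", "g2"))
})

test_that("null profiles produce few edges at threshold 0.7", {
  sim <- gen_expression_matrix(100, 12, rep(c("a", "b"), each = 6),
                               noise_sd = 1, seed = 5)
  net <- build_network(sim)
  n_pairs <- choose(100, 2)
  expect_lt(nrow(net$edges) / n_pairs, 0.02)
})

test_that("MCODE vertex weights match hand values on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  expect_equal(unname(mcode_weights(k5)), rep(4, 5))

  star <- igraph::graph_from_edgelist(
    cbind("c", paste0("l", 1:5)), directed = FALSE)
  w <- mcode_weights(star)
  expect_equal(unname(w[paste0("l", 1:5)]), rep(0, 5))
  expect_equal(unname(w["c"]), 0)

  # pendant on a K5: clique weighs 4, pendant 0
  el <- rbind(t(utils::combn(paste0("k", 1:5), 2)), c("k1", "p1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  w2 <- mcode_weights(g)
  expect_equal(unname(w2["p1"]), 0)
  expect_equal(unname(w2[paste0("k", 2:5)]), rep(4, 4))
})

test_that("MCODE weights equal the brute-force k-core oracle", {
  for (s in 1:30) {
    g <- random_graph(n = sample(4:8, 1), p = stats::runif(1, 0.2, 0.8),
                      seed = 300 + s)
    got <- mcode_weights(g)
    want <- brute_mcode_weights(adj_from_igraph(g), igraph::V(g)$name)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("two bridged K5 cliques resolve into exactly the two cliques", {
  mc <- mcode_complexes(barbell_graph())
  expect_length(mc$complexes, 2)
  expect_setequal(mc$complexes[[1]], paste0("a", 1:5))
  expect_setequal(mc$complexes[[2]], paste0("b", 1:5))
  expect_equal(mc$scores, c(5, 5))
})

test_that("haircut excludes pendant vertices and is idempotent", {
  el <- rbind(t(utils::combn(paste0("k", 1:5), 2)), c("k1", "p1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  mc <- mcode_complexes(g, haircut = TRUE, fluff = TRUE)
  expect_length(mc$complexes, 1)
  expect_setequal(mc$complexes[[1]], paste0("k", 1:5))
  # running the algorithm on its own output changes nothing (haircut fixpoint)
  sub <- igraph::induced_subgraph(g, mc$complexes[[1]])
  mc2 <- mcode_complexes(sub)
  expect_setequal(mc2$complexes[[1]], mc$complexes[[1]])
})

test_that("complex detection ignores edge-list order", {
  el <- igraph::as_edgelist(barbell_graph())
  set.seed(7)
  for (i in 1:5) {
    perm <- sample(nrow(el))
    flip <- sample(c(TRUE, FALSE), nrow(el), replace = TRUE)
    el2 <- el[perm, ]
    el2[flip, ] <- el2[flip, 2:1]
    mc <- mcode_complexes(igraph::graph_from_edgelist(el2, directed = FALSE))
    expect_length(mc$complexes, 2)
    expect_setequal(mc$complexes[[1]], paste0("a", 1:5))
    expect_setequal(mc$complexes[[2]], paste0("b", 1:5))
  }
})

test_that("edgeless graphs produce no complexes", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- letters[1:4]
  mc <- mcode_complexes(g)
  expect_length(mc$complexes, 0)
  expect_equal(nrow(tidy(mc)), 0)
})

test_that("anchor selection returns the anchor's complex or warns", {
  mc <- mcode_complexes(barbell_graph())
  expect_setequal(select_anchor_cluster(mc, "b3"), paste0("b", 1:5))
  expect_warning(out <- select_anchor_cluster(mc, "zz"), "not in any complex")
  expect_length(out, 0)
})

test_that("planted modules are recovered end to end through DE and MCODE", {
  sim_de <- gen_expression_matrix(
    60, 12, rep(c("ctrl", "s1", "s2"), each = 4),
    modules = list(list(genes = 1:20, condition = "s1", effect = 2)),
    noise_sd = 0.5, seed = 8)
  de <- call_de(sim_de, contrast = c("s1", "ctrl"))
  expect_gt(mean(de$de[1:20]), 0.8)
  sim <- gen_expression_matrix(
    60, 12, rep(c("ctrl", "s1", "s2"), each = 4),
    modules = list(list(genes = 1:20, condition = "s1", effect = 1.5),
                   list(genes = 21:40, condition = "s2", effect = 1.5)),
    noise_sd = 0.5, module_cor = 0.8, seed = 8)
  mc <- mcode_complexes(build_network(sim))
  m1 <- sprintf("g%05d", 1:20)
  j <- max(vapply(mc$complexes, jaccard, double(1), b = m1))
  expect_gte(j, 0.8)
  anchor <- select_anchor_cluster(mc, "g00001")
  expect_gte(jaccard(anchor, m1), 0.8)
})
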