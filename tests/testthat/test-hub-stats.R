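test_that("hypergeometric upper tail matches hand-enumerated values", {
  expect_equal(hypergeomUpperTail(6, 3, 3, 2), 0.5)        # 10/20
  expect_equal(hypergeomUpperTail(10, 4, 3, 2), 1 / 3)     # 40/120
  expect_equal(hypergeomUpperTail(6, 3, 3, 1), 0.95)       # 19/20
  expect_equal(hypergeomUpperTail(50, 10, 7, 0), 1)
  expect_equal(hypergeomUpperTail(6, 3, 1, 1), 0.5)        # 3/6
})

test_that("hypergeometric tail validates its parameter bounds", {
  expect_error(hypergeomUpperTail(6, 7, 3, 2), "K <= N")
  expect_error(hypergeomUpperTail(6, 3, 7, 2), "n <= N")
  expect_error(hypergeomUpperTail(6, 3, 3, 4), "min\\(n, K\\)")
})

test_that("tail probability is monotone in k and bounded by 1", {
  for (par in list(c(20, 8, 6), c(12, 3, 9), c(40, 20, 15))) {
    N <- par[1]; K <- par[2]; n <- par[3]
    ks <- 0:min(n, K)
    p <- hypergeomUpperTail(rep(N, length(ks)), K, n, ks)
    expect_true(all(diff(p) < 0))   # strictly decreasing in k
    expect_true(all(p > 0 & p <= 1))
    expect_equal(p[1], 1)
  }
})

test_that("log-space tail agrees with phyper at database scale", {
  cases <- rbind(c(20000, 500, 300, 20), c(20000, 500, 300, 2),
                 c(15000, 462, 250, 30), c(30000, 1000, 50, 10))
  for (i in seq_len(nrow(cases))) {
    N <- cases[i, 1]; K <- cases[i, 2]; n <- cases[i, 3]; k <- cases[i, 4]
    ref <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(hypergeomUpperTail(N, K, n, k), ref, tolerance = 1e-12)
  }
})

test_that("node scores on the toy fixture match the hand trace", {
  db <- toyDb()
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  a <- scoreNode(db, cs, "A")
  expect_equal(a[, c("n", "k", "p_raw")],
               data.frame(n = 3L, k = 2L, p_raw = 0.5))
  e <- scoreNode(db, cs, "E")
  expect_equal(e[, c("n", "k", "p_raw")],
               data.frame(n = 3L, k = 1L, p_raw = 0.95))
  f <- scoreNode(db, cs, "F")
  expect_equal(f[, c("n", "k", "p_raw")],
               data.frame(n = 1L, k = 1L, p_raw = 0.5))
  expect_error(scoreNode(db, cs, "Q"), "unknown node")
})

test_that("BH adjustment reproduces hand step-up values and input order", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.8)),
               c(0.02, 0.02, 0.04, 0.8))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(0.5, 0.8, 0.5, 0.8, 0.95, 0.5)), rep(0.95, 6))
  expect_error(bhAdjust(c(0.5, 0)), "invalid p-value")
  expect_error(bhAdjust(c(0.5, 1.2)), "invalid p-value")
  expect_error(bhAdjust(numeric(0)), "invalid p-value")
})

test_that("BH contract: adjusted >= raw and order preserved on sorted scale", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(adj, stepUpOracle(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("network scoring uses database-wide n and the network BH family", {
  db <- toyDb()
  ci <- toyContext(c("B", "E"))
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  net <- buildNetwork(db, ci)
  sc <- scoreNetwork(db, net, cs)
  expect_equal(nrow(sc), 6L)
  a <- sc[sc$node == "A", ]
  expect_equal(a$n, 3L); expect_equal(a$k, 2L)
  expect_equal(a$p_raw, 0.5); expect_equal(a$p_adj, 0.95)
  # two-node family: m = 2
  db2 <- buildInteractionDb(parseEdgeList("S\tX"))
  cs2 <- resolveContext(parseContextTable(c("gene", "X"), "gene", "all"), db2)
  sc2 <- scoreNetwork(db2, buildNetwork(db2, parseContextTable(
    c("gene", "S"), "gene", "all")), cs2)
  expect_equal(nrow(sc2), 2L)
  expect_equal(sc2$p_adj, bhAdjust(sc2$p_raw))
})

test_that("a node's own contextual label does not enter its score", {
  db <- toyDb()
  withCtxB <- resolveContext(toyContext(c("B", "C", "E")), db)
  # F's only interactor is E; B's label is irrelevant to F
  f1 <- scoreNode(db, withCtxB, "F")
  expect_equal(f1$k, 1L)
  # E is contextual but is not its own interactor: k counts C only among
  # {C, D, F}
  e1 <- scoreNode(db, withCtxB, "E")
  expect_equal(e1$k, 1L)
})

test_that("hub rankings order deterministically under both criteria", {
  db <- toyDb()
  ci <- toyContext(c("B", "E"))
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  sc <- scoreNetwork(db, buildNetwork(db, ci), cs)
  rkD <- rankHubs(sc, "degree", 3)
  expect_setequal(topNodes(rkD), c("A", "C", "E"))  # all db_degree 3
  # degree ties break by ascending p_adj then node id; here p_adj ties at
  # 0.95, so lexicographic
  expect_equal(topNodes(rkD), c("A", "C", "E"))
  rkC <- rankHubs(sc, "contextual", 1)
  expect_equal(rkC@table$p_adj[1], min(sc$p_adj))
  # tie-break chain on exact constructed scores: p_adj, p_raw, -k,
  # -db_degree, node
  tied <- data.frame(
    node = c("V", "W", "X", "Y", "Z"),
    n = c(5L, 5L, 5L, 4L, 5L), k = c(2L, 3L, 3L, 3L, 3L),
    db_degree = c(5L, 5L, 5L, 4L, 5L),
    p_raw = c(0.2, 0.2, 0.2, 0.2, 0.1),
    p_adj = c(0.4, 0.4, 0.4, 0.4, 0.4))
  expect_equal(rankingTable(rankHubs(tied, "contextual", 5))$node,
               c("Z", "W", "X", "Y", "V"))
  big <- rankHubs(sc, "contextual", 50)
  expect_equal(big@top, 6L)   # no padding beyond the family
  expect_error(rankHubs(sc, "betweenness"), "invalid criterion")
})

test_that("permuting score rows leaves the ranking unchanged", {
  db <- toyDb()
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  sc <- scoreNetwork(db, buildNetwork(db, toyContext(c("B", "E"))), cs)
  set.seed(5)
  perm <- sc[sample(nrow(sc)), ]
  for (crit in c("contextual", "degree")) {
    expect_equal(rankingTable(rankHubs(perm, crit, 6))$node,
                 rankingTable(rankHubs(sc, crit, 6))$node)
  }
})

test_that("ranking overlap is measured by shared set and Jaccard", {
  db <- toyDb()
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  sc <- scoreNetwork(db, buildNetwork(db, toyContext(c("B", "E"))), cs)
  rkC <- rankHubs(sc, "contextual", 6)
  same <- compareRankings(rkC, rkC)
  expect_equal(same$jaccard, 1)
  # top-3 lists sharing 1 node with 5 in the union
  a <- rankHubs(sc, "contextual", 3)
  fake <- sc[sc$node %in% c("A", "B", "D"), ]
  b <- rankHubs(fake, "degree", 3)
  ov <- compareRankings(a, b)
  expect_equal(length(union(topNodes(a), topNodes(b))), 5L)
  expect_equal(ov$nShared, 1L)
  expect_equal(ov$jaccard, 0.2)
})

test_that("node analyzer lists interactors contextual-first", {
  db <- toyDb()
  ci <- toyContext(c("B", "E"))
  cs <- resolveContext(toyContext(c("B", "C", "E")), db)
  net <- buildNetwork(db, ci)
  sc <- scoreNetwork(db, net, cs)
  repA <- nodeReport(db, sc, net, cs, "A")
  expect_equal(repA$interactors$interactor, c("B", "C", "D"))
  expect_equal(repA$interactors$contextual, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(repA$interactors), sc$n[sc$node == "A"])
  repF <- nodeReport(db, sc, net, cs, "F")
  expect_equal(repF$interactors$interactor, "E")
  expect_true(repF$interactors$contextual)
  expect_error(nodeReport(db, sc, net, cs, "Q"), "node not in network")
})

test_that("super-uniformity holds for null-labeled toy-scale databases", {
  set.seed(23)
  pvals <- c()
  for (rep in 1:30) {
    sim <- generateNull(syntheticSpec(40, edgeProb = 0.12, K = 8,
                                      seed = 1000 + rep))
    cs <- resolveContext(sim$context, sim$db)
    for (v in dbNodes(sim$db)) {
      pvals <- c(pvals, scoreNode(sim$db, cs, v)$p_raw)
    }
  }
  for (alpha in c(0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + 3 * se)
  }
})
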