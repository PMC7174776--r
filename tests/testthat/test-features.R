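test_that("type-1 features count associations and bin similarities", {
  A <- association_matrix(matrix(c(1, 0, 1, 0, 0, 0), 2, 3),
                          c("m1", "m2"), c("d1", "d2", "d3"))
  sim <- similarity_matrix(matrix(1, 2, 2), c("m1", "m2"), role = "MMS")
  f <- type1_features("m1", "mirna", A, sim, feature_config())
  expect_equal(unname(f[["num.ass"]]), 2)
  expect_equal(unname(f[["me.sim"]]), 1)
  # one other entity with similarity 1.0 falls in the last (closed) bin
  expect_equal(unname(f[paste0("dis.sim.", 1:5)]), c(0, 0, 0, 0, 1),
               ignore_attr = TRUE)
  f2 <- type1_features("m2", "mirna", A, sim)
  expect_equal(unname(f2[["num.ass"]]), 0)

  # a similarity row of all 1.0 against 4 others lands entirely in bin 5
  sim5 <- similarity_matrix(matrix(1, 5, 5), paste0("e", 1:5), role = "MMS")
  A5 <- association_matrix(matrix(0, 5, 2), paste0("e", 1:5), c("d1", "d2"))
  f5 <- type1_features("e1", "mirna", A5, sim5)
  expect_equal(unname(f5[paste0("dis.sim.", 1:5)]), c(0, 0, 0, 0, 4),
               ignore_attr = TRUE)

  # histogram always partitions the other entities
  set.seed(3)
  v <- matrix(runif(64), 8); v <- (v + t(v)) / 2; diag(v) <- 1
  simr <- similarity_matrix(v, paste0("e", 1:8), role = "MMS")
  Ar <- association_matrix(matrix(0, 8, 2), paste0("e", 1:8), c("x", "y"))
  fr <- type1_features("e3", "mirna", Ar, simr)
  expect_equal(sum(fr[paste0("dis.sim.", 1:5)]), 7)

  expect_error(type1_features("nope", "mirna", A, sim), "unknown")
})

test_that("entity graph links pairs strictly above the off-diagonal mean", {
  ids <- c("a", "b", "c")
  const <- similarity_matrix(matrix(.5, 3, 3) + diag(3) * .5, ids,
                             role = "MMS")
  g0 <- build_entity_graph(const)
  expect_equal(igraph::ecount(g0$graph), 0)   # nothing exceeds the mean

  v <- matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3)
  g1 <- build_entity_graph(similarity_matrix(v, ids, role = "MMS"))
  expect_equal(igraph::ecount(g1$graph), 1)   # only the 0.9 pair
  expect_true(igraph::are_adjacent(g1$graph, 1, 2))
  expect_false(igraph::is_directed(g1$graph))
})

test_that("type-2 features: degree, padded top similarities, centralities", {
  # 3-node star: centre has normalized betweenness 1
  v <- matrix(c(1, .9, .9, .9, 1, .1, .9, .1, 1), 3)
  ids <- c("ctr", "u", "w")
  sim <- similarity_matrix(v, ids, role = "MMS")
  g <- build_entity_graph(sim)
  f <- type2_features("ctr", g, sim, feature_config(k_sim = 2))
  expect_equal(unname(f[["num.nb"]]), 2)
  expect_equal(unname(f[["bt"]]), 1)
  expect_equal(unname(f[c("k.sim.1", "k.sim.2")]), c(.9, .9),
               ignore_attr = TRUE)

  # isolated node: everything zero except the padded similarities
  iso <- similarity_matrix(matrix(.5, 3, 3) + diag(3) * .5, ids,
                           role = "MMS")
  gi <- build_entity_graph(iso)
  fi <- type2_features("u", gi, iso, feature_config(k_sim = 2))
  expect_equal(unname(fi[c("num.nb", "bt", "cl")]), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(fi[c("k.sim.1", "k.sim.2")]), c(.5, .5),
               ignore_attr = TRUE)
})

test_that("centralities agree with brute-force BFS oracles on random
           graphs up to 8 nodes", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(3:8, 1)
    adj <- matrix(rbinom(n * n, 1, 0.4), n)
    adj <- (adj | t(adj)) * 1
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    eg <- structure(list(graph = g, nodes = as.character(seq_len(n))),
                    class = "entity_graph")
    cent <- chlmda:::.centralities(eg)
    expect_equal(cent$bt, oracle_betweenness(adj), tolerance = 1e-10)
    expect_equal(cent$cl, oracle_closeness(adj), tolerance = 1e-10)
  }
})

test_that("type-3 features count cross-neighbour associations and use the
           bipartite graph centralities", {
  A <- association_matrix(rbind(c(1, 1, 0), c(0, 1, 0)),
                          c("m1", "m2"), c("d1", "d2", "d3"))
  # disease graph: only d1 -- d2 exceeds the off-diagonal mean;
  # miRNA graph: constant off-diagonal, hence no edges
  dsim <- similarity_matrix(rbind(c(1, .9, .1), c(.9, 1, .1),
                                  c(.1, .1, 1)),
                            c("d1", "d2", "d3"), role = "DMS")
  msim <- similarity_matrix(matrix(.1, 2, 2) + diag(2) * .9,
                            c("m1", "m2"), role = "MMS")
  dg <- build_entity_graph(dsim)
  mg <- build_entity_graph(msim)
  expect_equal(igraph::ecount(dg$graph), 1)
  expect_equal(igraph::ecount(mg$graph), 0)
  f <- type3_features(c("m1", "d1"), A, mg, dg)
  # d1's only neighbour is d2 and A[m1, d2] = 1
  expect_equal(unname(f[["m.d.nb"]]), 1)
  # m1 has no neighbours
  expect_equal(unname(f[["d.m.nb"]]), 0)

  # bipartite centralities match the BFS oracle; node order is
  # (m1, m2, d1, d2, d3) with edges m1-d1, m1-d2, m2-d2
  adj <- matrix(0, 5, 5)
  adj[1, 3] <- adj[1, 4] <- adj[2, 4] <- 1
  adj <- adj + t(adj)
  expect_equal(unname(f[c("m.d.bt", "m.d.cl")]),
               c(oracle_betweenness(adj)[1], oracle_closeness(adj)[1]),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unname(f[c("d.m.bt", "d.m.cl")]),
               c(oracle_betweenness(adj)[3], oracle_closeness(adj)[3]),
               ignore_attr = TRUE, tolerance = 1e-10)

  # zero association matrix: all four centralities are 0
  A0 <- association_matrix(matrix(0, 2, 3), c("m1", "m2"),
                           c("d1", "d2", "d3"))
  f0 <- type3_features(c("m1", "d1"), A0, mg, dg)
  expect_equal(unname(f0[c("m.d.bt", "m.d.cl", "d.m.bt", "d.m.cl")]),
               rep(0, 4), ignore_attr = TRUE)
})

test_that("assembled table has the documented width, is deterministic, and
           matches the per-entity operations row by row", {
  ds <- small_planted()
  sims <- suppressWarnings(multi_similarity(ds$A, ds$SM, ds$dag))
  cfg <- feature_config()
  pos <- positive_pairs(ds$A)
  ft <- assemble_pair_features(ds$A, sims$MMS, sims$DMS, cfg, pos)
  expect_equal(ncol(ft$X), 2 * (2 + 5) + 2 * (3 + 20) + 6)  # 66
  expect_true(all(is.finite(ft$X)))
  expect_setequal(unlist(ft$blocks), seq_len(ncol(ft$X)))
  expect_true(all(rowSums(ft$Y) == 1))

  ft2 <- assemble_pair_features(ds$A, sims$MMS, sims$DMS, cfg, pos)
  expect_identical(ft$X, ft2$X)

  # one row cross-checked against the standalone feature operations
  i <- 5L
  m <- pos$mirna[[i]]; d <- pos$disease[[i]]
  mg <- build_entity_graph(reindex_similarity(sims$MMS, ds$A$mirna_ids))
  dg <- build_entity_graph(reindex_similarity(sims$DMS, ds$A$disease_ids))
  row <- c(type1_features(m, "mirna", ds$A, sims$MMS, cfg),
           type1_features(d, "disease", ds$A, sims$DMS, cfg),
           type2_features(m, mg, sims$MMS, cfg),
           type2_features(d, dg, sims$DMS, cfg),
           type3_features(c(m, d), ds$A, mg, dg))
  expect_equal(unname(ft$X[i, ]), unname(row), tolerance = 1e-12)
})

test_that("negative sampling avoids positives, honours the seed, and
           errors when the pool is too small", {
  ds <- small_planted()
  cfg <- feature_config(rng_seed = 11)
  neg <- sample_negatives(ds$A, 10, cfg)
  expect_equal(nrow(neg), 10)
  expect_true(all(ds$A$values[cbind(match(neg$mirna, ds$A$mirna_ids),
                                    match(neg$disease, ds$A$disease_ids))]
                  == 0))
  expect_identical(sample_negatives(ds$A, 10, cfg), neg)
  neg2 <- sample_negatives(ds$A, 10, feature_config(rng_seed = 12))
  expect_false(identical(neg, neg2))

  tiny <- association_matrix(matrix(c(1, 1, 1, 0), 2, 2),
                             c("m1", "m2"), c("d1", "d2"))
  expect_error(sample_negatives(tiny, 5, cfg), "candidate negatives")

  # exclusion list is respected
  excl <- chlmda:::.zero_pairs(ds$A)[1:5, ]
  neg3 <- sample_negatives(ds$A, nrow(chlmda:::.zero_pairs(ds$A)) - 5,
                           feature_config(rng_seed = 3), exclude = excl)
  expect_false(any(paste(neg3$mirna, neg3$disease) %in%
                     paste(excl$mirna, excl$disease)))
})
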