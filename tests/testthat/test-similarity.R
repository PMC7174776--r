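test_that("model-1 contribution is -log of the DAG frequency", {
  # corpus of 100 single-term diseases plus a shared root exercises the
  # counting directly
  n <- 100
  edges <- cbind("root", paste0("d", seq_len(n)))
  corpus <- dag_corpus(disease_dag(edges), paste0("d", seq_len(n)))
  expect_equal(d1_contribution("root", corpus), 0)       # in all DAGs
  expect_equal(d1_contribution("d1", corpus), log(100))  # in exactly one
  # a term in 10 of 100 DAGs: give 10 diseases a shared mid-level parent
  edges2 <- rbind(cbind("root", "mid"),
                  cbind("mid", paste0("d", 1:10)),
                  cbind("root", paste0("d", 11:100)))
  corpus2 <- dag_corpus(disease_dag(edges2), paste0("d", seq_len(n)))
  expect_equal(d1_contribution("mid", corpus2), log(10), tolerance = 1e-12)
  expect_error(d1_contribution("absent", corpus), "no disease DAG")
})

test_that("model-2 contributions decay per generation", {
  chain <- dag_corpus(disease_dag(rbind(c("r", "a"), c("a", "dis"))), "dis")
  c2 <- d2_contribution("dis", chain, delta_sc = 0.5)
  expect_equal(c2$d2[["dis"]], 1)
  expect_equal(c2$d2[["a"]], 0.5)
  expect_equal(c2$d2[["r"]], 0.25)
  expect_equal(c2$dv2, 1.75)

  single <- dag_corpus(disease_dag(NULL, nodes = "solo"), "solo")
  s <- d2_contribution("solo", single)
  expect_equal(s$d2, c(solo = 1))
  expect_equal(s$dv2, 1)

  diamond <- dag_corpus(disease_dag(rbind(c("r", "a"), c("r", "b"),
                                          c("a", "dis"), c("b", "dis"))),
                        "dis")
  d <- d2_contribution("dis", diamond, delta_sc = 0.5)
  expect_equal(d$d2[["r"]], 0.25)  # max over the two 0.25 paths

  expect_error(d2_contribution("dis", chain, delta_sc = 0), "delta_sc")
  expect_error(d2_contribution("dis", chain, delta_sc = 1.5), "delta_sc")
})

test_that("semantic similarity is 1 on the diagonal, 0 for disjoint DAGs,
           symmetric, and matches a brute-force shared-term sum", {
  corpus <- toy_corpus()
  for (model in 1:2) {
    expect_equal(semantic_similarity("b", "b", corpus, model), 1)
    expect_equal(semantic_similarity("b", "c", corpus, model),
                 semantic_similarity("c", "b", corpus, model))
  }
  # disjoint: two separate roots
  dj <- dag_corpus(disease_dag(rbind(c("r1", "x"), c("r2", "y"))),
                   c("x", "y"))
  expect_equal(semantic_similarity("x", "y", dj, 1), 0)
  expect_equal(semantic_similarity("x", "y", dj, 2), 0)

  # brute force for model 1 on the 4-term toy corpus: T(b)={b,a,r},
  # T(c)={c,a,r}, shared {a,r}; D1(t) = -log(n_t/3)
  d1 <- function(t) {
    n_t <- sum(vapply(corpus$term_sets, function(ts) t %in% ts, logical(1)))
    -log(n_t / 3)
  }
  num <- sum(vapply(c("a", "r"), function(t) 2 * d1(t), 1))
  den <- sum(vapply(c("b", "a", "r"), d1, 1)) +
    sum(vapply(c("c", "a", "r"), d1, 1))
  expect_equal(semantic_similarity("b", "c", corpus, 1), num / den,
               tolerance = 1e-12)

  # matrix route agrees with the pairwise route on random corpora
  for (seed in 1:3) {
    dag <- simulate_dag(15, branching = 2, seed = seed)
    cp <- dag_corpus(dag, dag$nodes[6:15])
    for (model in 1:2) {
      S <- semantic_similarity_matrix(cp, model)
      expect_identical(S$values, t(S$values))
      expect_true(all(diag(S$values) == 1))
      i <- cp$diseases[[2]]; j <- cp$diseases[[7]]
      expect_equal(S$values[i, j],
                   semantic_similarity(i, j, cp, model), tolerance = 1e-12)
    }
  }
})

test_that("fuse_sd averages elementwise", {
  ids <- c("a", "b")
  s1 <- similarity_matrix(matrix(c(1, .4, .4, 1), 2), ids, role = "SD1")
  s2 <- similarity_matrix(matrix(c(1, .6, .6, 1), 2), ids, role = "SD2")
  expect_equal(fuse_sd(s1, s2)$values[1, 2], 0.5)
  expect_equal(fuse_sd(s1, s1)$values, s1$values)
  s3 <- similarity_matrix(diag(2), c("a", "c"), role = "SD2")
  expect_error(fuse_sd(s1, s3), "mismatch")
})

test_that("WKNNP keeps known links, only raises entries, and propagates
           across duplicate profiles", {
  A <- association_matrix(matrix(c(1, 0, 0, 0), 2, 2),
                          c("m1", "m2"), c("d1", "d2"))
  # zero similarity: nothing propagates
  S0m <- similarity_matrix(matrix(0, 2, 2), c("m1", "m2"))
  S0d <- similarity_matrix(matrix(0, 2, 2), c("d1", "d2"))
  out0 <- suppressWarnings(wknnp_complete(A, S0m, S0d, wknnp_config(K = 1)))
  expect_equal(out0$values, A$values)

  # duplicate rows with similarity 1, K=1: m1's link reaches m2's estimate
  # at value 1 before averaging with the column side
  Sm <- similarity_matrix(matrix(c(1, 1, 1, 1), 2), c("m1", "m2"))
  out <- wknnp_complete(A, Sm, S0d, wknnp_config(K = 1))
  expect_equal(out$values["m2", "d1"], 0.5)  # (row est 1 + col est 0)/2
  expect_equal(out$values["m1", "d1"], 1)    # known stays 1
  expect_true(all(out$values >= A$values))

  # monotone: raising an input entry never lowers any output entry
  ds <- small_planted()
  SD <- similarity_matrix(diag(length(ds$A$disease_ids)) * 0 + 0.3 +
                            diag(length(ds$A$disease_ids)) * 0.7,
                          ds$A$disease_ids)
  base <- wknnp_complete(ds$A, ds$SM, SD, wknnp_config(K = 5))
  bumped <- ds$A$values
  zero_at <- which(bumped == 0)[1]
  bumped[zero_at] <- 1
  Ab <- association_matrix(bumped, ds$A$mirna_ids, ds$A$disease_ids)
  out_b <- wknnp_complete(Ab, ds$SM, SD, wknnp_config(K = 5))
  expect_true(all(out_b$values - base$values >= -1e-12))

  # K larger than both entity counts warns once per side
  w <- capture_warnings(wknnp_complete(A, Sm, S0d, wknnp_config(K = 10)))
  expect_length(w, 2)
  expect_match(w, "truncated", all = TRUE)
})

test_that("Gipk bandwidth and kernel follow the profile norms", {
  expect_equal(gipk_bandwidth(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(gipk_bandwidth(diag(2) / sqrt(1)), 1)
  expect_equal(gipk_bandwidth(2 * rbind(c(1, 0), c(0, 1))),
               1 / 4)                         # scaling by 2 divides by 4
  expect_error(gipk_bandwidth(matrix(0, 2, 2)), "zero")

  G <- gipk_similarity(rbind(c(1, 0), c(0, 1)), ids = c("p", "q"))
  expect_equal(unname(diag(G$values)), c(1, 1))
  expect_equal(G$values[1, 2], exp(-2), tolerance = 1e-12)

  prof <- matrix(rbinom(60, 1, .4), 10)
  rownames(prof) <- paste0("e", 1:10)
  G2 <- gipk_similarity(prof)
  expect_identical(G2$values, t(G2$values))
  expect_true(all(G2$values > 0 & G2$values <= 1))
  # identical profiles give similarity 1
  prof[2, ] <- prof[1, ]
  G3 <- gipk_similarity(prof)
  expect_equal(G3$values[1, 2], 1)
})

test_that("multi-similarity fusion takes the kernel where the base is zero
           and the average elsewhere", {
  ids <- c("a", "b", "c")
  base <- similarity_matrix(matrix(c(1, 0, .6, 0, 1, 0, .6, 0, 1), 3), ids)
  gip <- similarity_matrix(matrix(c(1, .4, .4, .4, 1, .4, .4, .4, 1), 3),
                           ids, role = "GIM")
  f <- fuse_multi_similarity(base, gip)
  expect_equal(f$values["a", "b"], 0.4)       # base 0 -> kernel
  expect_equal(f$values["a", "c"], 0.5)       # (0.6 + 0.4)/2
  expect_equal(fuse_multi_similarity(gip, gip)$values, gip$values)
  expect_true(all(f$values >= 0 & f$values <= 1))
})
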