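# Pair feature engineering: statistical summaries (type 1), similarity-graph
# topology (type 2) and association-matrix cross features (type 3), plus
# 1:1 negative sampling and label construction.

#' Feature configuration
#'
#' @param k_sim number of largest neighbour similarities kept as type-2
#'   features (default 20).
#' @param hist_bins number of equal-width bins over `[0, 1]` for the type-1
#'   similarity histogram (default 5).
#' @param negative_ratio negatives sampled per positive (default 1).
#' @param rng_seed integer seed for negative sampling.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(k_sim = 20, hist_bins = 5, negative_ratio = 1,
                           rng_seed = 1L) {
  if (k_sim < 1 || hist_bins < 1) stop("k_sim and hist_bins must be >= 1")
  if (negative_ratio <= 0) stop("negative_ratio must be positive")
  structure(list(k_sim = as.integer(k_sim), hist_bins = as.integer(hist_bins),
                 negative_ratio = negative_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "feature_config")
}

# evaluate expr under a temporary RNG state so callers stay unaffected
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.hist_counts <- function(v, bins) {
  # equal-width partition of [0,1], right-open except the last bin
  idx <- pmin(floor(v * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}

#' Threshold a similarity matrix into an entity graph
#'
#' Entities i and j (i != j) are linked iff their similarity strictly
#' exceeds the mean of all off-diagonal similarities. The graph is simple
#' and undirected.
#'
#' @param sim [similarity_matrix()].
#' @return Object of class `entity_graph`: fields `graph` (igraph), `nodes`,
#'   `source_role`, `threshold`.
#' @export
build_entity_graph <- function(sim) {
  v <- sim$values
  off <- v[row(v) != col(v)]
  thr <- mean(off)
  adj <- (v > thr)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, nodes = sim$ids, source_role = sim$role,
                 threshold = thr),
            class = "entity_graph")
}

#' Bipartite association graph
#'
#' Undirected graph over all miRNAs and diseases with an edge for every
#' known association; the substrate of the type-3 centrality features.
#'
#' @param A [association_matrix()].
#' @return `entity_graph` whose nodes are `c(mirna_ids, disease_ids)`.
#' @export
build_bipartite_graph <- function(A) {
  nm <- length(A$mirna_ids); nd <- length(A$disease_ids)
  adj <- matrix(FALSE, nm + nd, nm + nd)
  adj[seq_len(nm), nm + seq_len(nd)] <- A$values == 1
  adj[nm + seq_len(nd), seq_len(nm)] <- t(A$values == 1)
  nodes <- c(A$mirna_ids, A$disease_ids)
  dimnames(adj) <- list(nodes, nodes)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, nodes = nodes, source_role = "A-bipartite",
                 threshold = NA_real_),
            class = "entity_graph")
}

# normalized betweenness and Wasserman-Faust closeness for every vertex;
# isolated vertices get 0 for both
.centralities <- function(eg) {
  g <- eg$graph
  n <- igraph::vcount(g)
  bt <- if (n >= 3) igraph::betweenness(g, normalized = TRUE)
        else rep(0, n)
  bt[!is.finite(bt)] <- 0
  d <- igraph::distances(g)
  cl <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0L || sum(reach) == 0) return(0)
    # component-scaled closeness: (k/(n-1)) * (k / sum of distances)
    k <- length(reach)
    (k / (n - 1)) * (k / sum(reach))
  }, 1)
  list(bt = unname(bt), cl = cl)
}

#' Type-1 (statistical) features of an entity
#'
#' `num.ass`: number of known associations in the entity's row/column of A;
#' `me.sim`: mean similarity to all other entities (self excluded);
#' `dis.sim`: histogram of those similarities in `hist_bins` equal-width
#' bins over `[0, 1]`.
#'
#' @param entity identifier.
#' @param kind `"mirna"` or `"disease"`.
#' @param A [association_matrix()].
#' @param sim the entity's [similarity_matrix()] (MMS or DMS).
#' @param cfg [feature_config()].
#' @return Named numeric vector of length `2 + hist_bins`.
#' @export
type1_features <- function(entity, kind = c("mirna", "disease"), A, sim,
                           cfg = feature_config()) {
  kind <- match.arg(kind)
  ids <- if (kind == "mirna") A$mirna_ids else A$disease_ids
  i <- match(entity, ids)
  if (is.na(i)) stop("unknown ", kind, " '", entity, "'")
  num_ass <- if (kind == "mirna") sum(A$values[i, ] == 1)
             else sum(A$values[, i] == 1)
  srow <- sim$values[match(entity, sim$ids), ][-match(entity, sim$ids)]
  me_sim <- if (length(srow)) mean(srow) else 0
  h <- .hist_counts(srow, cfg$hist_bins)
  setNames(c(num_ass, me_sim, h),
           c("num.ass", "me.sim", paste0("dis.sim.", seq_len(cfg$hist_bins))))
}

#' Type-2 (graph-theoretic) features of an entity
#'
#' Degree in the thresholded similarity graph, the `k_sim` largest
#' similarities to other entities (descending, zero-padded), and normalised
#' betweenness and closeness in that graph.
#'
#' @param entity identifier.
#' @param graph [build_entity_graph()] output.
#' @param sim the [similarity_matrix()] the graph was built from.
#' @param cfg [feature_config()].
#' @return Named numeric vector of length `3 + k_sim`.
#' @export
type2_features <- function(entity, graph, sim, cfg = feature_config()) {
  i <- match(entity, graph$nodes)
  if (is.na(i)) stop("unknown entity '", entity, "'")
  cent <- .centralities(graph)
  deg <- igraph::degree(graph$graph)[[i]]
  srow <- sort(sim$values[match(entity, sim$ids), ][-match(entity, sim$ids)],
               decreasing = TRUE)
  ks <- rep(0, cfg$k_sim)
  take <- min(cfg$k_sim, length(srow))
  if (take > 0) ks[seq_len(take)] <- srow[seq_len(take)]
  setNames(c(deg, ks, cent$bt[[i]], cent$cl[[i]]),
           c("num.nb", paste0("k.sim.", seq_len(cfg$k_sim)), "bt", "cl"))
}

#' Type-3 (cross) features of a miRNA-disease pair
#'
#' `m.d.nb`: associations between the miRNA and the disease's
#' similarity-graph neighbours; `d.m.nb`: associations between the disease
#' and the miRNA's similarity-graph neighbours; plus betweenness and
#' closeness of both the miRNA node and the disease node in the bipartite
#' association graph.
#'
#' @param pair length-2 character vector `(mirna, disease)`.
#' @param A [association_matrix()].
#' @param mg miRNA entity graph (from MMS).
#' @param dg disease entity graph (from DMS).
#' @param bg optional precomputed [build_bipartite_graph()] output.
#' @return Named numeric vector of length 6.
#' @export
type3_features <- function(pair, A, mg, dg, bg = build_bipartite_graph(A)) {
  m <- pair[[1]]; d <- pair[[2]]
  mi <- match(m, A$mirna_ids); di <- match(d, A$disease_ids)
  if (is.na(mi) || is.na(di)) stop("unknown pair (", m, ", ", d, ")")
  d_nbrs <- igraph::neighbors(dg$graph, match(d, dg$nodes))
  m_nbrs <- igraph::neighbors(mg$graph, match(m, mg$nodes))
  md_nb <- if (length(d_nbrs)) sum(A$values[mi, as.integer(d_nbrs)] == 1)
           else 0
  dm_nb <- if (length(m_nbrs)) sum(A$values[as.integer(m_nbrs), di] == 1)
           else 0
  cent <- .centralities(bg)
  bi_m <- match(m, bg$nodes); bi_d <- match(d, bg$nodes)
  setNames(c(md_nb, dm_nb, cent$bt[[bi_m]], cent$cl[[bi_m]],
             cent$bt[[bi_d]], cent$cl[[bi_d]]),
           c("m.d.nb", "d.m.nb", "m.d.bt", "m.d.cl", "d.m.bt", "d.m.cl"))
}

# node-level feature tables computed once; pair rows are then lookups
.entity_feature_table <- function(A, sim, graph, cfg, kind) {
  ids <- if (kind == "mirna") A$mirna_ids else A$disease_ids
  n <- length(ids)
  num_ass <- if (kind == "mirna") rowSums(A$values == 1)
             else colSums(A$values == 1)
  cent <- .centralities(graph)
  deg <- igraph::degree(graph$graph)
  t1 <- matrix(0, n, 2L + cfg$hist_bins)
  t2 <- matrix(0, n, 3L + cfg$k_sim)
  for (i in seq_len(n)) {
    srow <- sim$values[i, -i]
    t1[i, ] <- c(num_ass[[i]], if (length(srow)) mean(srow) else 0,
                 .hist_counts(srow, cfg$hist_bins))
    ks <- rep(0, cfg$k_sim)
    srt <- sort(srow, decreasing = TRUE)
    take <- min(cfg$k_sim, length(srt))
    if (take > 0) ks[seq_len(take)] <- srt[seq_len(take)]
    t2[i, ] <- c(deg[[i]], ks, cent$bt[[i]], cent$cl[[i]])
  }
  p <- substr(kind, 1, 1)
  colnames(t1) <- paste0(p, ".t1.", c("num.ass", "me.sim",
                                      paste0("dis.sim.", seq_len(cfg$hist_bins))))
  colnames(t2) <- paste0(p, ".t2.", c("num.nb",
                                      paste0("k.sim.", seq_len(cfg$k_sim)),
                                      "bt", "cl"))
  rownames(t1) <- rownames(t2) <- ids
  list(t1 = t1, t2 = t2)
}

#' Assemble the pair feature table
#'
#' One row per (miRNA, disease) pair: type-1 and type-2 features of the
#' miRNA and of the disease, then the type-3 cross features. With default
#' configuration the row has `2*(2+5) + 2*(3+20) + 6 = 66` columns.
#'
#' @param A binary [association_matrix()] (the masked training matrix under
#'   cross-validation).
#' @param MMS,DMS fused multi-similarity matrices in `A`'s orders.
#' @param cfg [feature_config()].
#' @param pairs data.frame with columns `mirna`, `disease` and optionally
#'   `label` (1 = associated, 0 = not).
#' @return Object of class `pair_feature_table`: `X` (n x c matrix with
#'   `feature_names` as colnames), `Y` (n x 2 one-hot, column 1 = positive
#'   class) when labels are present, `pairs`, `feature_names`, and
#'   `blocks` (named list mapping feature family -> column indices).
#' @export
assemble_pair_features <- function(A, MMS, DMS, cfg = feature_config(),
                                   pairs) {
  stopifnot(nrow(pairs) > 0L)
  MMS <- reindex_similarity(MMS, A$mirna_ids)
  DMS <- reindex_similarity(DMS, A$disease_ids)
  mg <- build_entity_graph(MMS)
  dg <- build_entity_graph(DMS)
  bg <- build_bipartite_graph(A)
  mt <- .entity_feature_table(A, MMS, mg, cfg, "mirna")
  dt <- .entity_feature_table(A, DMS, dg, cfg, "disease")
  bcent <- .centralities(bg)

  nm <- length(A$mirna_ids)
  mi <- match(pairs$mirna, A$mirna_ids)
  di <- match(pairs$disease, A$disease_ids)
  if (anyNA(mi) || anyNA(di))
    stop("pair list contains identifiers absent from the association matrix")

  # type-3 neighbour counts via adjacency products
  m_adj <- as.matrix(igraph::as_adjacency_matrix(mg$graph))
  d_adj <- as.matrix(igraph::as_adjacency_matrix(dg$graph))
  Abin <- (A$values == 1) * 1
  md_nb <- Abin %*% d_adj     # [m, d]: associations of m with d's neighbours
  dm_nb <- m_adj %*% Abin     # [m, d]: associations of d with m's neighbours

  n <- nrow(pairs)
  t3 <- cbind(md_nb[cbind(mi, di)], dm_nb[cbind(mi, di)],
              bcent$bt[mi], bcent$cl[mi], bcent$bt[nm + di],
              bcent$cl[nm + di])
  colnames(t3) <- paste0("t3.", c("m.d.nb", "d.m.nb", "m.d.bt", "m.d.cl",
                                  "d.m.bt", "d.m.cl"))
  X <- cbind(mt$t1[mi, , drop = FALSE], dt$t1[di, , drop = FALSE],
             mt$t2[mi, , drop = FALSE], dt$t2[di, , drop = FALSE], t3)
  rownames(X) <- NULL
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature '%s' for pair (%s, %s)",
                 colnames(X)[bad[[2L]]], pairs$mirna[bad[[1L]]],
                 pairs$disease[bad[[1L]]]))
  }
  blocks <- list(
    type1 = grep("\\.t1\\.", colnames(X)),
    type2 = grep("\\.t2\\.", colnames(X)),
    type3 = grep("^t3\\.", colnames(X)))
  Y <- NULL
  if (!is.null(pairs$label)) {
    lab <- as.integer(pairs$label)
    Y <- cbind(positive = lab, negative = 1L - lab)
  }
  structure(list(X = X, Y = Y,
                 pairs = pairs[, c("mirna", "disease"), drop = FALSE],
                 feature_names = colnames(X), blocks = blocks),
            class = "pair_feature_table")
}

#' @export
print.pair_feature_table <- function(x, ...) {
  cat(sprintf("pair_feature_table: %d pairs x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (!is.null(x$Y)) sprintf(" (%d positive)", sum(x$Y[, 1]))
              else ""))
  invisible(x)
}

#' Sample negative miRNA-disease pairs
#'
#' Uniform sample without replacement from the zero entries of `A`,
#' reproducible from `cfg$rng_seed`.
#'
#' @param A [association_matrix()].
#' @param n_pos number of positive pairs to match.
#' @param cfg [feature_config()]; `negative_ratio * n_pos` pairs (rounded
#'   up) are drawn.
#' @param exclude optional data.frame of pairs (`mirna`, `disease`) that
#'   must not be sampled even though their `A` entry is 0 (e.g. masked
#'   test positives).
#' @return data.frame with columns `mirna`, `disease`, `label` (all 0).
#' @export
sample_negatives <- function(A, n_pos, cfg = feature_config(),
                             exclude = NULL) {
  want <- ceiling(cfg$negative_ratio * n_pos)
  zero <- which(A$values == 0)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ei <- match(exclude$mirna, A$mirna_ids)
    ej <- match(exclude$disease, A$disease_ids)
    zero <- setdiff(zero, (ej - 1L) * nrow(A$values) + ei)
  }
  if (length(zero) < want)
    stop("only ", length(zero), " candidate negatives for ", want,
         " requested")
  idx <- with_seed(cfg$rng_seed, sample(zero, want))
  data.frame(mirna = A$mirna_ids[(idx - 1L) %% nrow(A$values) + 1L],
             disease = A$disease_ids[(idx - 1L) %/% nrow(A$values) + 1L],
             label = 0L, stringsAsFactors = FALSE)
}

#' All positive pairs of an association matrix
#' @param A [association_matrix()].
#' @return data.frame with columns `mirna`, `disease`, `label` (all 1).
#' @export
positive_pairs <- function(A) {
  idx <- which(A$values == 1)
  data.frame(mirna = A$mirna_ids[(idx - 1L) %% nrow(A$values) + 1L],
             disease = A$disease_ids[(idx - 1L) %/% nrow(A$values) + 1L],
             label = 1L, stringsAsFactors = FALSE)
}
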