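# Cross-validation drivers with strict per-fold similarity recomputation,
# the rank-based AUC, and the feature-family ablation.

#' Full pipeline configuration
#'
#' Bundles every tunable of the prediction pipeline with its default.
#'
#' @param delta_sc semantic contribution factor (default 0.5).
#' @param wknnp [wknnp_config()].
#' @param features [feature_config()].
#' @param hypergraph [hypergraph_config()].
#' @param chl [chl_config()].
#' @param feature_blocks character subset of
#'   `c("type1", "type2", "type3")`; features outside the named families
#'   are dropped before training (default: all three).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_sc = 0.5, wknnp = wknnp_config(),
                            features = feature_config(),
                            hypergraph = hypergraph_config(),
                            chl = chl_config(),
                            feature_blocks = c("type1", "type2", "type3")) {
  feature_blocks <- match.arg(feature_blocks,
                              c("type1", "type2", "type3"),
                              several.ok = TRUE)
  structure(list(delta_sc = delta_sc, wknnp = wknnp, features = features,
                 hypergraph = hypergraph, chl = chl,
                 feature_blocks = feature_blocks),
            class = "pipeline_config")
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Probability that a random positive score exceeds a random negative
#' score, with half credit for ties:
#' `(sum over pairs of [pos > neg] + 1/2 [pos == neg]) / (n_pos * n_neg)`.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("both score sets must be non-empty")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

.cv_result <- function(auc_values, protocol, repeats,
                       fold_assignments = NULL) {
  structure(list(auc_values = auc_values, mean_auc = mean(auc_values),
                 sd_auc = if (length(auc_values) > 1) sd(auc_values) else 0,
                 fold_assignments = fold_assignments, protocol = protocol,
                 repeats = repeats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: mean AUC %.4f (sd %.4f) over %d value(s)\n",
              x$protocol, x$mean_auc, x$sd_auc, length(x$auc_values)))
  invisible(x)
}

.mask_pairs <- function(A, pairs) {
  v <- A$values
  if (nrow(pairs) > 0L)
    v[cbind(match(pairs$mirna, A$mirna_ids),
            match(pairs$disease, A$disease_ids))] <- 0
  association_matrix(v, A$mirna_ids, A$disease_ids)
}

.zero_pairs <- function(A) {
  idx <- which(A$values == 0)
  data.frame(mirna = A$mirna_ids[(idx - 1L) %% nrow(A$values) + 1L],
             disease = A$disease_ids[(idx - 1L) %/% nrow(A$values) + 1L],
             stringsAsFactors = FALSE)
}

#' Prepare one cross-validation fold
#'
#' Zeroes the test associations, then recomputes the entire similarity and
#' feature pipeline from the masked matrix only: WKNNP completion, Gipk
#' kernels, multi-similarity fusion, and the pair feature table. No
#' statistic derived from the held-out associations reaches the training
#' side.
#'
#' @param A_full binary [association_matrix()] with all known associations.
#' @param SM miRNA functional [similarity_matrix()].
#' @param dag [disease_dag()].
#' @param test_pairs data.frame (`mirna`, `disease`) of positives to hold
#'   out; must be 1-entries of `A_full`.
#' @param cfg [pipeline_config()].
#' @param fold_seed integer seed for the fold's negative sampling.
#' @return List: `train` (labelled [assemble_pair_features()] table:
#'   remaining positives + sampled negatives), `query` (feature table over
#'   the test pairs followed by all unknown candidate pairs), `test_idx`
#'   (row indices of the test pairs in `query`), `A_masked`, `sims`.
#' @export
prepare_fold <- function(A_full, SM, dag, test_pairs, cfg = pipeline_config(),
                         fold_seed = 1L) {
  if (nrow(test_pairs) > 0L) {
    ti <- cbind(match(test_pairs$mirna, A_full$mirna_ids),
                match(test_pairs$disease, A_full$disease_ids))
    if (anyNA(ti) || any(A_full$values[ti] != 1))
      stop("test pairs must be known associations of the full matrix")
  }
  A_masked <- .mask_pairs(A_full, test_pairs)
  sims <- multi_similarity(A_masked, SM, dag, cfg$delta_sc, cfg$wknnp)

  pos <- positive_pairs(A_masked)
  if (nrow(pos) == 0L) stop("no positives left after masking")
  fcfg <- cfg$features
  fcfg$rng_seed <- as.integer(fold_seed)
  neg <- sample_negatives(A_masked, nrow(pos), fcfg, exclude = test_pairs)
  train <- assemble_pair_features(A_masked, sims$MMS, sims$DMS, fcfg,
                                  rbind(pos, neg))

  cand <- .zero_pairs(A_masked)
  if (nrow(test_pairs) > 0L) {
    key <- paste(cand$mirna, cand$disease, sep = "\r")
    tkey <- paste(test_pairs$mirna, test_pairs$disease, sep = "\r")
    cand <- cand[!(key %in% tkey), , drop = FALSE]
    qpairs <- rbind(
      data.frame(mirna = test_pairs$mirna, disease = test_pairs$disease,
                 stringsAsFactors = FALSE), cand)
  } else qpairs <- cand
  query <- assemble_pair_features(A_masked, sims$MMS, sims$DMS, fcfg, qpairs)
  list(train = train, query = query,
       test_idx = seq_len(nrow(test_pairs)), A_masked = A_masked,
       sims = sims)
}

.restrict_cols <- function(features, blocks) {
  if (length(blocks) == 3L) return(NULL)
  sort(unlist(features$blocks[blocks], use.names = FALSE))
}

# default scorer: train the combinative hypergraph model on the fold's
# training table and score the query table
.chl_scorer <- function(cfg) {
  function(train, query, fold_seed) {
    hg_cfg <- cfg$hypergraph
    hg_cfg$rng_seed <- as.integer(fold_seed)
    hg_cfg$k1 <- min(hg_cfg$k1, nrow(train$X) - 1L)
    hg_cfg$k2 <- min(hg_cfg$k2, nrow(train$X))
    cols <- .restrict_cols(train, cfg$feature_blocks)
    model <- train_chl(train, hg_cfg, cfg$chl, feature_cols = cols)
    predict_pairs(model, query)$score
  }
}

#' Leave-one-out cross-validation
#'
#' Each known association is held out in turn: the pipeline is recomputed
#' from the masked matrix, the model retrained, and the held-out pair
#' ranked against every unknown candidate pair. The per-positive AUC is the
#' fraction of candidates the test pair outranks (ties half); the global
#' AUC is their mean.
#'
#' @param A binary [association_matrix()].
#' @param SM miRNA functional [similarity_matrix()].
#' @param dag [disease_dag()].
#' @param cfg [pipeline_config()].
#' @param seed integer base seed for per-fold negative sampling and
#'   clustering.
#' @param scorer scoring backend `function(train, query, fold_seed)`
#'   returning one score per query row; the default trains the combinative
#'   hypergraph model. Swappable so oracle/random baselines can be run
#'   through the identical protocol.
#' @return [`cv_result`][kfold_cv()] with one AUC per held-out positive.
#' @export
loocv <- function(A, SM, dag, cfg = pipeline_config(), seed = 1L,
                  scorer = .chl_scorer(cfg)) {
  pos <- positive_pairs(A)
  if (nrow(pos) < 2L) stop("need at least two known associations")
  aucs <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    fold_seed <- (as.integer(seed) %% 100000L) * 10000L + i
    fold <- prepare_fold(A, SM, dag, pos[i, , drop = FALSE], cfg, fold_seed)
    sc <- scorer(fold$train, fold$query, fold_seed)
    aucs[[i]] <- auc_rank(sc[fold$test_idx], sc[-fold$test_idx])
  }
  .cv_result(aucs, "loocv", repeats = 1L)
}

#' k-fold cross-validation
#'
#' Known associations are randomly partitioned into `k` near-equal folds
#' per repeat. For each fold the test associations are masked, the full
#' similarity/feature pipeline recomputed, the model retrained, and the
#' test pairs scored together with all unknown candidate pairs. Test and
#' candidate scores are pooled across the `k` folds of a repeat into one
#' rank AUC; mean and standard deviation are taken over repeats.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions (default 1).
#' @return `cv_result` with one AUC per repeat and the fold assignment of
#'   the last repeat.
#' @export
kfold_cv <- function(A, SM, dag, cfg = pipeline_config(), k = 5L,
                     repeats = 1L, seed = 1L, scorer = .chl_scorer(cfg)) {
  pos <- positive_pairs(A)
  if (nrow(pos) < k) stop("fewer positives than folds")
  aucs <- numeric(repeats)
  assign_last <- NULL
  for (r in seq_len(repeats)) {
    perm <- with_seed((as.integer(seed) %% 100000L) * 100L + r,
                      sample.int(nrow(pos)))
    fold_of <- integer(nrow(pos))
    fold_of[perm] <- rep_len(seq_len(k), nrow(pos))
    pos_sc <- numeric(0); neg_sc <- numeric(0)
    for (f in seq_len(k)) {
      fold_seed <- (as.integer(seed) %% 100000L) * 10000L + r * 100L + f
      test <- pos[fold_of == f, c("mirna", "disease"), drop = FALSE]
      fold <- prepare_fold(A, SM, dag, test, cfg, fold_seed)
      sc <- scorer(fold$train, fold$query, fold_seed)
      pos_sc <- c(pos_sc, sc[fold$test_idx])
      neg_sc <- c(neg_sc, sc[-fold$test_idx])
    }
    aucs[[r]] <- auc_rank(pos_sc, neg_sc)
    assign_last <- data.frame(pos[, c("mirna", "disease")], fold = fold_of,
                              stringsAsFactors = FALSE)
  }
  .cv_result(aucs, "kfold", repeats = repeats,
             fold_assignments = assign_last)
}

#' Feature-family ablation
#'
#' Runs the k-fold protocol restricted to each of the seven non-empty
#' subsets of the three feature families and reports the mean AUC per
#' combination.
#'
#' @inheritParams kfold_cv
#' @return Named list combination -> `cv_result`; names like
#'   `"type1+type3"`.
#' @export
feature_ablation <- function(A, SM, dag, cfg = pipeline_config(), k = 5L,
                             repeats = 1L, seed = 1L) {
  fams <- c("type1", "type2", "type3")
  combos <- unlist(lapply(seq_along(fams), function(m)
    utils::combn(fams, m, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (cb in combos) {
    cfg_cb <- cfg
    cfg_cb$feature_blocks <- cb
    out[[paste(cb, collapse = "+")]] <-
      kfold_cv(A, SM, dag, cfg_cb, k = k, repeats = repeats, seed = seed)
  }
  out
}
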