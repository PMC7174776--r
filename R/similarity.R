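# Similarity layer: DAG-based disease semantic similarity (two contribution
# models), weighted-KNN interaction-profile completion, Gaussian
# interaction-profile kernels, and the zero-aware multi-similarity fusion.

#' Build a disease DAG corpus
#'
#' Restricts a disease hierarchy to the diseases of interest: each disease
#' contributes one DAG, namely its ancestor-closed term set `T(d)` together
#' with the parent->child edges among those terms. The corpus is the unit
#' over which term frequencies (model-1 contributions) are counted.
#'
#' @param dag [disease_dag()] for the full hierarchy.
#' @param diseases character vector of disease terms; all must be hierarchy
#'   nodes.
#' @return Object of class `dag_corpus` with fields `diseases`, `term_sets`
#'   (named list disease -> `T(d)`), `children`, `n_diseases`.
#' @export
dag_corpus <- function(dag, diseases) {
  diseases <- as.character(diseases)
  missing <- setdiff(diseases, dag$nodes)
  if (length(missing) > 0L)
    stop("diseases absent from the hierarchy: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  structure(list(diseases = diseases,
                 term_sets = dag$dag_of[diseases],
                 children = dag$children,
                 n_diseases = length(diseases)),
            class = "dag_corpus")
}

#' Model-1 (frequency-based) semantic contribution of a term
#'
#' The contribution of term `t` is `-log(n_t / N)` where `n_t` is the number
#' of disease DAGs in the corpus whose term set contains `t` and `N` is the
#' number of diseases. Rare terms therefore contribute more. Natural
#' logarithm; the downstream similarity is invariant to the log base.
#'
#' @param term a term identifier.
#' @param corpus [dag_corpus()].
#' @return Non-negative scalar contribution.
#' @export
d1_contribution <- function(term, corpus) {
  stopifnot(inherits(corpus, "dag_corpus"))
  n_t <- sum(vapply(corpus$term_sets, function(ts) term %in% ts, logical(1)))
  if (n_t == 0L)
    stop("term '", term, "' occurs in no disease DAG of the corpus")
  -log(n_t / corpus$n_diseases)
}

#' Model-2 (decay-based) semantic contributions for one disease
#'
#' Within the DAG of `disease`, the disease's own term contributes 1 and
#' every ancestor term `t` contributes `delta_sc` times the largest
#' contribution among its children inside `T(disease)`, so contributions
#' decay per generation up the hierarchy.
#'
#' @param disease a disease term with a DAG in the corpus.
#' @param corpus [dag_corpus()].
#' @param delta_sc semantic contribution factor in `(0, 1]`, default 0.5.
#' @return List with `d2` (named numeric over `T(disease)`) and `dv2`
#'   (their sum, the semantic value of the disease).
#' @export
d2_contribution <- function(disease, corpus, delta_sc = 0.5) {
  stopifnot(inherits(corpus, "dag_corpus"))
  if (!(delta_sc > 0 && delta_sc <= 1))
    stop("delta_sc must lie in (0, 1], got ", delta_sc)
  terms <- corpus$term_sets[[disease]]
  if (is.null(terms)) stop("disease '", disease, "' not in corpus")
  d2 <- setNames(rep(NA_real_, length(terms)), terms)
  contrib <- function(t) {
    if (!is.na(d2[[t]])) return(d2[[t]])
    val <- if (identical(t, disease)) 1 else {
      kids <- intersect(corpus$children[[t]], terms)
      # every proper ancestor of `disease` has a child on a path to it
      delta_sc * max(vapply(kids, contrib, 1))
    }
    d2[[t]] <<- val
    val
  }
  for (t in terms) contrib(t)
  list(d2 = d2, dv2 = sum(d2))
}

#' Semantic similarity between two diseases
#'
#' Normalised overlap of per-term contributions over the shared terms of the
#' two disease DAGs:
#' `sum over t in T(di) & T(dj) of (D_di(t) + D_dj(t)) / (DV(di) + DV(dj))`,
#' with contributions from the frequency model (`model = 1`) or the decay
#' model (`model = 2`).
#'
#' @param di,dj disease terms with DAGs in the corpus.
#' @param corpus [dag_corpus()].
#' @param model 1 or 2.
#' @param delta_sc decay factor for model 2.
#' @return Similarity in `[0, 1]`; 1 when `di == dj` (unless both semantic
#'   values are zero, which yields 0 with a warning).
#' @export
semantic_similarity <- function(di, dj, corpus, model = 1, delta_sc = 0.5) {
  stopifnot(model %in% c(1, 2))
  ti <- corpus$term_sets[[di]]
  tj <- corpus$term_sets[[dj]]
  if (is.null(ti) || is.null(tj)) stop("both diseases must be in the corpus")
  shared <- intersect(ti, tj)
  if (model == 1) {
    d1 <- vapply(unique(c(ti, tj)), d1_contribution, 1, corpus = corpus)
    num <- if (length(shared)) sum(d1[shared] + d1[shared]) else 0
    den <- sum(d1[ti]) + sum(d1[tj])
  } else {
    ci <- d2_contribution(di, corpus, delta_sc)
    cj <- d2_contribution(dj, corpus, delta_sc)
    num <- if (length(shared)) sum(ci$d2[shared] + cj$d2[shared]) else 0
    den <- ci$dv2 + cj$dv2
  }
  if (den == 0) {
    warning("zero semantic value for both '", di, "' and '", dj,
            "'; returning 0")
    return(0)
  }
  num / den
}

#' Semantic similarity matrix over a corpus
#'
#' @param corpus [dag_corpus()].
#' @param model 1 or 2.
#' @param delta_sc decay factor for model 2.
#' @return [similarity_matrix()] with role `SD1` or `SD2`.
#' @export
semantic_similarity_matrix <- function(corpus, model = 1, delta_sc = 0.5) {
  ds <- corpus$diseases
  n <- length(ds)
  if (model == 1) {
    all_terms <- unique(unlist(corpus$term_sets, use.names = FALSE))
    d1 <- vapply(all_terms, d1_contribution, 1, corpus = corpus)
    contrib <- lapply(corpus$term_sets, function(ts) d1[ts])
  } else {
    contrib <- lapply(ds, function(d) d2_contribution(d, corpus, delta_sc)$d2)
    names(contrib) <- ds
  }
  dv <- vapply(contrib, sum, 1)
  m <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
      den <- dv[[i]] + dv[[j]]
      val <- if (den == 0) 0 else
        (sum(contrib[[i]][shared]) + sum(contrib[[j]][shared])) / den
      m[i, j] <- m[j, i] <- val
    }
    if (dv[[i]] == 0) m[i, i] <- 0
  }
  similarity_matrix(m, ids = ds, role = if (model == 1) "SD1" else "SD2")
}

#' Average two disease semantic similarity matrices
#'
#' The working disease similarity is the elementwise mean of the
#' frequency-model and decay-model matrices.
#'
#' @param sd1,sd2 [similarity_matrix()] objects over the same identifiers.
#' @return [similarity_matrix()] with role `SD`.
#' @export
fuse_sd <- function(sd1, sd2) {
  if (!identical(sd1$ids, sd2$ids))
    stop("similarity matrices have mismatched identifiers")
  similarity_matrix((sd1$values + sd2$values) / 2, ids = sd1$ids, role = "SD")
}

#' WKNNP configuration
#'
#' @param K number of nearest known neighbours used per entity (default 20).
#' @param decay rank-decay factor in `(0, 1]` applied as `decay^(rank-1)`
#'   to neighbour weights (default 0.8).
#' @return Object of class `wknnp_config`.
#' @export
wknnp_config <- function(K = 20, decay = 0.8) {
  if (K < 1) stop("K must be >= 1")
  if (!(decay > 0 && decay <= 1)) stop("decay must lie in (0, 1]")
  structure(list(K = as.integer(K), decay = decay), class = "wknnp_config")
}

.wknnp_side <- function(A, sim, K, decay) {
  # similarity-weighted average of the K most similar other rows of A
  n <- nrow(A)
  est <- matrix(0, n, ncol(A))
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    ord <- order(s, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    nbr <- ord[seq_len(K)]
    w <- decay^(seq_len(K) - 1L) * sim[i, nbr]
    tot <- sum(w)
    if (tot > 0) est[i, ] <- as.numeric(w %*% A[nbr, , drop = FALSE]) / tot
  }
  est
}

#' Weighted K-nearest-neighbour profile completion
#'
#' Replaces zero entries of the association matrix with similarity-weighted
#' estimates borrowed from the profiles of each entity's most similar
#' neighbours. For each miRNA row the estimate is the decay-weighted average
#' of its `K` most SM-similar other rows; columns are treated analogously
#' with the disease similarity. The completed matrix is the elementwise
#' maximum of the original `A` and the mean of the row-side and column-side
#' estimates, clipped to `[0, 1]`, so known associations stay 1 and no entry
#' decreases.
#'
#' @param A [association_matrix()].
#' @param SM miRNA [similarity_matrix()] in `A`'s row order.
#' @param SD disease [similarity_matrix()] in `A`'s column order.
#' @param cfg [wknnp_config()].
#' @return [association_matrix()] with entries in `[0, 1]`.
#' @export
wknnp_complete <- function(A, SM, SD, cfg = wknnp_config()) {
  stopifnot(inherits(A, "association_matrix"))
  if (!identical(SM$ids, A$mirna_ids) || !identical(SD$ids, A$disease_ids))
    stop("similarity identifiers must match the association matrix; ",
         "use reindex_similarity()")
  nm <- nrow(A$values); nd <- ncol(A$values)
  Km <- cfg$K; Kd <- cfg$K
  if (Km >= nm) {
    warning("K truncated to ", nm - 1L, " (only ", nm, " miRNAs)")
    Km <- nm - 1L
  }
  if (Kd >= nd) {
    warning("K truncated to ", nd - 1L, " (only ", nd, " diseases)")
    Kd <- nd - 1L
  }
  row_est <- .wknnp_side(A$values, SM$values, Km, cfg$decay)
  col_est <- t(.wknnp_side(t(A$values), SD$values, Kd, cfg$decay))
  out <- pmax(A$values, (row_est + col_est) / 2)
  out[out > 1] <- 1
  out[out < 0] <- 0
  association_matrix(out, A$mirna_ids, A$disease_ids)
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' `gamma = 1 / mean squared profile norm`, so the kernel is scale-adapted
#' to the density of the interaction matrix.
#'
#' @param profiles numeric matrix; one profile per row.
#' @return Positive scalar bandwidth.
#' @export
gipk_bandwidth <- function(profiles) {
  profiles <- as.matrix(profiles)
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) stop("all interaction profiles are zero; bandwidth undefined")
  1 / msq
}

#' Gaussian interaction-profile kernel similarity
#'
#' `K[i, j] = exp(-gamma * ||profile_i - profile_j||^2)` with the bandwidth
#' from [gipk_bandwidth()]. Symmetric with unit diagonal and entries in
#' `(0, 1]`.
#'
#' @param profiles numeric matrix; one profile per row.
#' @param ids identifiers for the rows.
#' @param role similarity role tag (`"GIM"` for miRNAs, `"GID"` for
#'   diseases).
#' @return [similarity_matrix()].
#' @export
gipk_similarity <- function(profiles, ids = rownames(profiles),
                            role = "GIM") {
  profiles <- as.matrix(profiles)
  gamma <- gipk_bandwidth(profiles)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  similarity_matrix(k, ids = ids, role = role)
}

#' Fuse a base similarity with a Gipk similarity
#'
#' Where the base similarity is exactly zero (no evidence) the kernel value
#' is used alone; elsewhere the two are averaged.
#'
#' @param base [similarity_matrix()] (e.g. SM or SD).
#' @param gipk [similarity_matrix()] over the same identifiers.
#' @param role role tag for the result (`"MMS"` or `"DMS"`).
#' @return [similarity_matrix()].
#' @export
fuse_multi_similarity <- function(base, gipk, role = "MMS") {
  if (!identical(base$ids, gipk$ids))
    stop("similarity matrices have mismatched identifiers")
  out <- ifelse(base$values == 0, gipk$values,
                (base$values + gipk$values) / 2)
  similarity_matrix(out, ids = base$ids, role = role)
}

#' Compute fused multi-similarity matrices for a dataset
#'
#' Convenience pipeline: disease semantic similarity from the hierarchy
#' (both contribution models, averaged), WKNNP completion of the association
#' matrix, Gipk kernels on the completed profiles, and zero-aware fusion
#' into the miRNA and disease multi-similarity matrices.
#'
#' @param A binary [association_matrix()].
#' @param SM miRNA functional [similarity_matrix()].
#' @param dag [disease_dag()] covering `A`'s diseases.
#' @param delta_sc decay factor for the model-2 contribution.
#' @param wknnp [wknnp_config()].
#' @return List with `MMS`, `DMS`, `SD`, `A_completed`.
#' @export
multi_similarity <- function(A, SM, dag, delta_sc = 0.5,
                             wknnp = wknnp_config()) {
  SM <- reindex_similarity(SM, A$mirna_ids)
  corpus <- dag_corpus(dag, A$disease_ids)
  SD <- fuse_sd(semantic_similarity_matrix(corpus, 1),
                semantic_similarity_matrix(corpus, 2, delta_sc))
  Ac <- wknnp_complete(A, SM, SD, wknnp)
  GIM <- gipk_similarity(Ac$values, ids = A$mirna_ids, role = "GIM")
  GID <- gipk_similarity(t(Ac$values), ids = A$disease_ids, role = "GID")
  list(MMS = fuse_multi_similarity(SM, GIM, "MMS"),
       DMS = fuse_multi_similarity(SD, GID, "DMS"),
       SD = SD, A_completed = Ac)
}
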