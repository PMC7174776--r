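# Hypergraph construction over pair-feature vectors: KNN hyperedges
# (one per centroid vertex, Gaussian-affinity weighted) and K-means
# hyperedges (one per cluster, equal weights), plus the normalized
# hypergraph Laplacian.

#' Hypergraph configuration
#'
#' @param k1 neighbours per centroid for the KNN hypergraph (default 20);
#'   every KNN hyperedge then has `k1 + 1` vertices.
#' @param k2 number of K-means clusters (default 100); empty clusters are
#'   dropped.
#' @param rng_seed integer seed for the clustering initialisation.
#' @return Object of class `hypergraph_config`.
#' @export
hypergraph_config <- function(k1 = 20, k2 = 100, rng_seed = 1L) {
  if (k1 < 1 || k2 < 1) stop("k1 and k2 must be >= 1")
  structure(list(k1 = as.integer(k1), k2 = as.integer(k2),
                 rng_seed = as.integer(rng_seed)),
            class = "hypergraph_config")
}

#' Gaussian kernel scale of a feature matrix
#'
#' `sigma = (1/(n-1)) * sum_i ||x_i - xbar||^2`, the mean squared dispersion
#' of the rows around their centroid (with the n-1 denominator). Used as
#' the squared bandwidth of the hyperedge affinity kernel.
#'
#' @param X numeric feature matrix with `n >= 2` rows.
#' @return Positive scalar.
#' @export
gaussian_sigma <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two rows")
  xbar <- colMeans(X)
  s <- sum(sweep(X, 2, xbar)^2) / (n - 1)
  if (s == 0) stop("all feature rows identical; kernel scale degenerate")
  s
}

#' Gaussian affinity between two feature vectors
#'
#' `exp(-||xv - xu||^2 / sigma^2)` with `sigma` from [gaussian_sigma()].
#'
#' @param xv,xu numeric vectors of equal length.
#' @param sigma positive kernel scale.
#' @return Affinity in `(0, 1]`.
#' @export
pair_affinity <- function(xv, xu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((xv - xu)^2) / sigma^2)
}

.hypergraph <- function(H, W, kind) {
  De <- colSums(H)
  if (any(De < 1)) stop("empty hyperedge")
  Dv <- as.numeric(H %*% W)
  structure(list(H = H, W = W, Dv = Dv, De = De, kind = kind),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph [%s]: %d vertices, %d hyperedges\n",
              x$kind, nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' KNN hypergraph
#'
#' One hyperedge per vertex: the centroid plus its `k1` nearest rows by
#' Euclidean distance (ties broken by ascending index). The hyperedge
#' weight is the sum of Gaussian affinities between the centroid and each
#' of its neighbours, so tight neighbourhoods get heavy hyperedges.
#'
#' @param X numeric feature matrix (rows are vertices).
#' @param cfg [hypergraph_config()]; requires `k1 < nrow(X)`.
#' @return Object of class `hypergraph` with fields `H` (n x n incidence),
#'   `W` (hyperedge weights), `Dv`, `De`, `kind = "knn"`.
#' @export
build_knn_hypergraph <- function(X, cfg = hypergraph_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (cfg$k1 >= n) stop("k1 must be smaller than the number of vertices")
  sigma <- gaussian_sigma(X)
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  H <- matrix(0, n, n)
  W <- numeric(n)
  for (v in seq_len(n)) {
    ord <- order(d2[v, ], seq_len(n), method = "radix")
    nbr <- setdiff(ord, v)[seq_len(cfg$k1)]
    H[c(v, nbr), v] <- 1
    W[[v]] <- sum(exp(-d2[v, nbr] / sigma^2))
  }
  .hypergraph(H, W, "knn")
}

#' K-means hypergraph
#'
#' Vertices are clustered by K-means (k-means++-style multiple restarts,
#' fixed seed); each non-empty cluster becomes one hyperedge, and all
#' hyperedges share the equal weight `1/n_e`, so the weights sum to 1 and
#' the hyperedges partition the vertex set.
#'
#' @param X numeric feature matrix (rows are vertices).
#' @param cfg [hypergraph_config()]; requires `k2 <= nrow(X)`.
#' @return Object of class `hypergraph` with `kind = "kmeans"`.
#' @export
build_kmeans_hypergraph <- function(X, cfg = hypergraph_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (cfg$k2 > n) stop("k2 must not exceed the number of vertices")
  k2 <- cfg$k2
  n_distinct <- nrow(unique(X))
  if (k2 > n_distinct) {
    warning("k2 reduced to ", n_distinct, " (number of distinct rows)")
    k2 <- n_distinct
  }
  cl <- if (k2 == 1L) rep(1L, n) else {
    km <- with_seed(cfg$rng_seed,
                    suppressWarnings(
                      kmeans(X, centers = k2, nstart = 10,
                             iter.max = 300)))
    km$cluster
  }
  sizes <- tabulate(cl, nbins = max(cl))
  keep <- which(sizes > 0L)
  if (length(keep) < k2)
    warning(k2 - length(keep), " empty cluster(s) dropped")
  ne <- length(keep)
  H <- matrix(0, n, ne)
  for (j in seq_along(keep)) H[cl == keep[[j]], j] <- 1
  .hypergraph(H, rep(1 / ne, ne), "kmeans")
}

#' Normalized hypergraph Laplacian
#'
#' `Delta = I - Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}`, a symmetric positive
#' semi-definite operator whose quadratic form penalises label disagreement
#' between vertices sharing hyperedges.
#'
#' @param hg [build_knn_hypergraph()] / [build_kmeans_hypergraph()] output,
#'   or a list with fields `H` and `W`.
#' @return Symmetric n x n matrix.
#' @export
hypergraph_laplacian <- function(hg) {
  H <- hg$H
  W <- hg$W
  De <- colSums(H)
  Dv <- as.numeric(H %*% W)
  if (any(Dv <= 0))
    stop("isolated vertex (zero degree) at index ", which(Dv <= 0)[1L])
  n <- nrow(H)
  Hs <- (1 / sqrt(Dv)) * H          # Dv^{-1/2} H
  Theta <- Hs %*% (W / De * t(Hs))  # Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}
  Delta <- diag(n) - Theta
  (Delta + t(Delta)) / 2
}

#' Hypergraph Laplacian regularizer
#'
#' The smoothness penalty `tr(P^T X^T Delta X P)`, identical (up to
#' floating point) to the explicit pairwise double sum
#' `1/2 * sum_k sum_e sum_{u,v} w(e) h(u,e) h(v,e) / delta(e) *
#'  ((XP)(u,k)/sqrt(d(u)) - (XP)(v,k)/sqrt(d(v)))^2`.
#'
#' @param P c x l projection matrix.
#' @param X n x c feature matrix.
#' @param hg hypergraph.
#' @param form `"trace"` (default) or `"sum"` for the explicit double-sum
#'   evaluation (slow; used as a cross-check).
#' @return Non-negative scalar.
#' @export
omega_regularizer <- function(P, X, hg, form = c("trace", "sum")) {
  form <- match.arg(form)
  F <- as.matrix(X) %*% as.matrix(P)
  if (form == "trace") {
    Delta <- hypergraph_laplacian(hg)
    return(sum(F * (Delta %*% F)))
  }
  H <- hg$H; W <- hg$W
  De <- colSums(H)
  Dv <- as.numeric(H %*% W)
  G <- F / sqrt(Dv)
  acc <- 0
  for (e in seq_along(W)) {
    verts <- which(H[, e] == 1)
    for (u in verts) for (v in verts) {
      acc <- acc + W[[e]] / De[[e]] * sum((G[u, ] - G[v, ])^2)
    }
  }
  acc / 2
}
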