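# Combinative hypergraph learning: a closed-form Laplacian-regularised
# ridge projection per hypergraph view, simplex combination weights from
# the per-view objectives, and linear scoring of query pairs.

#' CHL hyperparameters
#'
#' @param lam weight of the empirical loss term (default `10`).
#' @param mu ridge regulariser on each projection matrix (default `1`).
#' @param eta regulariser on the combination weights (default `1000`);
#'   larger `eta` pulls the weights toward the uniform `(0.5, 0.5)`.
#' @return Object of class `chl_config`.
#' @export
chl_config <- function(lam = 10, mu = 1, eta = 1000) {
  if (lam <= 0 || mu <= 0 || eta <= 0)
    stop("lam, mu and eta must all be strictly positive")
  structure(list(lam = lam, mu = mu, eta = eta), class = "chl_config")
}

#' Column standardizer
#'
#' Means and standard deviations of the training feature columns;
#' zero-variance columns get unit scale so they are centred but not
#' inflated.
#'
#' @param X training feature matrix.
#' @return List with `center` and `scale` vectors.
#' @export
feature_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

#' Apply a standardizer to a feature matrix
#' @param X feature matrix.
#' @param stats output of [feature_standardizer()].
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(X, stats) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
}

#' Closed-form projection matrix for one hypergraph view
#'
#' Minimises `tr(P' X' Delta X P) + lam ||XP - Y||^2 + mu ||P||^2` in closed
#' form: `P = lam (X' Delta X + lam X'X + mu I)^{-1} X' Y`, computed by a
#' symmetric positive-definite solve (mu > 0 guarantees definiteness).
#'
#' @param X n x c feature matrix.
#' @param Y n x l label matrix.
#' @param Delta n x n hypergraph Laplacian.
#' @param cfg [chl_config()].
#' @return c x l projection matrix.
#' @export
fit_projection <- function(X, Y, Delta, cfg = chl_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  c <- ncol(X)
  M <- crossprod(X, Delta %*% X) + cfg$lam * crossprod(X) +
    cfg$mu * diag(c)
  M <- (M + t(M)) / 2
  rhs <- cfg$lam * crossprod(X, Y)
  P <- solve(M, rhs)
  resid <- max(abs(M %*% P - rhs)) / max(1, max(abs(rhs)))
  if (resid > 1e-8)
    stop("projection solve failed stationarity check (residual ",
         format(resid), ")")
  P
}

#' Per-view objective value
#'
#' `Theta = Omega(P) + lam ||XP - Y||^2_F + mu ||P||^2_F`, the quantity the
#' combination weights trade off between the two hypergraph views.
#'
#' @param P projection matrix.
#' @param X feature matrix.
#' @param Y label matrix.
#' @param hg hypergraph (or a precomputed Laplacian via `Delta`).
#' @param cfg [chl_config()].
#' @param Delta optional precomputed Laplacian.
#' @return Non-negative scalar.
#' @export
view_objective <- function(P, X, Y, hg = NULL, cfg = chl_config(),
                           Delta = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y); P <- as.matrix(P)
  if (is.null(Delta)) Delta <- hypergraph_laplacian(hg)
  F <- X %*% P
  sum(F * (Delta %*% F)) + cfg$lam * sum((F - Y)^2) + cfg$mu * sum(P^2)
}

# Euclidean projection of v onto the probability simplex
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[[rho]] - 1) / rho
  pmax(v - theta, 0)
}

#' Combination weights from per-view objectives
#'
#' Stationarity of the Lagrangian gives
#' `beta_i = 1/2 + sum(Theta)/(4 eta) - Theta_i/(2 eta)`; views with larger
#' objectives get smaller weights. When that formula leaves the feasible
#' region the weights are Euclidean-projected onto the probability simplex
#' (the non-negativity constraint made active).
#'
#' @param theta numeric vector of per-view objective values (length 2 in
#'   the standard two-view model).
#' @param eta positive weight regulariser.
#' @return Named list: `beta` (non-negative, summing to 1), `eps` (the
#'   Lagrange multiplier), `clamped` (logical).
#' @export
combination_weights <- function(theta, eta) {
  if (eta <= 0) stop("eta must be positive")
  k <- length(theta)
  beta <- 1 / k + sum(theta) / (2 * k * eta) - theta / (2 * eta)
  eps <- -(sum(theta) + 2 * eta) / k
  clamped <- any(beta < 0)
  if (clamped) beta <- .project_simplex(beta)
  beta <- beta / sum(beta)
  list(beta = beta, eps = eps, clamped = clamped)
}

#' Fit the combinative hypergraph learning model
#'
#' Learns one projection matrix per hypergraph view from the closed-form
#' Laplacian-regularised ridge system, evaluates each view's objective,
#' and combines the views with simplex weights.
#'
#' @param X n x c standardized training feature matrix.
#' @param Y n x 2 one-hot label matrix (column 1 = positive class).
#' @param hypergraphs list of hypergraphs built on the rows of `X` (two in
#'   the standard model: KNN and K-means).
#' @param cfg [chl_config()].
#' @param feature_stats standardizer used on `X`, stored for scoring.
#' @return Object of class `chl_model` with fields `P` (list of
#'   projections), `beta`, `theta`, `eps`, `config`, `feature_stats`.
#' @export
chl_fit <- function(X, Y, hypergraphs, cfg = chl_config(),
                    feature_stats = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(length(hypergraphs) >= 1L)
  Deltas <- lapply(hypergraphs, hypergraph_laplacian)
  P <- lapply(Deltas, function(D) fit_projection(X, Y, D, cfg))
  theta <- vapply(seq_along(P), function(i)
    view_objective(P[[i]], X, Y, cfg = cfg, Delta = Deltas[[i]]), 1)
  cw <- combination_weights(theta, cfg$eta)
  structure(list(P = P, beta = cw$beta, theta = theta, eps = cw$eps,
                 config = cfg, feature_stats = feature_stats),
            class = "chl_model")
}

#' @export
print.chl_model <- function(x, ...) {
  cat(sprintf("chl_model: %d views, beta = (%s), theta = (%s)\n",
              length(x$P), paste(sprintf("%.3f", x$beta), collapse = ", "),
              paste(sprintf("%.3g", x$theta), collapse = ", ")))
  invisible(x)
}

#' Score query pairs with a fitted model
#'
#' `S(x) = sum_i beta_i x P_i`; the scalar ranking score is the
#' positive-class column minus the negative-class column of `S`.
#'
#' @param model [chl_fit()] output.
#' @param Xquery query feature matrix on the raw feature scale (it is
#'   standardized with the model's stored training statistics), unless
#'   `standardized = TRUE`.
#' @param standardized set to `TRUE` if `Xquery` is already standardized.
#' @return Numeric vector of ranking scores, one per query row.
#' @export
chl_score <- function(model, Xquery, standardized = FALSE) {
  Xquery <- as.matrix(Xquery)
  if (!standardized && !is.null(model$feature_stats))
    Xquery <- apply_standardizer(Xquery, model$feature_stats)
  if (ncol(Xquery) != nrow(model$P[[1L]]))
    stop("query has ", ncol(Xquery), " features but the model expects ",
         nrow(model$P[[1L]]))
  S <- Reduce(`+`, lapply(seq_along(model$P), function(i)
    model$beta[[i]] * (Xquery %*% model$P[[i]])))
  as.numeric(S[, 1L] - S[, 2L])
}

#' Train the full model from a pair feature table
#'
#' Standardizes the training features, builds the KNN and K-means
#' hypergraphs on the standardized rows, and fits the combinative model.
#'
#' @param features labelled [assemble_pair_features()] output.
#' @param hg_cfg [hypergraph_config()].
#' @param cfg [chl_config()].
#' @param feature_cols optional column indices restricting the feature set
#'   (used by the ablation driver).
#' @return [chl_fit()] model (with `feature_cols` recorded).
#' @export
train_chl <- function(features, hg_cfg = hypergraph_config(),
                      cfg = chl_config(), feature_cols = NULL) {
  if (is.null(features$Y)) stop("training requires labelled pairs")
  X <- features$X
  if (!is.null(feature_cols)) X <- X[, feature_cols, drop = FALSE]
  stats <- feature_standardizer(X)
  Xs <- apply_standardizer(X, stats)
  hgs <- list(build_knn_hypergraph(Xs, hg_cfg),
              build_kmeans_hypergraph(Xs, hg_cfg))
  model <- chl_fit(Xs, features$Y, hgs, cfg, feature_stats = stats)
  model$feature_cols <- feature_cols
  model
}

#' Score a query feature table
#'
#' @param model [train_chl()] output.
#' @param features unlabelled or labelled [assemble_pair_features()] output.
#' @return data.frame `mirna`, `disease`, `score`.
#' @export
predict_pairs <- function(model, features) {
  X <- features$X
  if (!is.null(model$feature_cols))
    X <- X[, model$feature_cols, drop = FALSE]
  data.frame(features$pairs, score = chl_score(model, X),
             stringsAsFactors = FALSE)
}
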