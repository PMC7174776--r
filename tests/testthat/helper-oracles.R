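# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: centralities come from a hand-rolled BFS, the
# ridge solution from a QR factorisation of the augmented system, and
# optimisation minima from numerical optimisation.

# BFS shortest-path distances and path counts from one source
.bfs_paths <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); sig <- numeric(n)
  d[[s]] <- 0; sig[[s]] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(adj[u, ] > 0)) {
        if (!is.finite(d[[w]])) {
          d[[w]] <- d[[u]] + 1
          nxt <- c(nxt, w)
        }
        if (d[[w]] == d[[u]] + 1) sig[[w]] <- sig[[w]] + sig[[u]]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sig = sig)
}

# normalized betweenness by explicit pair enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  bfs <- lapply(seq_len(n), function(s) .bfs_paths(adj, s))
  bt <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      dst <- bfs[[s]]$d[[t]]
      if (!is.finite(dst) || bfs[[s]]$sig[[t]] == 0) next
      if (bfs[[s]]$d[[v]] + bfs[[v]]$d[[t]] == dst)
        acc <- acc + bfs[[s]]$sig[[v]] * bfs[[v]]$sig[[t]] / bfs[[s]]$sig[[t]]
    }
    bt[[v]] <- acc / ((n - 1) * (n - 2) / 2)
  }
  bt
}

# component-scaled (Wasserman-Faust) closeness by explicit BFS
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    d <- .bfs_paths(adj, v)$d[-v]
    reach <- d[is.finite(d)]
    if (length(reach) == 0L || sum(reach) == 0) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, 1)
}

# ridge regression via QR on the augmented system (independent of the
# normal-equation solve in fit_projection)
oracle_ridge <- function(X, Y, lam, mu) {
  Xa <- rbind(sqrt(lam) * X, sqrt(mu) * diag(ncol(X)))
  Ya <- rbind(sqrt(lam) * Y, matrix(0, ncol(X), ncol(Y)))
  qr.solve(Xa, Ya)
}

# numeric minimiser of the per-view objective over vec(P)
oracle_min_objective <- function(X, Y, Delta, lam, mu, starts = 3L,
                                 seed = 1L) {
  c <- ncol(X); l <- ncol(Y)
  obj <- function(p) {
    P <- matrix(p, c, l)
    F <- X %*% P
    sum(F * (Delta %*% F)) + lam * sum((F - Y)^2) + mu * sum(P^2)
  }
  best <- Inf
  set.seed(seed)
  for (s in seq_len(starts)) {
    p0 <- rnorm(c * l, sd = if (s == 1) 0 else 1)
    r <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# constrained minimiser of beta.theta + eta*||beta||^2 on the 2-simplex
# by grid search
oracle_weights_grid <- function(theta, eta, step = 1e-3) {
  b1 <- seq(0, 1, by = step)
  val <- b1 * theta[[1]] + (1 - b1) * theta[[2]] +
    eta * (b1^2 + (1 - b1)^2)
  b <- b1[[which.min(val)]]
  c(b, 1 - b)
}

# random valid hypergraph over n vertices (every vertex covered)
random_hypergraph <- function(n, ne = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(ne)) ne <- sample(2:5, 1)
  repeat {
    H <- matrix(rbinom(n * ne, 1, 0.5), n, ne)
    if (all(colSums(H) >= 1) && all(rowSums(H) >= 1)) break
  }
  list(H = H, W = runif(ne, 0.2, 2), kind = "random")
}

# small planted dataset shared by evaluation tests
small_planted <- function(seed = 0L) {
  simulate_dataset(synth_config(nm = 20, nd = 15, rank = 2, density = 0.15,
                                noise = 0, rng_seed = seed))
}

# toy 3-disease corpus: chain r -> a -> b plus sibling leaf c under a
toy_corpus <- function() {
  dag <- disease_dag(rbind(c("r", "a"), c("a", "b"), c("a", "c")))
  dag_corpus(dag, c("b", "c", "a"))
}
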