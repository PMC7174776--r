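# Synthetic study data: a low-rank planted association matrix, a miRNA
# functional similarity consistent with the planted factors, and a disease
# hierarchy whose topology follows the disease-side factors. Every
# similarity the predictor exploits (functional, interaction-profile,
# semantic) is a proxy for shared latent factors, so recovery of the
# planted links is a meaningful end-to-end check.

#' Synthetic dataset configuration
#'
#' Defaults define the package's reference study conditions: a 60 x 40
#' association matrix of rank 3 at 8% density with a 2% entry flip rate.
#'
#' @param nm number of miRNAs (default 60).
#' @param nd number of diseases (default 40).
#' @param rank number of latent factors (default 3).
#' @param density fraction of entries set to 1 before noise (default 0.08).
#' @param noise probability of flipping each entry (default 0.02).
#' @param dag_branching branching factor of the disease hierarchy
#'   (default 3).
#' @param rng_seed integer seed (default 0).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(nm = 60, nd = 40, rank = 3, density = 0.08,
                         noise = 0.02, dag_branching = 3, rng_seed = 0L) {
  if (rank > min(nm, nd)) stop("rank must not exceed min(nm, nd)")
  if (!(density > 0 && density < 1)) stop("density must lie in (0, 1)")
  if (!(noise >= 0 && noise < 1)) stop("noise must lie in [0, 1)")
  if (density * nm * nd < 10)
    stop("configuration yields fewer than 10 expected associations")
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 rank = as.integer(rank), density = density, noise = noise,
                 dag_branching = as.integer(dag_branching),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

# sparse non-negative factor matrix: each row loads on one primary factor
# plus occasional weak secondary loadings
.factor_matrix <- function(n, rank) {
  U <- matrix(runif(n * rank, 0, 0.25) * rbinom(n * rank, 1, 0.3), n, rank)
  primary <- sample(rank, n, replace = TRUE)
  U[cbind(seq_len(n), primary)] <- runif(n, 0.5, 1.5)
  U
}

# rooted tree over `ids` whose internal structure follows K-means splits of
# the factor rows, so hierarchy proximity tracks factor-space proximity
.factor_tree <- function(ids, V, branching) {
  counter <- new.env()
  counter$i <- 0L
  edges <- list()
  new_internal <- function() {
    counter$i <- counter$i + 1L
    paste0("T", counter$i)
  }
  split_group <- function(members, parent) {
    if (length(members) <= branching) {
      for (m in members)
        edges[[length(edges) + 1L]] <<- c(parent, ids[[m]])
      return(invisible(NULL))
    }
    Vsub <- V[members, , drop = FALSE]
    k <- min(branching, nrow(unique(Vsub)))
    groups <- if (k < 2L) {
      split(members, rep_len(seq_len(branching), length(members)))
    } else {
      cl <- tryCatch(
        suppressWarnings(kmeans(Vsub, centers = k, nstart = 5))$cluster,
        error = function(e) rep_len(seq_len(k), length(members)))
      split(members, cl)
    }
    groups <- groups[vapply(groups, length, 1L) > 0L]
    if (length(groups) == 1L)
      groups <- split(members, rep_len(1:2, length(members)))
    for (g in groups) {
      node <- new_internal()
      edges[[length(edges) + 1L]] <<- c(parent, node)
      split_group(g, node)
    }
  }
  split_group(seq_along(ids), "ROOT")
  disease_dag(do.call(rbind, edges))
}

#' Simulate a random rooted disease hierarchy
#'
#' Grows a rooted tree term by term; each new term attaches to a uniformly
#' chosen existing term that still has spare child capacity.
#'
#' @param n_terms number of terms (>= 1).
#' @param branching maximum children per term (default 3).
#' @param seed integer seed.
#' @return [disease_dag()] over terms `t1 ... t<n_terms>`.
#' @export
simulate_dag <- function(n_terms, branching = 3, seed = 0L) {
  stopifnot(n_terms >= 1)
  ids <- paste0("t", seq_len(n_terms))
  if (n_terms == 1L) return(disease_dag(NULL, nodes = ids))
  with_seed(seed, {
    child_count <- integer(n_terms)
    edges <- matrix(character(), 0, 2)
    for (i in 2:n_terms) {
      open <- which(child_count[seq_len(i - 1L)] < branching)
      parent <- open[[sample.int(length(open), 1L)]]
      child_count[[parent]] <- child_count[[parent]] + 1L
      edges <- rbind(edges, c(ids[[parent]], ids[[i]]))
    }
    disease_dag(edges)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Draws sparse non-negative latent factors `U` (miRNAs) and `V`
#' (diseases), thresholds `U V'` at the quantile matching the target
#' density, and flips entries with the configured noise probability to
#' produce the binary association matrix. The miRNA functional similarity
#' is the cosine similarity of the `U` rows; the disease hierarchy is a
#' rooted tree whose splits follow K-means clusters of `V`, so diseases
#' with nearby factors share deep ancestors.
#'
#' @param cfg [synth_config()].
#' @return List with `A` ([association_matrix()]), `SM`
#'   ([similarity_matrix()]), `dag` ([disease_dag()]; diseases are its
#'   leaves), and the latent `U`, `V` for diagnostics.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  with_seed(cfg$rng_seed, {
    mirnas <- sprintf("mir-%03d", seq_len(cfg$nm))
    diseases <- sprintf("dis-%03d", seq_len(cfg$nd))
    U <- .factor_matrix(cfg$nm, cfg$rank)
    V <- .factor_matrix(cfg$nd, cfg$rank)
    P <- U %*% t(V)
    want <- round(cfg$density * cfg$nm * cfg$nd)
    if (sum(P > 0) < want)
      stop("target density unreachable: only ", sum(P > 0),
           " positive scores for ", want, " requested associations")
    thr <- quantile(P, 1 - cfg$density, names = FALSE)
    A <- (P > thr) * 1
    if (cfg$noise > 0) {
      flip <- matrix(rbinom(length(A), 1, cfg$noise), nrow(A)) == 1
      A[flip] <- 1 - A[flip]
    }

    nrm <- sqrt(rowSums(U^2))
    cs <- tcrossprod(U) / outer(nrm, nrm)
    cs[!is.finite(cs)] <- 0
    diag(cs) <- 1
    cs[cs < 0] <- 0
    cs[cs > 1] <- 1

    dag <- .factor_tree(diseases, V, cfg$dag_branching)
    list(A = association_matrix(A, mirnas, diseases),
         SM = similarity_matrix(cs, ids = mirnas, role = "SM"),
         dag = dag, U = U, V = V)
  })
}
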