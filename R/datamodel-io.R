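#' @importFrom stats kmeans quantile rbinom runif sd setNames
#' @importFrom utils head read.table write.table
NULL

# ---- domain types ----------------------------------------------------------

#' Construct an association matrix
#'
#' Container for the binary (or, after profile completion, unit-interval)
#' miRNA x disease association matrix `A`. Rows are miRNAs, columns diseases;
#' row i is the interaction profile of miRNA i and column j the interaction
#' profile of disease j.
#'
#' @param values numeric matrix, nm x nd, entries in `[0, 1]`.
#' @param mirna_ids character vector of unique miRNA identifiers (length nm).
#' @param disease_ids character vector of unique disease identifiers
#'   (length nd).
#' @return An object of class `association_matrix` wrapping the dimnamed
#'   matrix.
#' @export
association_matrix <- function(values, mirna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mirna_ids) || is.null(disease_ids))
    stop("association_matrix requires miRNA and disease identifiers")
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA identifier: ", mirna_ids[duplicated(mirna_ids)][1L])
  if (anyDuplicated(disease_ids))
    stop("duplicate disease identifier: ",
         disease_ids[duplicated(disease_ids)][1L])
  if (length(mirna_ids) != nrow(values) || length(disease_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("association values must be finite and within [0, 1]")
  dimnames(values) <- list(mirna_ids, disease_ids)
  structure(list(values = values, mirna_ids = mirna_ids,
                 disease_ids = disease_ids),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d miRNAs x %d diseases, %d known links\n",
              length(x$mirna_ids), length(x$disease_ids),
              sum(x$values == 1)))
  invisible(x)
}

#' Construct a similarity matrix
#'
#' Square symmetric similarity container used for every similarity role in
#' the pipeline: the input miRNA functional similarity (`SM`), DAG-based
#' disease semantic similarities (`SD1`, `SD2`, fused `SD`), Gaussian
#' interaction-profile kernels (`GIM`, `GID`) and the fused multi-similarity
#' matrices (`MMS`, `DMS`).
#'
#' Mildly asymmetric input (max abs asymmetry below `tol`) is symmetrised as
#' `(M + t(M))/2`; larger asymmetry is an error. The stored matrix is exactly
#' symmetric.
#'
#' @param values square numeric matrix with entries in `[0, 1]`.
#' @param ids character vector of entity identifiers.
#' @param role one of `"SM"`, `"SD"`, `"SD1"`, `"SD2"`, `"GIM"`, `"GID"`,
#'   `"MMS"`, `"DMS"`.
#' @param tol asymmetry tolerance (default `1e-8`).
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, ids = rownames(values), role = "SM",
                              tol = 1e-8) {
  values <- as.matrix(values)
  role <- match.arg(role, c("SM", "SD", "SD1", "SD2", "GIM", "GID",
                            "MMS", "DMS"))
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square, got ",
         nrow(values), "x", ncol(values))
  if (is.null(ids)) stop("similarity_matrix requires identifiers")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate identifier: ", ids[duplicated(ids)][1L])
  if (length(ids) != nrow(values))
    stop("identifier length does not match matrix dimension")
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("similarity values must be finite and within [0, 1]")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, tol))
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 1] <- 1
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, role = role),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d entities, mean off-diagonal %.4f\n",
              x$role, length(x$ids),
              mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' Construct a disease DAG
#'
#' Holds a MeSH-like disease hierarchy as a parent -> child edge relation
#' plus, for every node, its ancestor-closed term set `T(d)` (the node
#' itself and everything reachable by repeatedly following child -> parent
#' edges). The per-disease term sets are the inputs of the semantic
#' similarity models.
#'
#' @param edges two-column data.frame or matrix (`parent`, `child`) of term
#'   identifiers; may have zero rows.
#' @param nodes optional character vector of terms; isolated terms (no
#'   edges) must be listed here to be part of the DAG.
#' @return Object of class `disease_dag` with fields `nodes`, `edges`
#'   (data.frame), `dag_of` (named list term -> character vector `T(d)`),
#'   and `children` (named list term -> child terms).
#' @export
disease_dag <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) != 2L) stop("edge list must have exactly two columns")
    names(edges) <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
  }
  nodes <- unique(c(as.character(nodes), edges$parent, edges$child))
  if (length(nodes) == 0L) stop("disease DAG has no nodes")

  parents_of <- split(edges$parent, factor(edges$child, levels = nodes))
  children_of <- split(edges$child, factor(edges$parent, levels = nodes))

  # Kahn's algorithm on the parent->child relation detects cycles.
  indeg <- vapply(parents_of, length, 1L)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children_of[[v]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) {
    member <- nodes[indeg_work > 0L][1L]
    stop("cycle detected in disease hierarchy involving term '", member, "'")
  }

  dag_of <- setNames(vector("list", length(nodes)), nodes)
  ancestors <- function(v) {
    if (!is.null(dag_of[[v]])) return(dag_of[[v]])
    anc <- v
    for (p in parents_of[[v]]) anc <- union(anc, ancestors(p))
    dag_of[[v]] <<- anc
    anc
  }
  for (v in nodes) ancestors(v)

  structure(list(nodes = nodes, edges = edges, dag_of = dag_of,
                 children = children_of),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d terms, %d parent->child edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# ---- TSV readers / writers -------------------------------------------------

.read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE, quote = "", comment.char = "",
                   stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a binary association matrix from TSV
#'
#' Expects a tab-separated file whose header row holds disease identifiers
#' (first cell empty), whose first column holds miRNA identifiers, and whose
#' body is strictly 0/1.
#'
#' @param path file path.
#' @return [association_matrix()].
#' @export
read_association_tsv <- function(path) {
  m <- .read_matrix_tsv(path)
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary association entry %s at row '%s', column '%s'",
                 format(m[bad[1L, , drop = FALSE]]),
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  association_matrix(m)
}

#' Write an association matrix to TSV
#' @param A [association_matrix()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(A, path) {
  .write_matrix_tsv(A$values, path)
}

.write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(formatC(m, digits = 10, format = "g"))
  # integers (0/1) format without decoration; keep exact text round-trip
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], df[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a similarity matrix from TSV
#'
#' @param path file path to a square TSV with identical header and first
#'   column identifiers.
#' @param role similarity role tag, see [similarity_matrix()].
#' @return [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path, role = "SM") {
  m <- .read_matrix_tsv(path)
  if (!identical(rownames(m), colnames(m)))
    stop("similarity TSV row and column identifiers differ")
  similarity_matrix(m, role = role)
}

#' Write a similarity matrix to TSV
#' @param S [similarity_matrix()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(S, path) {
  .write_matrix_tsv(S$values, path)
}

#' Read a disease hierarchy edge list from TSV
#'
#' Two tab-separated columns, parent then child, no header. Terms appearing
#' only as parents or only as children are included automatically.
#'
#' @param path file path.
#' @return [disease_dag()].
#' @export
read_dag_edges <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   col.names = c("parent", "child"))
  disease_dag(df)
}

#' Write a disease hierarchy edge list to TSV
#' @param dag [disease_dag()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_dag_edges <- function(dag, path) {
  write.table(dag$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write pair scores to TSV
#' @param scores data.frame with columns `mirna`, `disease`, `score`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  stopifnot(all(c("mirna", "disease", "score") %in% names(scores)))
  if (any(!is.finite(scores$score))) stop("scores must be finite")
  write.table(scores[, c("mirna", "disease", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Reindex a similarity matrix to a reference identifier order
#'
#' Identifier matching is by exact string; an id present in `ids` but
#' missing from `S` is an error.
#'
#' @param S [similarity_matrix()].
#' @param ids character vector giving the target order.
#' @return [similarity_matrix()] with rows/columns in `ids` order.
#' @export
reindex_similarity <- function(S, ids) {
  missing <- setdiff(ids, S$ids)
  if (length(missing) > 0L)
    stop("similarity matrix [", S$role, "] is missing identifiers: ",
         paste(head(missing, 5L), collapse = ", "))
  similarity_matrix(S$values[ids, ids, drop = FALSE], ids = ids,
                    role = S$role)
}
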