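## Correlation-graph construction and Markov clustering (MCL).

#' Build a thresholded Pearson correlation graph
#'
#' Edges connect gene pairs with Pearson correlation at least `min_r`
#' (across samples). Zero-variance genes cannot be correlated and are
#' excluded with a warning.
#'
#' @param mat genes-by-samples numeric matrix (for RNA, log2 of floored
#'   normalized counts is the conventional scale).
#' @param min_r correlation threshold (0.85 for RNA, 0.8 for protein at
#'   the published operating point).
#' @return a [CorrelationGraph].
#' @export
correlationGraph <- function(mat, min_r) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " zero-variance gene(s) excluded from the correlation graph")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  cc <- cor(t(mat))
  idx <- which(upper.tri(cc) & cc >= min_r, arr.ind = TRUE)
  edges <- data.frame(from = rownames(cc)[idx[, 1]],
                      to = rownames(cc)[idx[, 2]],
                      weight = cc[idx], row.names = NULL,
                      stringsAsFactors = FALSE)
  CorrelationGraph(nodes = rownames(cc), edges = edges, minR = min_r)
}

#' Markov clustering of a correlation graph
#'
#' Classic MCL: the weighted adjacency matrix with unit self-loops is made
#' column-stochastic, then expansion (matrix squaring) and inflation
#' (elementwise power followed by column renormalization) alternate until
#' the matrix change falls below `tol` or `max_iter` is reached. Clusters
#' are the connected attractor systems of the limit matrix; singletons are
#' reported as unassigned. Entries below `prune` are dropped between
#' iterations to keep the matrix sparse; this is the standard MCL pruning
#' and does not affect the attractor structure at the default tolerance.
#'
#' @param graph a [CorrelationGraph].
#' @param inflation inflation exponent (default 2.2, the long-standing
#'   default of graph-layout MCL tools).
#' @param max_iter iteration cap; hitting it flags the result
#'   non-converged.
#' @param tol convergence tolerance on the max absolute matrix change.
#' @param prune sparsity threshold between iterations.
#' @return a [ClusterSet] (clusters ordered by decreasing size).
#' @export
mcl <- function(graph, inflation = 2.2, max_iter = 200, tol = 1e-6,
                prune = 1e-8) {
  stopifnot(is(graph, "CorrelationGraph"))
  nodes <- graph@nodes
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  e <- graph@edges
  i <- c(match(e$from, nodes), match(e$to, nodes), seq_len(n))
  j <- c(match(e$to, nodes), match(e$from, nodes), seq_len(n))
  w <- c(e$weight, e$weight, rep(1, n))  # symmetric + unit self-loops
  M <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  normalizeCols <- function(m) {
    cs <- Matrix::colSums(m)
    m %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalizeCols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                        # expansion
    M2@x <- M2@x^inflation               # inflation
    M2 <- normalizeCols(M2)
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalizeCols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; interpreting the current matrix")
  ## attractor systems = connected components of the limit matrix support
  S <- (M + Matrix::t(M)) > tol
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  cl <- split(nodes, memb)
  sizes <- lengths(cl)
  clusters_list <- unname(cl[sizes >= 2L])
  clusters_list <- clusters_list[order(-lengths(clusters_list))]
  ClusterSet(clusters = clusters_list,
             unassigned = as.character(unlist(cl[sizes < 2L],
                                              use.names = FALSE)),
             converged = converged)
}
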