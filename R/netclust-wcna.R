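## Weighted correlation network module detection: soft-thresholded
## adjacency, topological overlap, average-linkage clustering with a
## static cut, module eigengenes and eigengene-dissimilarity merging.

#' Weighted correlation network module detection
#'
#' Unsigned adjacency `a_ij = |pearson(g_i, g_j)|^power`, topological
#' overlap dissimilarity `1 - TOM` with
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' average-linkage hierarchical clustering, and a static tree cut at the
#' height yielding the maximal number of branches of size at least
#' `min_module` (smallest such height on ties). Branches below the size
#' cutoff go to `unassigned`. Each module's eigengene is the first
#' principal component of its standardized expression, sign-fixed so the
#' mean member correlation is positive; module pairs whose eigengene
#' dissimilarity (1 - correlation) falls below `mediss` are merged
#' iteratively, recomputing eigengenes after each merge.
#'
#' @param mat genes-by-samples numeric matrix (log2 scale for RNA).
#' @param power soft-threshold exponent (7 for RNA, 18 for protein at the
#'   published operating point).
#' @param min_module minimum module size (default 30).
#' @param mediss eigengene-dissimilarity merge threshold (0.3 RNA, 0.5
#'   protein).
#' @return a [ModuleSet].
#' @export
wcna <- function(mat, power, min_module = 30, mediss = 0.3) {
  mat <- as.matrix(mat)
  if (nrow(mat) < min_module)
    stop("need at least min_module (", min_module, ") genes")
  cc <- suppressWarnings(cor(t(mat)))  # NA diagnosis follows explicitly
  if (anyNA(cc)) {
    bad <- rownames(cc)[unique(which(is.na(cc), arr.ind = TRUE)[, 1])]
    stop("degenerate correlations (zero variance?) for gene(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  A <- abs(cc)^power
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  dissTOM <- 1 - TOM
  h <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  heights <- sort(unique(h$height))
  cuts <- c((heights[-length(heights)] + heights[-1]) / 2,
            max(heights) - 1e-12)
  ## static cut: the height giving the most branches of size >= min_module;
  ## ties go to the highest such height (lower ties can split a coherent
  ## block into sub-branches while a sibling block is still fragmented)
  best_n <- -1L
  best_labels <- NULL
  for (ct in cuts) {
    lab <- stats::cutree(h, h = ct)
    nbig <- sum(table(lab) >= min_module)
    if (nbig >= best_n && nbig > 0L) {
      best_n <- nbig
      best_labels <- lab
    }
  }
  best_n <- max(best_n, 0L)
  if (best_n == 0L)
    return(ModuleSet(modules = list(),
                     eigengenes = matrix(numeric(), ncol(mat), 0),
                     unassigned = rownames(mat),
                     params = list(power = power, minModule = min_module,
                                   mediss = mediss)))
  tab <- table(best_labels)
  keep_ids <- names(tab)[tab >= min_module]
  mods <- lapply(keep_ids, function(id)
    rownames(mat)[best_labels == as.integer(id)])
  unas <- rownames(mat)[!best_labels %in% as.integer(keep_ids)]
  eg <- function(members) firstPCProfile(zTransform(mat[members, , drop = FALSE]))
  eigs <- vapply(mods, eg, numeric(ncol(mat)))
  ## iterative eigengene merging
  repeat {
    if (length(mods) < 2L) break
    dd <- 1 - cor(eigs)
    diag(dd) <- Inf
    m <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    if (dd[m[1], m[2]] >= mediss) break
    a <- min(m); b <- max(m)
    mods[[a]] <- c(mods[[a]], mods[[b]])
    mods[[b]] <- NULL
    eigs <- eigs[, -b, drop = FALSE]
    eigs[, a] <- eg(mods[[a]])
  }
  ord <- order(-lengths(mods))
  mods <- mods[ord]
  eigs <- eigs[, ord, drop = FALSE]
  names(mods) <- paste0("M", seq_along(mods))
  colnames(eigs) <- names(mods)
  rownames(eigs) <- colnames(mat)
  ModuleSet(modules = mods, eigengenes = eigs, unassigned = unas,
            params = list(power = power, minModule = min_module,
                          mediss = mediss))
}

#' Select the effector cluster
#'
#' Scores each cluster/module by how specifically its mean z-profile is
#' high in the CX3CR1+ populations:
#' `score = min over CX3CR1+ groups of mean z  -  max over (CX3CR1- and
#' naive) groups of mean z`, and returns the argmax. Ties go to the larger
#' cluster, then to the lexicographically first member gene.
#'
#' @param x a [ClusterSet], [ModuleSet] or plain list of gene-id vectors.
#' @param group_mean_z genes-by-population matrix of z-scored group means
#'   (covering all cluster members).
#' @return `list(genes, score, scores)` with `scores` the per-cluster
#'   score vector.
#' @export
selectEffectorCluster <- function(x, group_mean_z) {
  cl <- if (is(x, "ClusterSet")) clusters(x)
        else if (is(x, "ModuleSet")) modules(x)
        else x
  if (!length(cl)) stop("no clusters to select from")
  miss <- setdiff(unlist(cl, use.names = FALSE), rownames(group_mean_z))
  if (length(miss))
    stop("cluster member(s) missing from group_mean_z: ",
         paste(head(miss, 5), collapse = ", "))
  pos <- intersect(cxPositive(), colnames(group_mean_z))
  oth <- intersect(c(cxNegative(), "NAIVE"), colnames(group_mean_z))
  if (!length(pos) || !length(oth))
    stop("group_mean_z must contain CX3CR1+ and CX3CR1-/naive columns")
  scores <- vapply(cl, function(members) {
    prof <- colMeans(group_mean_z[members, , drop = FALSE])
    min(prof[pos]) - max(prof[oth])
  }, numeric(1))
  best <- max(scores)
  cand <- which(scores == best)
  if (length(cand) > 1L) {
    sizes <- lengths(cl)[cand]
    cand <- cand[sizes == max(sizes)]
    if (length(cand) > 1L) {
      firsts <- vapply(cl[cand], function(m) sort(m)[1], "")
      cand <- cand[order(firsts)][1]
    }
  }
  sel <- cand[1]
  list(genes = cl[[sel]], score = unname(scores[sel]),
       scores = unname(scores))
}
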