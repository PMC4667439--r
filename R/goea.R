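## Hypergeometric gene-set enrichment and enrichment-map construction.

#' Hypergeometric gene-set over-representation test
#'
#' For each term, with `N` universe genes, `K` term members in the
#' universe, `n` query genes and `k` hits, the upper-tail probability
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)` is computed exactly, and
#' BH adjustment is applied over all tested terms. Term memberships are
#' intersected with the universe first; terms with no member in the
#' universe are skipped, not scored.
#'
#' @param query character gene set (must be contained in `universe`).
#' @param universe character background gene set (conventionally the
#'   present genes of the relevant omics).
#' @param collection a [GeneSetCollection].
#' @return an [EnrichmentResult].
#' @examples
#' coll <- GeneSetCollection(sets = list(T1 = c("a", "b", "c")),
#'                           termNames = c(T1 = "demo"))
#' hypergeomEnrich(c("a", "b"), letters[1:10], coll)
#' @export
hypergeomEnrich <- function(query, universe, collection) {
  stopifnot(is(collection, "GeneSetCollection"))
  query <- unique(query)
  universe <- unique(universe)
  offenders <- setdiff(query, universe)
  if (length(offenders))
    stop("query gene(s) not in universe: ",
         paste(head(offenders, 10), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(geneSets(collection)), function(id) {
    members <- intersect(geneSets(collection)[[id]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = unname(collection@termNames[id]),
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(EnrichmentResult(table = DataFrame(
      term_id = character(), term_name = character(), k = integer(),
      K = integer(), n = integer(), N = integer(), p = numeric(),
      q = numeric())))
  rows$q <- bhFDR(rows$p)
  EnrichmentResult(table = DataFrame(rows))
}

#' Build an enrichment-map network
#'
#' Nodes are terms whose q-value passes `q_cutoff`; an edge connects two
#' terms when the Jaccard similarity of their memberships (restricted to
#' the universe, when given) reaches `jaccard_min`.
#'
#' @param result an [EnrichmentResult].
#' @param collection the [GeneSetCollection] the result was computed from.
#' @param universe optional character vector to restrict memberships to
#'   (use the same universe as the enrichment test).
#' @param jaccard_min Jaccard threshold (default 0.25).
#' @param q_cutoff FDR q-value cutoff (default 0.025).
#' @return an [EnrichmentNetwork].
#' @export
enrichmentMap <- function(result, collection, universe = NULL,
                          jaccard_min = 0.25, q_cutoff = 0.025) {
  stopifnot(is(result, "EnrichmentResult"), is(collection, "GeneSetCollection"))
  tb <- enrichTable(result)
  keep <- tb$q <= q_cutoff
  nodes <- data.frame(term_id = tb$term_id[keep],
                      term_name = tb$term_name[keep],
                      q = tb$q[keep], k = tb$k[keep],
                      stringsAsFactors = FALSE)
  members <- lapply(geneSets(collection)[nodes$term_id], function(m) {
    if (is.null(universe)) m else intersect(m, universe)
  })
  edges <- data.frame(from = character(), to = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    pairs <- utils::combn(nrow(nodes), 2)
    jac <- apply(pairs, 2, function(ij) {
      a <- members[[ij[1]]]; b <- members[[ij[2]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    sel <- jac >= jaccard_min
    edges <- data.frame(from = nodes$term_id[pairs[1, sel]],
                        to = nodes$term_id[pairs[2, sel]],
                        jaccard = jac[sel], stringsAsFactors = FALSE)
  }
  EnrichmentNetwork(nodes = nodes, edges = edges,
                    params = list(jaccardMin = jaccard_min,
                                  qCutoff = q_cutoff))
}
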