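## Shared fixtures and independent oracles. Everything is generated in
## code; no binary fixtures.

## A small synthetic study reused across files (cached per test run).
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateStudy(n_genes = 800, n_sig = 60, n_modules = 2,
                              reps_per_group = 5, detect_frac = 0.8,
                              n_terms = 30, seed = 101)
    cache
  }
})

## Expression matrix with one value pattern per population, `reps`
## replicates each, plus optional per-sample jitter.
makeEM <- function(group_values, reps = 3, scale = "normalized_counts",
                   jitter = 0) {
  pops <- cxPopulations()
  stopifnot(ncol(group_values) == length(pops))
  vals <- group_values[, rep(seq_along(pops), each = reps), drop = FALSE]
  if (jitter > 0) vals <- vals + matrix(rnorm(length(vals), 0, jitter),
                                        nrow(vals))
  colnames(vals) <- paste0(rep(pops, each = reps), "_R",
                           rep(seq_len(reps), length(pops)))
  if (is.null(rownames(vals)))
    rownames(vals) <- paste0("g", seq_len(nrow(vals)))
  CXExperiment(vals, rep(pops, each = reps), scale = scale)
}

## Independent step-up BH oracle (direct evaluation of the formula).
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(pmin(1, p[ord][js] * m / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

## Exhaustive hypergeometric upper tail: fraction of n-subsets of a size-N
## universe containing at least k of the K marked elements.
bruteHyperTail <- function(N, K, n, k) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

## Rand index between two partitions given as membership vectors.
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

## Canonical form of a clustering for comparison: sorted list of sorted
## clusters plus sorted unassigned set.
canonicalClustering <- function(clusters, unassigned) {
  cl <- lapply(clusters, sort)
  cl <- cl[order(vapply(cl, `[[`, "", 1L))]
  list(clusters = cl, unassigned = sort(unassigned))
}
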