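## Internal numeric helpers shared across modules.

## Column-group means of a gene x sample matrix; returns gene x group matrix
## with groups in cxPopulations() order (only groups present).
groupMeans <- function(mat, groups) {
  groups <- factor(as.character(groups),
                   levels = intersect(cxPopulations(), unique(as.character(groups))))
  gm <- vapply(levels(groups), function(g) {
    rowMeans(mat[, groups == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(mat),
                                     dimnames = list(rownames(mat), levels(groups)))
  gm
}

## Vectorized one-way ANOVA across columns grouped by `groups`.
## Returns list(F, p, df1, df2). NA rows (zero within-group variance in every
## group AND equal means) get F = 0 / p = 1; zero residual variance with
## unequal means gets F = Inf / p = 0.
rowFStats <- function(mat, groups) {
  groups <- droplevels(factor(as.character(groups)))
  k <- nlevels(groups)
  n <- ncol(mat)
  if (k < 2L) stop("need at least two groups for ANOVA")
  ns <- as.vector(table(groups))
  if (any(ns < 2L)) stop("need >= 2 replicates in every group")
  gm <- vapply(levels(groups), function(g)
    rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(mat))
  grand <- rowMeans(mat)
  ss_between <- as.vector(gm^2 %*% ns) - n * grand^2
  ss_total <- rowSums(mat^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  ss_between <- pmax(ss_between, 0)
  df1 <- k - 1L
  df2 <- n - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  ## degenerate rows: no residual variance
  zero_w <- ss_within <= 1e-12 * pmax(ss_total, 1e-300)
  Fv[zero_w & ss_between > 1e-12] <- Inf
  Fv[zero_w & ss_between <= 1e-12] <- 0
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  p[is.infinite(Fv)] <- 0
  p[Fv == 0] <- 1
  list(F = Fv, p = p, df1 = df1, df2 = df2)
}

## log2 of a floored normalized-count matrix (values >= 1 so log2 >= 0).
log2Floored <- function(mat) log2(pmax(mat, 1))

## First principal component summary of a gene x sample block: returns the
## per-sample right singular vector (unit length), sign-fixed so the mean
## correlation with member rows is positive.
firstPCProfile <- function(block_z) {
  sv <- svd(block_z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  cors <- block_z %*% v
  if (mean(cors) < 0) v <- -v
  v
}

## Deterministic per-stage seed derived from a base seed; stays < 2^31.
stageSeed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483629)
}
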