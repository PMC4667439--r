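## Normalization and filtering: median-of-ratios size factors, floored
## normalized counts, present/variable filters for RNA and microarray,
## z-standardization, sample PCA, proteome valid-value filtering and
## downshifted-normal imputation.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of the ratio
#' count / geometric mean. Factors are scale-equivariant: multiplying one
#' sample's counts by c multiplies its factor by c and no other.
#'
#' @param x a [CXExperiment] with `scale = "counts"`, or a plain count
#'   matrix.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(2, 6, 4, 12), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' medianRatioSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianRatioSizeFactors <- function(x) {
  mat <- if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
  loggeo <- rowMeans(log(mat))
  use <- is.finite(loggeo)   # genes with nonzero counts in every sample
  if (!any(use))
    stop("no gene has nonzero counts in all samples; size factors are ",
         "undefined. Consider a pseudo-reference fallback explicitly ",
         "(e.g. add a pseudocount) rather than relying on a silent one.")
  apply(mat[use, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - loggeo[use])))
}

#' Normalize counts by size factors and floor at 1
#'
#' Divides each sample's counts by its size factor and sets values below 1
#' to 1, so downstream fold changes against unexpressed genes stay bounded.
#'
#' @param x a [CXExperiment] with `scale = "counts"`.
#' @param factors per-sample size factors; computed with
#'   [medianRatioSizeFactors()] when missing.
#' @param floor the floor value (default 1).
#' @return a [CXExperiment] with `scale = "normalized_counts"`.
#' @export
normalizeCounts <- function(x, factors = medianRatioSizeFactors(x),
                            floor = 1) {
  stopifnot(is(x, "CXExperiment"))
  if (length(factors) != ncol(x))
    stop("need one size factor per sample")
  norm <- sweep(assay(x), 2, factors, `/`)
  norm[norm < floor] <- floor
  CXExperiment(norm, populations(x), scale = "normalized_counts")
}

#' Present-gene filter for normalized RNA-seq counts
#'
#' A gene is present when its mean normalized count exceeds `min_mean`
#' (strictly) in at least one population.
#'
#' @param x a [CXExperiment] with `scale = "normalized_counts"`.
#' @param min_mean strict group-mean threshold (default 10).
#' @return the filtered [CXExperiment] (gene order preserved).
#' @export
filterPresentRNA <- function(x, min_mean = 10) {
  stopifnot(is(x, "CXExperiment"))
  gm <- groupMeans(assay(x), populations(x))
  keep <- apply(gm, 1, max) > min_mean
  message("present filter (RNA): ", sum(keep), " of ", length(keep),
          " genes kept")
  x[keep, ]
}

#' Present-gene filter for log2 microarray intensities
#'
#' Probesets whose mean log2 intensity is below the background threshold in
#' every population are excluded; a gene is kept when at least one group
#' mean reaches the background.
#'
#' @param x a [CXExperiment] with `scale = "log2"`.
#' @param background background log2 intensity (default 6.7886).
#' @return the filtered [CXExperiment].
#' @export
filterPresentMicroarray <- function(x, background = 6.7886) {
  stopifnot(is(x, "CXExperiment"))
  gm <- groupMeans(assay(x), populations(x))
  keep <- apply(gm, 1, max) >= background
  message("present filter (microarray): ", sum(keep), " of ", length(keep),
          " genes kept")
  x[keep, ]
}

#' Variable-gene filter (one-way ANOVA across the five populations)
#'
#' Keeps genes whose one-way ANOVA p-value across populations falls below
#' `alpha`. For normalized counts the test runs on log2 values (count
#' noise is multiplicative). The p-value is unadjusted by default; set
#' `adjust = TRUE` to apply BH first. Constant genes (zero variance
#' everywhere) are dropped with a warning.
#'
#' @param x a [CXExperiment].
#' @param alpha significance threshold (default 0.05).
#' @param adjust apply BH adjustment before thresholding.
#' @return the filtered [CXExperiment].
#' @export
filterVariable <- function(x, alpha = 0.05, adjust = FALSE) {
  stopifnot(is(x, "CXExperiment"))
  mat <- assay(x)
  if (scaleType(x) == "normalized_counts") mat <- log2Floored(mat)
  const <- apply(mat, 1, function(v) var(v) == 0)
  if (any(const))
    warning(sum(const), " constant gene(s) dropped before the variable filter")
  fs <- rowFStats(mat[!const, , drop = FALSE], populations(x))
  p <- if (adjust) p.adjust(fs$p, "BH") else fs$p
  keep_ids <- rownames(mat)[!const][p < alpha]
  message("variable filter: ", length(keep_ids), " of ", nrow(mat),
          " genes kept at alpha = ", alpha)
  x[rownames(x) %in% keep_ids, ]
}

#' Per-gene z-standardization
#'
#' Standardizes each gene to mean 0 and sample standard deviation 1
#' (denominator n - 1). Zero-variance genes are dropped with a warning.
#'
#' @param x a [CXExperiment] or numeric matrix.
#' @return a numeric matrix of standardized values (possibly fewer rows).
#' @export
zTransform <- function(x) {
  mat <- if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped in z-transform")
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (mat - rowMeans(mat)) / sds
}

#' Sample PCA via singular value decomposition
#'
#' PCA on a genes-by-samples matrix of z-transformed values, with samples
#' as observations. Loadings are orthonormal; the sign convention makes the
#' largest-magnitude loading of each component positive. Explained
#' variances sum to the total variance of the input.
#'
#' @param zmat genes-by-samples matrix (typically from [zTransform()]).
#' @return `list(scores, loadings, explained)`: scores are
#'   samples-by-component, `explained` the per-component variance.
#' @export
samplePCA <- function(zmat) {
  x <- t(zmat)                          # samples x genes
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  d <- ncol(xc)
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- sv$v
  colnames(loadings) <- colnames(scores)
  rownames(loadings) <- colnames(x)
  explained <- sv$d^2 / (nrow(x) - 1)
  list(scores = scores, loadings = loadings, explained = explained)
}

#' Quantile normalization (sorted-mean substitution)
#'
#' Utility for microarray intensities: each sample's sorted values are
#' replaced by the mean of the sorted values across samples; ties receive
#' the average of the substituted values.
#'
#' @param mat genes-by-samples numeric matrix.
#' @return the normalized matrix.
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  ranks <- apply(mat, 2, rank, ties.method = "average")
  sorted <- apply(mat, 2, sort)
  target <- rowMeans(sorted)
  out <- apply(ranks, 2, function(r) {
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter a protein table by flags and valid quantifications
#'
#' Removes rows flagged contaminant, reverse (decoy) or
#' only-identified-by-site, then requires at least `min_valid` non-missing
#' intensities in at least one population of biological replicates. Output
#' intensities are log2-transformed (`scale = "log2"`); missingness stays
#' explicit as `NA`.
#'
#' @param x a [ProteinExperiment] with `scale = "linear"` and labeled
#'   samples.
#' @param min_valid minimum valid quantifications in at least one group.
#' @return the filtered, log2-scale [ProteinExperiment].
#' @export
filterProteins <- function(x, min_valid = 3) {
  stopifnot(is(x, "ProteinExperiment"), scaleType(x) == "linear")
  pop <- populations(x)
  if (anyNA(pop))
    stop("population labels are required for the valid-value filter")
  rd <- rowData(x)
  clean <- !(rd$contaminant | rd$reverse | rd$site_only)
  vals <- assay(x)
  valid <- !is.na(vals)
  enough <- rep(FALSE, nrow(vals))
  for (g in levels(droplevels(pop))) {
    cnt <- rowSums(valid[, pop == g, drop = FALSE])
    enough <- enough | cnt >= min_valid
  }
  keep <- clean & enough
  message("protein filter: ", sum(keep), " of ", length(keep),
          " rows kept (", sum(!clean), " flagged, ",
          sum(clean & !enough), " with too few valid values)")
  out <- x[keep, ]
  assay(out) <- log2(assay(out))
  out@scale <- "log2"
  validObject(out)
  out
}

#' Impute missing log2 intensities from a downshifted normal
#'
#' Models values below the detection limit: for each sample column with
#' observed mean mu and standard deviation sigma, each missing cell is
#' replaced by a draw from Normal(mu - shift * sigma, (width * sigma)^2).
#' With `per_column = FALSE` the observed mean/sd of the whole matrix are
#' used instead.
#'
#' @param x a log2-scale [ProteinExperiment].
#' @param shift downward shift in observed standard deviations (default
#'   1.8).
#' @param width imputation width as a fraction of the observed standard
#'   deviation (default 0.3).
#' @param seed RNG seed; imputation is deterministic under it.
#' @param per_column impute from per-sample statistics (default) or global.
#' @return the completed [ProteinExperiment] (no `NA` left).
#' @export
imputeMissing <- function(x, shift = 1.8, width = 0.3, seed = 1,
                          per_column = TRUE) {
  stopifnot(is(x, "ProteinExperiment"), scaleType(x) == "log2")
  vals <- assay(x)
  set.seed(seed)
  if (per_column) {
    for (j in seq_len(ncol(vals))) {
      obs <- vals[, j][!is.na(vals[, j])]
      miss <- which(is.na(vals[, j]))
      if (!length(miss)) next
      if (length(obs) < 2L || sd(obs) == 0)
        stop("sample '", colnames(vals)[j],
             "' has no usable observed values to impute from")
      vals[miss, j] <- rnorm(length(miss), mean(obs) - shift * sd(obs),
                             width * sd(obs))
    }
  } else {
    obs <- vals[!is.na(vals)]
    miss <- which(is.na(vals))
    if (length(miss)) {
      if (length(obs) < 2L || sd(obs) == 0)
        stop("no usable observed values to impute from")
      vals[miss] <- rnorm(length(miss), mean(obs) - shift * sd(obs),
                          width * sd(obs))
    }
  }
  assay(x) <- vals
  x
}
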