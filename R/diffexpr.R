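## Differential expression: per-gene one-way ANOVA across the five
## populations, BH correction, contrast fold changes from (floored)
## normalized group means, and the derived comparison tables.

#' Default contrasts: each memory population against naive
#' @return named list of `c(test, ref)` pairs.
#' @export
defaultContrasts <- function() {
  tests <- setdiff(cxPopulations(), "NAIVE")
  setNames(lapply(tests, function(t) c(t, "NAIVE")),
           paste0(tests, ".vs.NAIVE"))
}

#' Per-gene ANOVA differential expression
#'
#' One-way ANOVA p-value per gene across all five populations, BH-adjusted
#' over all tested genes, plus fold changes per requested contrast computed
#' from the group means on the normalized scale (floored upstream, so fold
#' changes stay bounded). For normalized counts the F-test runs on log2
#' values (count noise is multiplicative; the linear scale would make the
#' test heteroscedastic), while fold changes stay ratios of the floored
#' linear group means. The classical equal-variance F-test is the default;
#' `welch = TRUE` switches to Welch's correction.
#'
#' @param x a [CXExperiment] (normalized counts or log2 values).
#' @param contrasts named list of `c(test, ref)` population pairs.
#' @param welch use Welch's unequal-variance ANOVA.
#' @return a [DEResult].
#' @examples
#' sim <- generateRNA(n_genes = 200, n_sig = 20, n_modules = 0,
#'                    reps_per_group = 3, seed = 3)
#' em <- normalizeCounts(sim$counts)
#' de <- anovaDE(em)
#' de
#' @export
anovaDE <- function(x, contrasts = defaultContrasts(), welch = FALSE) {
  stopifnot(is(x, "CXExperiment"))
  pop <- populations(x)
  labs <- unlist(contrasts)
  missing_lab <- setdiff(labs, as.character(unique(pop)))
  if (length(missing_lab))
    stop("contrast population(s) absent from labels: ",
         paste(unique(missing_lab), collapse = ", "))
  mat <- assay(x)
  tmat <- if (scaleType(x) == "normalized_counts") log2Floored(mat) else mat
  if (welch) {
    pv <- apply(tmat, 1, function(v) {
      ok <- tryCatch(stats::oneway.test(v ~ pop)$p.value, error = function(e) NA_real_)
      if (is.na(ok)) 1 else ok
    })
    Fv <- apply(tmat, 1, function(v)
      tryCatch(unname(stats::oneway.test(v ~ pop)$statistic),
               error = function(e) 0))
    fs <- list(F = Fv, p = pv)
  } else {
    fs <- rowFStats(tmat, pop)
  }
  q <- bhFDR(fs$p)
  gm <- groupMeans(mat, pop)
  ## on the log2 scale the ratio of group means is meaningless; fold
  ## change is the (geometric-mean) ratio 2^(mean difference)
  is_log <- scaleType(x) == "log2"
  fc <- vapply(contrasts, function(ct) {
    if (is_log) 2^(gm[, ct[1]] - gm[, ct[2]])
    else gm[, ct[1]] / gm[, ct[2]]
  }, numeric(nrow(mat)))
  if (is.null(dim(fc)))
    fc <- matrix(fc, nrow = nrow(mat),
                 dimnames = list(rownames(mat), names(contrasts)))
  colnames(gm) <- paste0("mean.", colnames(gm))
  st <- DataFrame(gm, F = fs$F, p = fs$p, q = q, row.names = rownames(mat))
  DEResult(stats = st, fc = fc, log2fc = log2(fc), contrasts = contrasts)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q[(i)] = min over j >= i of min(1, p[(j)] * m / j)`, mapped back to the
#' input order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p numeric p-values.
#' @return q-values in input order.
#' @export
bhFDR <- function(p) p.adjust(p, method = "BH")

#' Genes commonly and significantly upregulated in both CX3CR1+ populations
#'
#' Genes with q below `fdr` and fold change above `fc` (strictly) in both
#' contrasts CX3CR1+CD62Lhi vs naive and CX3CR1+CD62Llo vs naive.
#'
#' @param de a [DEResult] containing the two CX3CR1+ vs naive contrasts.
#' @param fc fold-change threshold (default 2).
#' @param fdr FDR threshold (default 0.05).
#' @return character vector of gene ids.
#' @export
commonUpregulated <- function(de, fc = 2, fdr = 0.05) {
  stopifnot(is(de, "DEResult"))
  cts <- paste0(cxPositive(), ".vs.NAIVE")
  missing_ct <- setdiff(cts, colnames(de@fc))
  if (length(missing_ct))
    stop("DEResult lacks contrast(s): ", paste(missing_ct, collapse = ", "))
  ok <- de@stats$q < fdr
  for (ct in cts) ok <- ok & de@fc[, ct] > fc
  rownames(de@stats)[ok]
}

#' Ratio-ratio comparison table
#'
#' log10 mean ratios of two contrasts for genes differentially expressed
#' (q below `fdr` and fold change above `fc` or below `1/fc`) in at least
#' one of the two contrasts.
#'
#' @param de a [DEResult].
#' @param contrast_x,contrast_y contrast names in `de`.
#' @param fc,fdr DE thresholds.
#' @return data.frame with columns `gene`, `log10_ratio_x`,
#'   `log10_ratio_y`.
#' @export
ratioRatio <- function(de, contrast_x, contrast_y, fc = 2, fdr = 0.05) {
  stopifnot(is(de, "DEResult"))
  for (ct in c(contrast_x, contrast_y))
    if (!ct %in% colnames(de@fc)) stop("unknown contrast: ", ct)
  sig <- de@stats$q < fdr
  de_in <- function(ct) sig & (de@fc[, ct] > fc | de@fc[, ct] < 1 / fc)
  keep <- de_in(contrast_x) | de_in(contrast_y)
  data.frame(gene = rownames(de@stats)[keep],
             log10_ratio_x = log10(de@fc[keep, contrast_x]),
             log10_ratio_y = log10(de@fc[keep, contrast_y]),
             row.names = NULL)
}

#' Fold-change rank table with cross-omics discordance
#'
#' Orders genes by the primary log2 fold change (descending) and overlays
#' the secondary (other-omics) log2 fold change; a gene is discordant when
#' its secondary log2 fold change is negative.
#'
#' @param primary_fc named numeric vector of log2 fold changes defining the
#'   ranking.
#' @param secondary_fc named numeric vector for the overlay (missing genes
#'   become `NA` and are not counted as discordant).
#' @return `list(table = data.frame(gene, rank, primary_log2fc,
#'   secondary_log2fc), discordant = count)`.
#' @export
foldChangeRank <- function(primary_fc, secondary_fc) {
  if (is.null(names(primary_fc)))
    stop("primary_fc must be named by gene")
  ord <- order(primary_fc, decreasing = TRUE)
  genes <- names(primary_fc)[ord]
  sec <- secondary_fc[genes]
  names(sec) <- genes
  tab <- data.frame(gene = genes, rank = seq_along(genes),
                    primary_log2fc = unname(primary_fc[ord]),
                    secondary_log2fc = unname(sec), row.names = NULL)
  list(table = tab, discordant = sum(sec < 0, na.rm = TRUE))
}
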