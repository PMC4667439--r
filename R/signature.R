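## Consensus signature logic: intersect DE with the co-regulation engines,
## refine, mirror on the proteome, and relate the two omics.

#' Derive the pre-signature from DE and the two clustering engines
#'
#' `(mcl_selected  intersect  de_common)  union
#'  (wcna_selected intersect  de_common)`, with per-gene provenance
#' recording which route(s) contributed it. Member order follows
#' `de_common`.
#'
#' @param de_common genes commonly upregulated in both CX3CR1+ populations
#'   ([commonUpregulated()]).
#' @param mcl_selected member genes of the effector MCL cluster.
#' @param wcna_selected member genes of the effector network module.
#' @param omics `"rna"` or `"protein"`.
#' @return a [SignatureSet] with `stage = "pre"`.
#' @export
derivePreSignature <- function(de_common, mcl_selected, wcna_selected,
                               omics = "rna") {
  via_mcl <- intersect(de_common, mcl_selected)
  via_wcna <- intersect(de_common, wcna_selected)
  genes <- de_common[de_common %in% union(via_mcl, via_wcna)]
  prov <- lapply(genes, function(g)
    c("DE&MCL", "DE&WCNA")[c(g %in% via_mcl, g %in% via_wcna)])
  SignatureSet(genes = genes, provenance = setNames(prov, genes),
               stage = "pre", omics = omics)
}

## pooled CX3CR1+ and CX3CR1- sample means per gene
pooledPosNegMeans <- function(mat, pop) {
  pos <- rowMeans(mat[, pop %in% cxPositive(), drop = FALSE])
  neg <- rowMeans(mat[, pop %in% cxNegative(), drop = FALSE])
  list(pos = pos, neg = neg)
}

#' Refine an RNA signature by CX3CR1+/CX3CR1- fold change and difference
#'
#' Computes, per pre-signature gene, the fold change and absolute
#' difference between the pooled mean of the two CX3CR1+ populations and
#' the pooled mean of the two CX3CR1- populations (normalized scale).
#' Under the default `rule = "AND"` a gene is removed when the fold change
#' is below `fc_min` AND the absolute difference is below `abs_diff_min`
#' (`"OR"` removes when either fails). Blocklisted genes (polymorphic MHC
#' class II by default) are removed last.
#'
#' @param pre a `stage = "pre"` [SignatureSet].
#' @param em a [CXExperiment] with normalized counts covering every pre
#'   gene.
#' @param fc_min fold-change threshold (default 1.5).
#' @param abs_diff_min absolute-difference threshold (default 50).
#' @param blocklist gene ids removed unconditionally.
#' @param rule `"AND"` (default) or `"OR"`.
#' @param subtract_cx3neg also remove genes significantly upregulated in
#'   both CX3CR1- populations versus naive (pass the [DEResult] via
#'   `de`); off by default since the CX3CR1+/CX3CR1- filter already
#'   enforces effector specificity and the signature deliberately retains
#'   genes with intermediate CX3CR1- expression.
#' @param de a [DEResult]; only used when `subtract_cx3neg = TRUE`.
#' @param de_fc,de_fdr thresholds for the optional subtraction.
#' @return a [SignatureSet] with `stage = "refined"`.
#' @export
refineSignature <- function(pre, em, fc_min = 1.5, abs_diff_min = 50,
                            blocklist = defaultMHC2Blocklist(),
                            rule = c("AND", "OR"),
                            subtract_cx3neg = FALSE, de = NULL,
                            de_fc = 2, de_fdr = 0.05) {
  rule <- match.arg(rule)
  stopifnot(is(pre, "SignatureSet"), is(em, "CXExperiment"))
  genes <- signatureGenes(pre)
  miss <- setdiff(genes, rownames(em))
  if (length(miss))
    stop("pre-signature gene(s) missing from the expression matrix: ",
         paste(head(miss, 5), collapse = ", "))
  if (!length(genes))
    return(SignatureSet(genes = character(), provenance = list(),
                        stage = "refined", omics = pre@omics))
  pm <- pooledPosNegMeans(assay(em)[genes, , drop = FALSE], populations(em))
  fc <- pm$pos / pm$neg
  adiff <- abs(pm$pos - pm$neg)
  removed <- if (rule == "AND") (fc < fc_min) & (adiff < abs_diff_min)
             else (fc < fc_min) | (adiff < abs_diff_min)
  keep <- genes[!removed]
  if (subtract_cx3neg) {
    if (is.null(de)) stop("subtract_cx3neg = TRUE requires the DEResult")
    cts <- paste0(cxNegative(), ".vs.NAIVE")
    up_neg <- deTable(de)$q < de_fdr
    for (ct in cts) up_neg <- up_neg & foldChanges(de)[, ct] > de_fc
    keep <- setdiff(keep, rownames(deTable(de))[up_neg])
  }
  keep <- setdiff(keep, blocklist)
  SignatureSet(genes = keep, provenance = provenance(pre)[keep],
               stage = "refined", omics = pre@omics)
}

#' Refine a protein signature by absolute linear-intensity difference
#'
#' Removal is on the absolute difference of pooled CX3CR1+ versus CX3CR1-
#' linear intensities only (no fold-change criterion), then the MHC class
#' II blocklist (matched against gene names) is applied.
#'
#' @param pre a `stage = "pre"` protein [SignatureSet] (ids are
#'   accessions).
#' @param pt a [ProteinExperiment]; log2 values are converted back to the
#'   linear scale for the difference.
#' @param abs_diff_min threshold on the linear intensity difference
#'   (default 1e6).
#' @param blocklist gene symbols removed unconditionally.
#' @return a [SignatureSet] with `stage = "refined"`.
#' @export
refineProteinSignature <- function(pre, pt, abs_diff_min = 1e6,
                                   blocklist = defaultMHC2Blocklist()) {
  stopifnot(is(pre, "SignatureSet"), is(pt, "ProteinExperiment"))
  acc <- signatureGenes(pre)
  miss <- setdiff(acc, rownames(pt))
  if (length(miss))
    stop("pre-signature protein(s) missing from the table: ",
         paste(head(miss, 5), collapse = ", "))
  if (!length(acc))
    return(SignatureSet(genes = character(), provenance = list(),
                        stage = "refined", omics = pre@omics))
  vals <- assay(pt)[acc, , drop = FALSE]
  if (scaleType(pt) == "log2") vals <- 2^vals
  pm <- pooledPosNegMeans(vals, populations(pt))
  keep <- acc[abs(pm$pos - pm$neg) >= abs_diff_min]
  blocked <- rownames(pt)[as.character(rowData(pt)$gene_name) %in% blocklist]
  keep <- setdiff(keep, blocked)
  SignatureSet(genes = keep, provenance = provenance(pre)[keep],
               stage = "refined", omics = pre@omics)
}

#' Match RNA genes to protein rows via an accession map
#'
#' Protein rows are mapped to gene symbols through `idmap`
#' (accession -> symbol); when several accessions map to one symbol the
#' row with the highest mean intensity wins (logged via message).
#'
#' @param rna_genes character gene ids.
#' @param pt a [ProteinExperiment].
#' @param idmap named character, accession -> symbol.
#' @return `list(pairs = data.frame(gene, accession), unmatched_genes,
#'   unmapped_accessions)`.
#' @export
matchOmics <- function(rna_genes, pt, idmap) {
  stopifnot(is(pt, "ProteinExperiment"))
  acc <- rownames(pt)
  unmapped <- acc[!acc %in% names(idmap)]
  mapped <- acc[acc %in% names(idmap)]
  sym <- idmap[mapped]
  mean_int <- rowMeans(assay(pt)[mapped, , drop = FALSE], na.rm = TRUE)
  ord <- order(-mean_int)
  first <- !duplicated(sym[ord])
  chosen <- mapped[ord][first]
  names(chosen) <- sym[ord][first]
  n_dropped <- length(mapped) - length(chosen)
  if (n_dropped > 0)
    message(n_dropped, " accession(s) dropped in favour of a ",
            "higher-intensity row mapping to the same symbol")
  hit <- rna_genes[rna_genes %in% names(chosen)]
  list(pairs = data.frame(gene = hit, accession = unname(chosen[hit]),
                          row.names = NULL),
       unmatched_genes = setdiff(rna_genes, hit),
       unmapped_accessions = unmapped)
}

#' Overlap of the refined transcriptome and proteome signatures
#'
#' @param rna_sig refined RNA [SignatureSet] (gene symbols).
#' @param prot_sig refined protein [SignatureSet] (accessions).
#' @param idmap named character, accession -> symbol.
#' @return character vector: gene symbols in both signatures.
#' @export
overlapSignatures <- function(rna_sig, prot_sig, idmap) {
  rg <- if (is(rna_sig, "SignatureSet")) signatureGenes(rna_sig) else rna_sig
  pa <- if (is(prot_sig, "SignatureSet")) signatureGenes(prot_sig) else prot_sig
  prot_genes <- unique(unname(idmap[pa[pa %in% names(idmap)]]))
  intersect(rg, prot_genes)
}

#' Signature genes detected in the proteome
#'
#' Members of the RNA signature with at least one matched,
#' filter-surviving protein row.
#'
#' @param rna_sig refined RNA [SignatureSet] or character vector.
#' @param pt a filtered [ProteinExperiment].
#' @param idmap named character, accession -> symbol.
#' @return `list(count, genes)`.
#' @export
detectedInProteome <- function(rna_sig, pt, idmap) {
  rg <- if (is(rna_sig, "SignatureSet")) signatureGenes(rna_sig) else rna_sig
  prot_genes <- unique(unname(idmap[rownames(pt)[rownames(pt) %in% names(idmap)]]))
  genes <- rg[rg %in% prot_genes]
  list(count = length(genes), genes = genes)
}

#' RNA expression histograms by protein-abundance class
#'
#' Present genes are binned by their matched protein's mean log2 intensity
#' into `n_classes` equal-width classes (plus a separate class for genes
#' without a detected protein); the per-class distribution of log2 RNA
#' expression is returned.
#'
#' @param rna_em a [CXExperiment] of present genes (normalized counts).
#' @param pt a log2-scale [ProteinExperiment].
#' @param idmap named character, accession -> symbol.
#' @param n_classes number of protein-intensity classes (default 5).
#' @return `list(table = data.frame(gene, class, rna_log2),
#'   class_medians, breaks)`; class `"unmatched"` collects genes without a
#'   protein.
#' @export
expressionClassHistogram <- function(rna_em, pt, idmap, n_classes = 5) {
  stopifnot(is(rna_em, "CXExperiment"), is(pt, "ProteinExperiment"),
            scaleType(pt) == "log2")
  genes <- rownames(rna_em)
  mm <- matchOmics(genes, pt, idmap)
  prot_mean <- rowMeans(assay(pt), na.rm = TRUE)
  rna_log2 <- rowMeans(log2Floored(assay(rna_em)))
  cls <- rep("unmatched", length(genes))
  names(cls) <- genes
  breaks <- numeric()
  if (nrow(mm$pairs)) {
    pv <- prot_mean[mm$pairs$accession]
    breaks <- if (min(pv) == max(pv))
      seq(min(pv) - 0.5, max(pv) + 0.5, length.out = n_classes + 1)
    else seq(min(pv), max(pv), length.out = n_classes + 1)
    bin <- cut(pv, breaks = breaks, include.lowest = TRUE,
               labels = paste0("C", seq_len(n_classes)))
    cls[mm$pairs$gene] <- as.character(bin)
  }
  tab <- data.frame(gene = genes, class = cls[genes],
                    rna_log2 = unname(rna_log2[genes]), row.names = NULL)
  med <- tapply(tab$rna_log2, tab$class, median)
  list(table = tab, class_medians = med, breaks = breaks)
}
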