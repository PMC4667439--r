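## End-to-end orchestration of the RNA and proteome workflows, with a
## run manifest recording inputs, parameters and per-stage counts.

digestObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

newManifest <- function(config, inputs) {
  structure(list(config = unclass(config),
                 inputs = lapply(inputs, digestObject),
                 stages = list()),
            class = "RunManifest")
}

addStage <- function(manifest, name, n_in, n_out, params = list(),
                     t0 = NULL) {
  manifest$stages[[name]] <- list(
    n_in = n_in, n_out = n_out, params = params,
    duration = if (is.null(t0)) NA_real_
               else as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest:", length(x$stages), "stages\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-18s %6s -> %-6s (%.2fs)\n", nm,
                as.character(st$n_in), as.character(st$n_out),
                ifelse(is.na(st$duration), 0, st$duration)))
  }
  invisible(x)
}

## z-scored group means (per gene across the five group means)
groupMeanZ <- function(mat, pop) {
  gm <- groupMeans(mat, pop)
  sds <- apply(gm, 1, sd)
  gm <- gm[sds > 0, , drop = FALSE]
  (gm - rowMeans(gm)) / apply(gm, 1, sd)
}

#' Run the full transcriptome signature workflow
#'
#' normalize (median-of-ratios, floor at 1) -> present filter -> variable
#' filter (PCA view) -> ANOVA DE, MCL and network modules on the present
#' genes -> effector-cluster selection -> pre-signature -> refinement ->
#' enrichment and enrichment map. When no gene passes the common-DE
#' criterion the clustering engines are skipped: the pre-signature is an
#' intersection with the DE list, so it is empty either way.
#'
#' @param counts a [CXExperiment] with `scale = "counts"`.
#' @param collection optional [GeneSetCollection] for the enrichment map.
#' @param config a [pipelineConfig()].
#' @param out_dir optional directory; when given, every intermediate table
#'   is written there as TSV.
#' @return `list(signature, pre_signature, enrichment, network, de,
#'   expression (present genes), variable, pca, mcl_clusters,
#'   wcna_modules, manifest)`.
#' @examples
#' sim <- generateRNA(n_genes = 400, n_sig = 40, n_modules = 1,
#'                    reps_per_group = 3, seed = 5, module_size = 40)
#' res <- runRNAPipeline(sim$counts,
#'                       config = pipelineConfig(wcna_min_module = 20))
#' res$signature
#' @export
runRNAPipeline <- function(counts, collection = NULL,
                           config = pipelineConfig(), out_dir = NULL) {
  stopifnot(is(counts, "CXExperiment"), scaleType(counts) == "counts")
  manifest <- newManifest(config, list(counts = counts,
                                       collection = collection))
  t0 <- Sys.time()
  sf <- medianRatioSizeFactors(counts)
  em <- normalizeCounts(counts, sf, floor = config$rna_floor)
  manifest <- addStage(manifest, "normalize", ncol(counts), ncol(em),
                       list(floor = config$rna_floor), t0)
  t0 <- Sys.time()
  present <- filterPresentRNA(em, config$present_min_mean_count)
  manifest <- addStage(manifest, "present", nrow(em), nrow(present),
                       list(min_mean = config$present_min_mean_count), t0)
  t0 <- Sys.time()
  variable <- filterVariable(present, config$variable_alpha,
                             config$variable_adjust)
  zv <- zTransform(variable)
  pca <- if (nrow(zv) >= 2) samplePCA(zv) else NULL
  manifest <- addStage(manifest, "variable", nrow(present), nrow(variable),
                       list(alpha = config$variable_alpha), t0)
  t0 <- Sys.time()
  de <- anovaDE(present, welch = config$welch)
  de_common <- commonUpregulated(de, config$de_fc, config$de_fdr)
  manifest <- addStage(manifest, "de", nrow(present), length(de_common),
                       list(fc = config$de_fc, fdr = config$de_fdr), t0)
  log2mat <- log2Floored(assay(present))
  gmz <- groupMeanZ(log2mat, populations(present))
  mcl_cs <- NULL
  mods <- NULL
  mcl_sel <- character()
  wcna_sel <- character()
  if (length(de_common)) {
    t0 <- Sys.time()
    graph <- correlationGraph(log2mat, config$mcl_min_r_rna)
    mcl_cs <- mcl(graph, inflation = config$mcl_inflation)
    if (length(clusters(mcl_cs)))
      mcl_sel <- selectEffectorCluster(mcl_cs, gmz)$genes
    manifest <- addStage(manifest, "mcl", length(graph@nodes),
                         length(clusters(mcl_cs)),
                         list(min_r = config$mcl_min_r_rna,
                              inflation = config$mcl_inflation), t0)
    t0 <- Sys.time()
    mods <- wcna(log2mat, power = config$wcna_power_rna,
                 min_module = config$wcna_min_module,
                 mediss = config$wcna_mediss_rna)
    if (length(modules(mods)))
      wcna_sel <- selectEffectorCluster(mods, gmz)$genes
    manifest <- addStage(manifest, "wcna", nrow(log2mat),
                         length(modules(mods)),
                         list(power = config$wcna_power_rna,
                              min_module = config$wcna_min_module,
                              mediss = config$wcna_mediss_rna), t0)
  } else {
    manifest <- addStage(manifest, "mcl", 0, 0, list(skipped = TRUE))
    manifest <- addStage(manifest, "wcna", 0, 0, list(skipped = TRUE))
  }
  t0 <- Sys.time()
  pre <- derivePreSignature(de_common, mcl_sel, wcna_sel, omics = "rna")
  sig <- refineSignature(pre, present, fc_min = config$refine_fc,
                         abs_diff_min = config$refine_abs_diff_rna,
                         blocklist = config$mhc2_blocklist,
                         rule = config$refine_rule,
                         subtract_cx3neg = config$subtract_cx3neg, de = de,
                         de_fc = config$de_fc, de_fdr = config$de_fdr)
  manifest <- addStage(manifest, "signature", length(signatureGenes(pre)),
                       length(signatureGenes(sig)),
                       list(fc = config$refine_fc,
                            abs_diff = config$refine_abs_diff_rna,
                            rule = config$refine_rule), t0)
  enr <- NULL
  net <- NULL
  if (!is.null(collection) && length(signatureGenes(sig))) {
    t0 <- Sys.time()
    universe <- if (config$goea_universe == "present") rownames(present)
                else rownames(em)
    enr <- hypergeomEnrich(intersect(signatureGenes(sig), universe),
                           universe, collection)
    net <- enrichmentMap(enr, collection, universe = universe,
                         jaccard_min = config$map_jaccard,
                         q_cutoff = config$map_q)
    manifest <- addStage(manifest, "goea", length(collection),
                         nrow(networkNodes(net)),
                         list(fdr = config$goea_fdr,
                              jaccard = config$map_jaccard,
                              q = config$map_q), t0)
  }
  res <- list(signature = sig, pre_signature = pre, enrichment = enr,
              network = net, de = de, expression = present,
              variable = variable, pca = pca, mcl_clusters = mcl_cs,
              wcna_modules = mods, manifest = manifest)
  if (!is.null(out_dir)) writeRNAOutputs(res, out_dir)
  res
}

writeRNAOutputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeSignature(res$signature, file.path(out_dir, "signature_refined.tsv"))
  writeSignature(res$pre_signature, file.path(out_dir, "signature_pre.tsv"))
  st <- as.data.frame(deTable(res$de))
  utils::write.table(cbind(gene = rownames(st), st,
                           foldChanges(res$de),
                           setNames(as.data.frame(foldChanges(res$de, log2 = TRUE)),
                                    paste0("log2.", colnames(foldChanges(res$de))))),
                     file.path(out_dir, "de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$network))
    writeNetwork(res$network, file.path(out_dir, "network_nodes.tsv"),
                 file.path(out_dir, "network_edges.tsv"))
  invisible(out_dir)
}

#' Run the proteome signature workflow
#'
#' flag/valid-value filter -> log2 -> downshifted-normal imputation ->
#' ANOVA DE, MCL (r >= 0.8) and network modules (power 18, merge 0.5) ->
#' pre-signature -> absolute-difference refinement.
#'
#' @param pt a [ProteinExperiment] with `scale = "linear"` and labels.
#' @param config a [pipelineConfig()].
#' @param out_dir optional output directory.
#' @return `list(signature, pre_signature, de, protein (imputed log2),
#'   mcl_clusters, wcna_modules, manifest)`.
#' @export
runProteinPipeline <- function(pt, config = pipelineConfig(),
                               out_dir = NULL) {
  stopifnot(is(pt, "ProteinExperiment"))
  manifest <- newManifest(config, list(protein = pt))
  t0 <- Sys.time()
  filt <- filterProteins(pt, config$protein_min_valid)
  manifest <- addStage(manifest, "filter", nrow(pt), nrow(filt),
                       list(min_valid = config$protein_min_valid), t0)
  t0 <- Sys.time()
  imp <- imputeMissing(filt, shift = config$impute_shift,
                       width = config$impute_width,
                       seed = stageSeed(config$rng_seed, "impute"),
                       per_column = config$impute_per_column)
  manifest <- addStage(manifest, "impute", sum(is.na(assay(filt))), 0,
                       list(shift = config$impute_shift,
                            width = config$impute_width), t0)
  em <- CXExperiment(assay(imp), populations(imp), scale = "log2")
  t0 <- Sys.time()
  de <- anovaDE(em, welch = config$welch)
  de_common <- commonUpregulated(de, config$de_fc, config$de_fdr)
  manifest <- addStage(manifest, "de", nrow(em), length(de_common),
                       list(fc = config$de_fc, fdr = config$de_fdr), t0)
  gmz <- groupMeanZ(assay(em), populations(em))
  mcl_cs <- NULL; mods <- NULL
  mcl_sel <- character(); wcna_sel <- character()
  if (length(de_common)) {
    t0 <- Sys.time()
    graph <- correlationGraph(assay(em), config$mcl_min_r_protein)
    mcl_cs <- mcl(graph, inflation = config$mcl_inflation)
    if (length(clusters(mcl_cs)))
      mcl_sel <- selectEffectorCluster(mcl_cs, gmz)$genes
    manifest <- addStage(manifest, "mcl", length(graph@nodes),
                         length(clusters(mcl_cs)),
                         list(min_r = config$mcl_min_r_protein), t0)
    t0 <- Sys.time()
    mods <- wcna(assay(em), power = config$wcna_power_protein,
                 min_module = config$wcna_min_module,
                 mediss = config$wcna_mediss_protein)
    if (length(modules(mods)))
      wcna_sel <- selectEffectorCluster(mods, gmz)$genes
    manifest <- addStage(manifest, "wcna", nrow(em), length(modules(mods)),
                         list(power = config$wcna_power_protein,
                              mediss = config$wcna_mediss_protein), t0)
  } else {
    manifest <- addStage(manifest, "mcl", 0, 0, list(skipped = TRUE))
    manifest <- addStage(manifest, "wcna", 0, 0, list(skipped = TRUE))
  }
  t0 <- Sys.time()
  pre <- derivePreSignature(de_common, mcl_sel, wcna_sel, omics = "protein")
  sig <- refineProteinSignature(pre, imp,
                                abs_diff_min = config$refine_abs_diff_protein,
                                blocklist = config$mhc2_blocklist)
  manifest <- addStage(manifest, "signature", length(signatureGenes(pre)),
                       length(signatureGenes(sig)),
                       list(abs_diff = config$refine_abs_diff_protein), t0)
  res <- list(signature = sig, pre_signature = pre, de = de, protein = imp,
              mcl_clusters = mcl_cs, wcna_modules = mods,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeSignature(sig, file.path(out_dir, "protein_signature_refined.tsv"))
    writeSignature(pre, file.path(out_dir, "protein_signature_pre.tsv"))
  }
  res
}

#' Relate the transcriptome and proteome signatures
#'
#' Computes the cross-omics overlap, the detected-in-proteome count,
#' fold-change rank tables with discordance counts in both directions
#' (pooled CX3CR1+ versus naive log2 fold changes), and the RNA expression
#' histogram by protein-abundance class.
#'
#' @param rna_res result of [runRNAPipeline()].
#' @param prot_res result of [runProteinPipeline()].
#' @param idmap named character, accession -> symbol.
#' @param n_classes protein-abundance classes for the histogram.
#' @param out_dir optional output directory.
#' @return `list(overlap, detected, rank_rna_primary, rank_protein_primary,
#'   histogram)`.
#' @export
runOverlap <- function(rna_res, prot_res, idmap, n_classes = 5,
                       out_dir = NULL) {
  rna_sig <- rna_res$signature
  prot_sig <- prot_res$signature
  pt <- prot_res$protein
  overlap <- overlapSignatures(rna_sig, prot_sig, idmap)
  detected <- detectedInProteome(rna_sig, pt, idmap)
  ## pooled CX3CR1+ vs naive log2 fold changes on each omics
  rna_mat <- log2Floored(assay(rna_res$expression))
  rna_pop <- populations(rna_res$expression)
  rna_fc <- rowMeans(rna_mat[, rna_pop %in% cxPositive(), drop = FALSE]) -
    rowMeans(rna_mat[, rna_pop == "NAIVE", drop = FALSE])
  prot_pop <- populations(pt)
  prot_fc_acc <- rowMeans(assay(pt)[, prot_pop %in% cxPositive(),
                                    drop = FALSE]) -
    rowMeans(assay(pt)[, prot_pop == "NAIVE", drop = FALSE])
  ## express protein fold changes by gene symbol for the RNA-primary view
  mm <- matchOmics(rownames(rna_mat), pt, idmap)
  prot_fc_gene <- setNames(prot_fc_acc[mm$pairs$accession], mm$pairs$gene)
  sig_genes <- signatureGenes(rna_sig)
  rank_rna <- foldChangeRank(rna_fc[intersect(sig_genes, names(rna_fc))],
                             prot_fc_gene)
  prot_members <- signatureGenes(prot_sig)
  rna_fc_for_prot <- setNames(
    rna_fc[idmap[prot_members]], prot_members)
  rank_prot <- foldChangeRank(prot_fc_acc[prot_members], rna_fc_for_prot)
  hist <- expressionClassHistogram(rna_res$expression, pt, idmap,
                                   n_classes = n_classes)
  res <- list(overlap = overlap, detected = detected,
              rank_rna_primary = rank_rna,
              rank_protein_primary = rank_prot, histogram = hist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene = overlap),
                       file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rank_rna$table,
                       file.path(out_dir, "rank_rna_primary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
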