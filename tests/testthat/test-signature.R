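test_that("pre-signature is the union of the two DE intersections", {
  de <- c("a", "b", "c")
  pre <- derivePreSignature(de, mcl_selected = c("a", "b", "x"),
                            wcna_selected = c("b", "c", "y"))
  expect_identical(signatureGenes(pre), c("a", "b", "c"))
  expect_setequal(provenance(pre)$b, c("DE&MCL", "DE&WCNA"))
  expect_identical(provenance(pre)$a, "DE&MCL")
  expect_identical(provenance(pre)$c, "DE&WCNA")
  ## empty DE list gives an empty pre-signature
  empty <- derivePreSignature(character(), c("a"), c("b"))
  expect_length(signatureGenes(empty), 0L)
  ## algebraic containment on random sets
  set.seed(4)
  for (i in 1:10) {
    u <- paste0("g", 1:30)
    d <- sample(u, 12); mc <- sample(u, 10); wc <- sample(u, 10)
    p <- derivePreSignature(d, mc, wc)
    expect_true(all(signatureGenes(p) %in% d))
    expect_setequal(signatureGenes(p),
                    union(intersect(d, mc), intersect(d, wc)))
  }
})

test_that("RNA refinement applies the FC/difference rule and blocklist", {
  pops <- cxPopulations()
  ## pooled CX3+ vs CX3- means: rows constructed per case
  gv <- rbind(weak_small  = c(5, 12, 12, 10, 10),    # FC 1.2, diff 2
              weak_big    = c(5, 3000, 3000, 2500, 2500), # FC 1.2, diff 500
              strong      = c(5, 400, 400, 100, 100),     # FC 4
              "HLA-DRA"   = c(5, 800, 800, 80, 80))       # strong but blocked
  em <- makeEM(gv, reps = 2)
  genes <- rownames(gv)
  pre <- SignatureSet(genes = genes,
                      provenance = setNames(as.list(rep("DE&MCL", 4)), genes),
                      stage = "pre", omics = "rna")
  ref_and <- refineSignature(pre, em, fc_min = 1.5, abs_diff_min = 50,
                             blocklist = defaultMHC2Blocklist(),
                             rule = "AND")
  expect_setequal(signatureGenes(ref_and), c("weak_big", "strong"))
  ref_or <- refineSignature(pre, em, fc_min = 1.5, abs_diff_min = 50,
                            blocklist = defaultMHC2Blocklist(),
                            rule = "OR")
  expect_identical(signatureGenes(ref_or), "strong")
  ## refined is always contained in pre
  expect_true(all(signatureGenes(ref_and) %in% signatureGenes(pre)))
  ## gene missing from the matrix errors
  pre2 <- SignatureSet(genes = "ghost",
                       provenance = list(ghost = "DE&MCL"),
                       stage = "pre", omics = "rna")
  expect_error(refineSignature(pre2, em), "missing from the expression")
})

test_that("protein refinement uses the absolute-difference rule only", {
  pops <- cxPopulations()
  cols <- paste0(rep(pops, each = 2), "_R", 1:2)
  vals <- rbind(P_small = c(rep(1e6, 2), rep(1.5e6, 4), rep(1.0e6, 4)),
                P_big   = c(rep(1e6, 2), rep(4e6, 4),   rep(1.5e6, 4)),
                P_hla   = c(rep(1e6, 2), rep(9e6, 4),   rep(1e6, 4)))
  colnames(vals) <- cols
  pt <- ProteinExperiment(vals, accession = rownames(vals),
                          population = rep(pops, each = 2),
                          gene_name = c("A", "B", "HLA-DRA"))
  pre <- SignatureSet(genes = rownames(vals),
                      provenance = setNames(as.list(rep("DE&MCL", 3)),
                                            rownames(vals)),
                      stage = "pre", omics = "protein")
  ref <- refineProteinSignature(pre, pt, abs_diff_min = 1e6)
  ## P_small diff 5e5 removed; P_big diff 2.5e6 kept; P_hla blocked
  expect_identical(signatureGenes(ref), "P_big")
  ## brute-force count on random tables
  set.seed(6)
  for (i in 1:10) {
    n <- 30
    rv <- matrix(10^runif(n * 10, 5.5, 7.5), n, 10,
                 dimnames = list(paste0("Q", 1:n), cols))
    ptr <- ProteinExperiment(rv, accession = rownames(rv),
                             population = rep(pops, each = 2))
    prer <- SignatureSet(genes = rownames(rv),
                         provenance = setNames(as.list(rep("DE&MCL", n)),
                                               rownames(rv)),
                         stage = "pre", omics = "protein")
    refr <- refineProteinSignature(prer, ptr, abs_diff_min = 1e6,
                                   blocklist = character())
    pos <- rowMeans(rv[, 3:6]); neg <- rowMeans(rv[, 7:10])
    expect_identical(length(signatureGenes(refr)),
                     sum(abs(pos - neg) >= 1e6))
  }
})

test_that("cross-omics matching resolves accession multiplicity by intensity", {
  pops <- cxPopulations()
  cols <- paste0(rep(pops, each = 2), "_R", 1:2)
  vals <- rbind(P1 = rep(5e6, 10), P2 = rep(9e6, 10), P3 = rep(1e6, 10))
  colnames(vals) <- cols
  pt <- ProteinExperiment(vals, accession = rownames(vals),
                          population = rep(pops, each = 2))
  idmap <- c(P1 = "GZMB", P2 = "GZMB", P3 = "PRF1")
  expect_message(mm <- matchOmics(c("GZMB", "PRF1", "SELL"), pt, idmap),
                 "higher-intensity")
  expect_identical(mm$pairs$accession[mm$pairs$gene == "GZMB"], "P2")
  expect_identical(mm$unmatched_genes, "SELL")
  ## unmapped accession is reported
  idmap2 <- c(P1 = "GZMB")
  mm2 <- matchOmics("GZMB", pt, idmap2)
  expect_setequal(mm2$unmapped_accessions, c("P2", "P3"))
  ## on fully bijective synthetic data every detected gene matches
  study <- smallStudy()
  filt <- filterProteins(study$protein)
  mm3 <- matchOmics(as.character(
    SummarizedExperiment::rowData(filt)$gene_name), filt, study$idmap)
  expect_identical(nrow(mm3$pairs), nrow(filt))
})

test_that("signature overlap and proteome detection behave as set operations", {
  idmap <- c(P_a = "a", P_b = "b", P_c = "c")
  rna <- SignatureSet(genes = c("a", "b"),
                      provenance = list(a = "DE&MCL", b = "DE&MCL"),
                      stage = "refined", omics = "rna")
  prot_same <- SignatureSet(genes = c("P_a", "P_b"),
                            provenance = list(P_a = "DE&MCL",
                                              P_b = "DE&MCL"),
                            stage = "refined", omics = "protein")
  prot_disj <- SignatureSet(genes = "P_c",
                            provenance = list(P_c = "DE&MCL"),
                            stage = "refined", omics = "protein")
  expect_setequal(overlapSignatures(rna, prot_same, idmap), c("a", "b"))
  expect_length(overlapSignatures(rna, prot_disj, idmap), 0L)
  ## detection: empty table gives zero, full table gives all
  pops <- cxPopulations()
  cols <- paste0(rep(pops, each = 2), "_R", 1:2)
  vals <- matrix(1e6, 3, 10, dimnames = list(names(idmap), cols))
  pt <- ProteinExperiment(vals, accession = names(idmap),
                          population = rep(pops, each = 2))
  expect_identical(detectedInProteome(rna, pt[0, ], idmap)$count, 0L)
  det <- detectedInProteome(rna, pt, idmap)
  expect_identical(det$count, 2L)
  expect_setequal(det$genes, c("a", "b"))
})

test_that("expression-class histograms conserve genes and track abundance", {
  study <- smallStudy()
  em <- normalizeCounts(study$counts)
  pres <- filterPresentRNA(em)
  filt <- filterProteins(study$protein)
  h <- expressionClassHistogram(pres, filt, study$idmap, n_classes = 5)
  expect_identical(nrow(h$table), nrow(pres))     # conservation
  med <- h$class_medians[paste0("C", 1:5)]
  expect_true(all(diff(med[!is.na(med)]) > 0))    # monotone in abundance
  ## degenerate: identical intensities occupy a single class
  pops <- cxPopulations()
  cols <- paste0(rep(pops, each = 2), "_R", 1:2)
  vals <- matrix(2^20, 3, 10,
                 dimnames = list(paste0("P_", rownames(pres)[1:3]), cols))
  ptc <- ProteinExperiment(log2(vals), accession = rownames(vals),
                           population = rep(pops, each = 2),
                           scale = "log2")
  idc <- setNames(rownames(pres)[1:3], rownames(vals))
  hc <- expressionClassHistogram(pres, ptc, idc, n_classes = 4)
  occupied <- setdiff(unique(hc$table$class), "unmatched")
  expect_length(occupied, 1L)
})
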