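## Seeded synthetic study generator. Plants the structure the analysis
## assumes: an effector-signature block high in both CX3CR1+ populations,
## co-regulated background modules, negative-binomial counts with
## sample-specific library sizes, log-normal protein intensities with
## missing-not-at-random dropout, and annotation terms enriched among the
## planted signature genes.

## Planted group-mean multiplier pattern for effector-signature genes:
## high in both CX3CR1+ populations, intermediate in CX3CR1-, baseline in
## naive. Per-gene effector strength e is drawn log-uniform over [4, 64]
## (canonical pattern (8, 8, 2, 2, 1) at e = 8); the CX3CR1- multiplier is
## e/4 so the CX3CR1+/CX3CR1- ratio is a constant 4. Heterogeneous effect
## sizes are what make per-gene fold changes informative (the ratio/ratio
## diagonal of concordant contrasts is flat without them).
sigMultipliers <- function(e) {
  cbind(NAIVE = rep(1, length(e)), CX3CR1P_CD62LHI = e,
        CX3CR1P_CD62LLO = e, CX3CR1N_CD62LHI = e / 4,
        CX3CR1N_CD62LLO = e / 4)
}

#' Generate a synthetic RNA-seq study with planted ground truth
#'
#' Counts are negative binomial (variance mu + d mu^2, dispersion d = 0.1)
#' with gene-wise base means drawn log-uniform over \[5, 5000\]
#' (co-regulated module genes over \[100, 5000\]: modules model expressed,
#' co-varying genes) and sample-specific library-size factors drawn
#' log-normal(0, 0.3). Planted effector-signature genes (module 1) get
#' group multipliers (e, e, e/4, e/4, 1) for (CX3CR1+CD62Lhi,
#' CX3CR1+CD62Llo, CX3CR1-CD62Lhi, CX3CR1-CD62Llo, naive), with per-gene
#' effector strength e log-uniform over \[4, 64\] around the canonical
#' (8, 8, 2, 2, 1) pattern. Each planted module shares a
#' per-sample latent log-normal factor, centered within each population so
#' co-regulation noise stays orthogonal to the group design; its scale
#' (log2 sd 0.75 for the signature block, whose group-effect pattern
#' already co-varies, and 2 for pure co-regulation modules) induces
#' within-module Pearson correlation of about 0.9 on the log2 normalized
#' scale.
#'
#' @param n_genes total genes.
#' @param n_sig planted effector-signature genes.
#' @param n_modules additional co-regulation-only modules (no group
#'   effect).
#' @param reps_per_group biological replicates per population (>= 2).
#' @param seed RNG seed; the output is fully reproducible from it.
#' @param module_size genes per co-regulation-only module.
#' @param dispersion negative-binomial dispersion d.
#' @return `list(counts = CXExperiment, truth = GroundTruth)`.
#' @examples
#' sim <- generateRNA(n_genes = 300, n_sig = 20, n_modules = 1,
#'                    reps_per_group = 3, seed = 7)
#' sim$truth
#' @export
generateRNA <- function(n_genes = 5000, n_sig = 200, n_modules = 3,
                        reps_per_group = 5, seed = 1,
                        module_size = 50, dispersion = 0.1) {
  if (reps_per_group < 2) stop("reps_per_group must be >= 2")
  if (n_sig + n_modules * module_size > n_genes)
    stop("impossible partition: n_sig + module genes (",
         n_sig + n_modules * module_size, ") exceeds n_genes (", n_genes, ")")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  pops <- cxPopulations()
  population <- rep(pops, each = reps_per_group)
  samples <- paste0(population, "_R", rep(seq_len(reps_per_group),
                                          times = length(pops)))
  ## planted partition
  module_map <- setNames(integer(n_genes), genes)
  pool <- sample(genes)
  sig_genes <- sort(pool[seq_len(n_sig)])
  module_map[sig_genes] <- 1L
  used <- n_sig
  for (m in seq_len(n_modules)) {
    mg <- pool[used + seq_len(module_size)]
    module_map[mg] <- m + 1L
    used <- used + module_size
  }
  ## base means: module genes are expressed genes
  base_mean <- 10^runif(n_genes, log10(5), log10(5000))
  base_mean[module_map > 0L] <- 10^runif(sum(module_map > 0L),
                                         log10(100), log10(5000))
  names(base_mean) <- genes
  ## group multipliers
  mult <- matrix(1, n_genes, length(pops), dimnames = list(genes, pops))
  if (n_sig > 0)
    mult[sig_genes, ] <- sigMultipliers(2^runif(n_sig, 2, 6))[, pops]
  effect <- mult * base_mean
  ## latent per-sample module factors (log2 scale), centered within each
  ## population so co-regulation noise is orthogonal to the group design
  ## (the factor models shared within-group variation, not group effects)
  tau <- c(0.75, rep(2, n_modules))  # module 1 = signature block
  n_samp <- length(samples)
  factors <- matrix(rnorm((n_modules + 1L) * n_samp), n_modules + 1L, n_samp)
  for (g in unique(population)) {
    idx <- population == g
    factors[, idx] <- factors[, idx, drop = FALSE] -
      rowMeans(factors[, idx, drop = FALSE])
  }
  lib <- rlnorm(n_samp, 0, 0.3)
  mu <- effect[, population, drop = FALSE]
  for (m in seq_len(n_modules + 1L)) {
    idx <- module_map == m
    mu[idx, ] <- mu[idx, , drop = FALSE] *
      rep(2^(tau[m] * factors[m, ]), each = sum(idx))
  }
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, n_samp, dimnames = list(genes, samples))
  truth <- GroundTruth(signatureGenes = sig_genes, moduleMap = module_map,
                       effect = effect, enrichedTerms = character())
  list(counts = CXExperiment(counts, population, scale = "counts"),
       truth = truth)
}

#' Generate a synthetic label-free proteome from planted ground truth
#'
#' A random `detect_frac` of genes get one protein row (accession
#' `"P_<gene>"`; the gene/protein map is bijective by design). Per-cell
#' log2 intensity is `a + b * log2(RNA group mean) + N(0, sd)` with
#' a = 20, b = 1, sd = 0.5. Each cell is then set missing with probability
#' logistic in minus the intensity (midpoint 27, scale 1), so dropout
#' concentrates at low abundance, the missing-not-at-random regime the
#' downshifted-normal imputation models. 2\% of rows are flagged as
#' contaminants.
#'
#' @param truth a [GroundTruth] from [generateRNA()].
#' @param detect_frac fraction of genes with a detected protein, in (0, 1].
#' @param seed RNG seed.
#' @param reps_per_group replicates per population.
#' @param a,b,noise_sd intensity model coefficients.
#' @param miss_mid,miss_scale logistic dropout midpoint and scale (log2
#'   intensity units).
#' @param contaminant_frac fraction of rows flagged as contaminant.
#' @return a [ProteinExperiment] (`scale = "linear"`, missing = `NA`).
#' @export
generateProtein <- function(truth, detect_frac = 0.8, seed = 1,
                            reps_per_group = 5, a = 20, b = 1,
                            noise_sd = 0.5, miss_mid = 27, miss_scale = 1,
                            contaminant_frac = 0.02) {
  stopifnot(is(truth, "GroundTruth"))
  if (detect_frac <= 0 || detect_frac > 1)
    stop("detect_frac must be in (0, 1]")
  set.seed(seed)
  genes <- rownames(truth@effect)
  n_det <- max(1L, round(detect_frac * length(genes)))
  det <- sort(sample(genes, n_det))
  pops <- cxPopulations()
  population <- rep(pops, each = reps_per_group)
  samples <- paste0(population, "_R", rep(seq_len(reps_per_group),
                                          times = length(pops)))
  gm <- truth@effect[det, population, drop = FALSE]
  log2i <- a + b * log2(gm) + matrix(rnorm(length(gm), 0, noise_sd),
                                     nrow(gm), ncol(gm))
  p_miss <- stats::plogis((miss_mid - log2i) / miss_scale)
  miss <- matrix(rbinom(length(p_miss), 1L, p_miss) == 1L,
                 nrow(p_miss), ncol(p_miss))
  vals <- 2^log2i
  vals[miss] <- NA_real_
  dimnames(vals) <- list(paste0("P_", det), samples)
  contaminant <- runif(n_det) < contaminant_frac
  ProteinExperiment(vals, accession = paste0("P_", det),
                    population = population, gene_name = det,
                    contaminant = contaminant)
}

#' Generate a synthetic annotation collection with planted enriched terms
#'
#' Term sizes are uniform on \[10, 200\]. A fifth of the terms (at least
#' one) are planted enriched: 60\% of their members are drawn from the
#' planted signature genes, the rest uniformly; background terms draw all
#' members uniformly from the gene universe.
#'
#' @param truth a [GroundTruth].
#' @param n_terms number of terms (0 gives an empty collection).
#' @param seed RNG seed.
#' @param enriched_frac fraction of terms planted enriched.
#' @param sig_frac fraction of an enriched term's members drawn from the
#'   signature.
#' @return `list(collection = GeneSetCollection, enriched = character,
#'   truth = GroundTruth)` where `truth` carries the planted term ids in
#'   its `enrichedTerms` slot.
#' @export
generateAnnotation <- function(truth, n_terms = 50, seed = 1,
                               enriched_frac = 0.2, sig_frac = 0.6) {
  stopifnot(is(truth, "GroundTruth"))
  set.seed(seed)
  if (n_terms == 0L) {
    coll <- GeneSetCollection(sets = list(), termNames = character())
    return(list(collection = coll, enriched = character(), truth = truth))
  }
  genes <- names(truth@moduleMap)
  sig <- truth@signatureGenes
  ids <- sprintf("TERM%04d", seq_len(n_terms))
  n_enr <- max(1L, round(enriched_frac * n_terms))
  enriched <- ids[seq_len(n_enr)]
  sets <- vector("list", n_terms)
  names(sets) <- ids
  for (i in seq_len(n_terms)) {
    size <- sample(10:200, 1L)
    if (i <= n_enr) {
      n_from_sig <- min(length(sig), round(sig_frac * size))
      members <- c(sample(sig, n_from_sig),
                   sample(setdiff(genes, sig), size - n_from_sig))
    } else {
      members <- sample(genes, size)
    }
    sets[[i]] <- sort(unique(members))
  }
  coll <- GeneSetCollection(
    sets = sets,
    termNames = setNames(paste0("synthetic term ", seq_len(n_terms)), ids))
  truth@enrichedTerms <- enriched
  validObject(truth)
  list(collection = coll, enriched = enriched, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline consumes: counts
#' with labels, protein table, annotation collection, accession-to-symbol
#' map and the combined ground truth. Per-component seeds are derived
#' deterministically from `seed`.
#'
#' @inheritParams generateRNA
#' @param detect_frac fraction of genes with a detected protein.
#' @param n_terms annotation terms.
#' @return `list(counts, protein, annotation, idmap, truth)`.
#' @examples
#' study <- simulateStudy(n_genes = 300, n_sig = 20, n_modules = 1,
#'                        reps_per_group = 3, seed = 11)
#' names(study)
#' @export
simulateStudy <- function(n_genes = 5000, n_sig = 200, n_modules = 3,
                          reps_per_group = 5, detect_frac = 0.8,
                          n_terms = 50, seed = 1) {
  rna <- generateRNA(n_genes, n_sig, n_modules, reps_per_group,
                     seed = stageSeed(seed, "rna"))
  prot <- generateProtein(rna$truth, detect_frac,
                          seed = stageSeed(seed, "protein"),
                          reps_per_group = reps_per_group)
  ann <- generateAnnotation(rna$truth, n_terms,
                            seed = stageSeed(seed, "annotation"))
  idmap <- setNames(as.character(rowData(prot)$gene_name),
                    as.character(rowData(prot)$accession))
  list(counts = rna$counts, protein = prot, annotation = ann$collection,
       idmap = idmap, truth = ann$truth)
}
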