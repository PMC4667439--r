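## Central S4 classes. Matrix-shaped data live in SummarizedExperiment
## subclasses; derived results are lightweight value classes.

#' CXExperiment: expression values for the five sorted T-cell populations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' gene-by-sample matrix plus a `population` column in `colData`. The
#' `scale` slot records what the values are:
#' \describe{
#'   \item{`counts`}{raw non-negative integer read counts}
#'   \item{`normalized_counts`}{median-of-ratios normalized counts floored
#'     at 1 (so fold changes against near-zero genes stay bounded)}
#'   \item{`log2`}{log2 intensities (microarray, log proteome, or
#'     log-transformed normalized counts)}
#'   \item{`zscore`}{per-gene standardized values (mean 0, sd 1)}
#' }
#'
#' @slot scale character scalar, one of the four scales above.
#' @param values numeric gene-by-sample matrix with unique row and column
#'   names.
#' @param population character or factor of population labels, one per
#'   sample, values from [cxPopulations()].
#' @param scale value scale, see above.
#' @return a `CXExperiment`.
#' @examples
#' m <- matrix(rpois(20, 30), nrow = 2,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
#' ce <- CXExperiment(m, rep(cxPopulations(), each = 2), scale = "counts")
#' populations(ce)
#' @export CXExperiment
#' @exportClass CXExperiment
CXExperiment <- setClass("CXExperiment",
  contains = "SummarizedExperiment",
  slots = c(scale = "character"))

setValidity("CXExperiment", function(object) {
  msg <- character()
  sc <- object@scale
  if (length(sc) != 1L ||
      !sc %in% c("counts", "normalized_counts", "log2", "zscore"))
    msg <- c(msg, "'scale' must be one of counts/normalized_counts/log2/zscore")
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  else {
    pop <- as.character(colData(object)$population)
    bad <- setdiff(unique(pop), cxPopulations())
    if (length(bad))
      msg <- c(msg, paste0("unknown population label(s): ",
                           paste(bad, collapse = ", ")))
    if (anyNA(pop)) msg <- c(msg, "population labels contain NA")
  }
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    msg <- c(msg, "at least one assay is required")
  else {
    v <- assay(object)
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(sc) == 1L && sc == "counts" && length(v)) {
      if (any(v < 0, na.rm = TRUE) || any(v != round(v), na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(sc) == 1L && sc == "normalized_counts" && length(v) &&
        any(v < 1, na.rm = TRUE))
      msg <- c(msg, "normalized counts must be floored at 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CXExperiment constructor from a plain matrix.
#' @export
CXExperiment <- function(values, population, scale = "counts") {
  values <- as.matrix(values)
  population <- as.character(population)
  if (length(population) != ncol(values))
    stop("need one population label per sample (got ", length(population),
         " labels for ", ncol(values), " samples)")
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(
      population = factor(population, levels = cxPopulations()),
      row.names = colnames(values)))
  new("CXExperiment", se, scale = scale)
}

#' @describeIn CXExperiment population labels as a factor with the five
#'   canonical levels.
#' @param x a `CXExperiment` (or `ProteinExperiment`)
#' @export
setMethod("populations", "SummarizedExperiment", function(x) {
  factor(as.character(colData(x)$population), levels = cxPopulations())
})

#' @describeIn CXExperiment the value scale.
#' @export
setMethod("scaleType", "CXExperiment", function(x) x@scale)

setMethod("show", "CXExperiment", function(object) {
  callNextMethod()
  cat("scale:", object@scale, "\n")
  cat("populations:",
      paste(levels(droplevels(populations(object))), collapse = ", "), "\n")
})

#' ProteinExperiment: label-free proteomics intensities
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass for a
#' MaxQuant-proteinGroups-style table: one row per protein group with LFQ
#' intensities per sample (missing = `NA`, never 0 internally), plus the
#' decoy/contaminant flags used for filtering. `rowData` columns:
#' `accession`, `gene_name`, `contaminant`, `reverse`, `site_only`.
#'
#' @slot scale `"linear"` (raw LFQ intensities) or `"log2"`.
#' @param intensities numeric protein-by-sample matrix; `NA` for missing.
#' @param accession character protein accessions (unique).
#' @param population population label per sample.
#' @param gene_name gene symbol per protein ("" when unknown).
#' @param contaminant,reverse,site_only logical flags per protein.
#' @param scale `"linear"` or `"log2"`.
#' @return a `ProteinExperiment`.
#' @export ProteinExperiment
#' @exportClass ProteinExperiment
ProteinExperiment <- setClass("ProteinExperiment",
  contains = "SummarizedExperiment",
  slots = c(scale = "character"))

setValidity("ProteinExperiment", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || !object@scale %in% c("linear", "log2"))
    msg <- c(msg, "'scale' must be 'linear' or 'log2'")
  need <- c("accession", "gene_name", "contaminant", "reverse", "site_only")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    for (fl in c("contaminant", "reverse", "site_only"))
      if (anyNA(rowData(object)[[fl]]))
        msg <- c(msg, paste0("flag '", fl, "' must be defined for every row"))
  }
  if (!"population" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  v <- assay(object)
  if (length(object@scale) == 1L && object@scale == "linear" &&
      any(v <= 0, na.rm = TRUE))
    msg <- c(msg, "linear intensities must be > 0 where present (0 means missing and must be NA)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProteinExperiment constructor from a plain matrix.
#' @export
ProteinExperiment <- function(intensities, accession, population,
                              gene_name = rep("", nrow(intensities)),
                              contaminant = logical(nrow(intensities)),
                              reverse = logical(nrow(intensities)),
                              site_only = logical(nrow(intensities)),
                              scale = "linear") {
  intensities <- as.matrix(intensities)
  rownames(intensities) <- accession
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = DataFrame(accession = accession, gene_name = gene_name,
                        contaminant = contaminant, reverse = reverse,
                        site_only = site_only, row.names = accession),
    colData = DataFrame(
      population = factor(as.character(population), levels = cxPopulations()),
      row.names = colnames(intensities)))
  new("ProteinExperiment", se, scale = scale)
}

#' @describeIn ProteinExperiment the intensity scale.
#' @export
setMethod("scaleType", "ProteinExperiment", function(x) x@scale)

setMethod("show", "ProteinExperiment", function(object) {
  callNextMethod()
  cat("scale:", object@scale, "| missing:",
      sum(is.na(assay(object))), "cells\n")
})

#' GroundTruth: what the synthetic generator planted
#'
#' @slot signatureGenes character ids of planted effector-signature genes.
#' @slot moduleMap named integer: planted module id per gene (0 = background,
#'   1 = the effector-signature block, 2.. = co-regulation-only modules).
#' @slot effect numeric gene-by-population matrix of group mean multipliers.
#' @slot enrichedTerms character ids of annotation terms planted to be
#'   enriched among signature genes.
#' @export GroundTruth
#' @exportClass GroundTruth
GroundTruth <- setClass("GroundTruth",
  slots = c(signatureGenes = "character", moduleMap = "integer",
            effect = "matrix", enrichedTerms = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (is.null(names(object@moduleMap)))
    msg <- c(msg, "moduleMap must be named by gene id")
  if (!all(object@signatureGenes %in% names(object@moduleMap)))
    msg <- c(msg, "signatureGenes must be a subset of all genes")
  eff <- object@effect
  if (length(eff)) {
    sg <- intersect(object@signatureGenes, rownames(eff))
    pos <- apply(eff[sg, cxPositive(), drop = FALSE], 1, min)
    neg <- apply(eff[sg, cxNegative(), drop = FALSE], 1, max)
    nv <- eff[sg, "NAIVE"]
    if (any(pos <= neg) || any(neg < nv))
      msg <- c(msg, "planted effect must satisfy CX3CR1+ > CX3CR1- >= naive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth ids of the planted signature genes.
#' @param x a `GroundTruth`
#' @export
setMethod("signatureGenes", "GroundTruth", function(x) x@signatureGenes)

#' @describeIn GroundTruth planted module id per gene (named integer).
#' @export
setMethod("moduleMap", "GroundTruth", function(x) x@moduleMap)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@moduleMap), "genes,",
      length(object@signatureGenes), "planted signature genes,",
      max(object@moduleMap), "planted modules,",
      length(object@enrichedTerms), "enriched terms\n")
})

#' DEResult: per-gene ANOVA statistics and contrast fold changes
#'
#' @slot stats `DataFrame` (one row per gene): the five group means on the
#'   normalized scale (`mean.<population>`), `F`, `p` and BH-adjusted `q`.
#' @slot fc numeric gene-by-contrast matrix of fold changes
#'   mean(test)/mean(ref).
#' @slot log2fc same, log2.
#' @slot contrasts named list of `c(test, ref)` label pairs.
#' @export
#' @exportClass DEResult
DEResult <- setClass("DEResult",
  slots = c(stats = "DataFrame", fc = "matrix", log2fc = "matrix",
            contrasts = "list"))

setValidity("DEResult", function(object) {
  msg <- character()
  st <- object@stats
  if (!all(c("F", "p", "q") %in% colnames(st)))
    msg <- c(msg, "stats must have columns F, p, q")
  else {
    if (any(st$q < st$p - 1e-12, na.rm = TRUE))
      msg <- c(msg, "q must be >= p")
  }
  if (length(object@fc) && any(object@fc <= 0, na.rm = TRUE))
    msg <- c(msg, "fold changes must be positive (inputs are floored)")
  if (nrow(object@fc) != nrow(st) || nrow(object@log2fc) != nrow(st))
    msg <- c(msg, "fc/log2fc must have one row per gene")
  if (length(msg)) msg else TRUE
})

#' @describeIn DEResult the per-gene statistics table.
#' @param x a `DEResult`
#' @export
setMethod("deTable", "DEResult", function(x) x@stats)

#' @describeIn DEResult gene-by-contrast fold-change matrix; set
#'   `log2 = TRUE` for log2 fold changes.
#' @param log2 return log2 fold changes instead of linear
#' @export
setMethod("foldChanges", "DEResult", function(x, log2 = FALSE) {
  if (log2) x@log2fc else x@fc
})

setMethod("show", "DEResult", function(object) {
  cat("DEResult:", nrow(object@stats), "genes,",
      length(object@contrasts), "contrasts (",
      paste(names(object@contrasts), collapse = ", "), ")\n",
      sum(object@stats$q < 0.05, na.rm = TRUE), "genes at q < 0.05\n")
})

#' CorrelationGraph: thresholded Pearson correlation graph
#'
#' @slot nodes character gene ids (zero-variance genes excluded upstream).
#' @slot edges data.frame with columns `from`, `to`, `weight` (Pearson r);
#'   undirected, no self loops, each pair listed once.
#' @slot minR the threshold used.
#' @export
#' @exportClass CorrelationGraph
CorrelationGraph <- setClass("CorrelationGraph",
  slots = c(nodes = "character", edges = "data.frame", minR = "numeric"))

setValidity("CorrelationGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, weight")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self loops are not allowed")
    if (any(e$weight < object@minR - 1e-12))
      msg <- c(msg, "all edge weights must be >= minR")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationGraph", function(object) {
  cat("CorrelationGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges at r >=", object@minR, "\n")
})

#' ClusterSet: disjoint gene clusters plus unassigned singletons
#'
#' @slot clusters list of disjoint character vectors (size >= 2 for MCL
#'   output), ordered by decreasing size.
#' @slot unassigned character ids not in any cluster.
#' @slot converged logical; `FALSE` when the producing iteration hit its
#'   iteration cap.
#' @export
#' @exportClass ClusterSet
ClusterSet <- setClass("ClusterSet",
  slots = c(clusters = "list", unassigned = "character",
            converged = "logical"),
  prototype = list(converged = TRUE))

setValidity("ClusterSet", function(object) {
  all_g <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(c(all_g, object@unassigned)))
    "clusters and unassigned must be disjoint" else TRUE
})

#' @describeIn ClusterSet the list of clusters.
#' @param x a `ClusterSet`
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

#' @describeIn ClusterSet genes in no cluster.
#' @export
setMethod("unassigned", "ClusterSet", function(x) x@unassigned)

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@clusters), "clusters (sizes",
      paste(head(lengths(object@clusters), 10), collapse = ", "),
      if (length(object@clusters) > 10) "...", "),",
      length(object@unassigned), "unassigned\n")
})

#' SOMGrid: a trained self-organizing map over gene expression profiles
#'
#' @slot codebook unit-by-dimension matrix of codebook vectors.
#' @slot assignment named integer: best-matching unit per gene.
#' @slot gridDim integer c(rows, cols).
#' @slot iterations training iterations performed.
#' @slot eigenProfiles unit-by-group matrix: first-eigenvector summary of
#'   member genes' group-mean profiles (the per-condition heat-map value).
#' @slot qeHistory quantization error measured at checkpoints during
#'   training (10 evenly spaced checkpoints).
#' @export
#' @exportClass SOMGrid
SOMGrid <- setClass("SOMGrid",
  slots = c(codebook = "matrix", assignment = "integer",
            gridDim = "integer", iterations = "integer",
            eigenProfiles = "matrix", qeHistory = "numeric"))

setValidity("SOMGrid", function(object) {
  msg <- character()
  if (prod(object@gridDim) != nrow(object@codebook))
    msg <- c(msg, "codebook must have one row per grid unit")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L ||
       max(object@assignment) > nrow(object@codebook)))
    msg <- c(msg, "assignments must index grid units")
  if (is.null(names(object@assignment)) && length(object@assignment))
    msg <- c(msg, "assignment must be named by gene")
  if (length(msg)) msg else TRUE
})

#' @describeIn SOMGrid best-matching unit per gene.
#' @param x a `SOMGrid`
#' @export
setMethod("somAssignment", "SOMGrid", function(x) x@assignment)

setMethod("show", "SOMGrid", function(object) {
  cat("SOMGrid:", paste(object@gridDim, collapse = "x"), "grid,",
      length(object@assignment), "genes,",
      object@iterations, "training iterations\n")
})

#' ModuleSet: weighted-correlation-network modules with eigengenes
#'
#' @slot modules named list of disjoint character vectors (module members).
#' @slot eigengenes sample-by-module matrix of unit-length eigengenes
#'   (first PC of each module's standardized expression, sign-fixed so the
#'   mean member correlation is positive).
#' @slot unassigned genes in no module (below the size cutoff).
#' @slot params list(power, minModule, mediss).
#' @export
#' @exportClass ModuleSet
ModuleSet <- setClass("ModuleSet",
  slots = c(modules = "list", eigengenes = "matrix",
            unassigned = "character", params = "list"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  g <- unlist(object@modules, use.names = FALSE)
  if (anyDuplicated(c(g, object@unassigned)))
    msg <- c(msg, "modules and unassigned must be disjoint")
  if (length(object@modules) &&
      !is.null(object@params$minModule) &&
      any(lengths(object@modules) < object@params$minModule))
    msg <- c(msg, "every module must have at least minModule members")
  if (length(object@modules) && ncol(object@eigengenes) != length(object@modules))
    msg <- c(msg, "one eigengene per module required")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModuleSet the module membership list.
#' @param x a `ModuleSet`
#' @export
setMethod("modules", "ModuleSet", function(x) x@modules)

#' @describeIn ModuleSet sample-by-module eigengene matrix.
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)

#' @describeIn ModuleSet genes below the module-size cutoff.
#' @export
setMethod("unassigned", "ModuleSet", function(x) x@unassigned)

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet:", length(object@modules), "modules (sizes",
      paste(lengths(object@modules), collapse = ", "), "),",
      length(object@unassigned), "unassigned; power =",
      object@params$power, "\n")
})

#' SignatureSet: an ordered gene (or protein) signature with provenance
#'
#' @slot genes ordered character ids.
#' @slot provenance named list: per gene, a subset of
#'   `c("DE&MCL", "DE&WCNA")` recording which intersection route(s)
#'   contributed it.
#' @slot stage `"pre"` or `"refined"`.
#' @slot omics `"rna"` or `"protein"`.
#' @export
#' @exportClass SignatureSet
SignatureSet <- setClass("SignatureSet",
  slots = c(genes = "character", provenance = "list", stage = "character",
            omics = "character"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (!object@stage %in% c("pre", "refined"))
    msg <- c(msg, "stage must be 'pre' or 'refined'")
  if (!object@omics %in% c("rna", "protein"))
    msg <- c(msg, "omics must be 'rna' or 'protein'")
  if (length(object@genes)) {
    if (!setequal(names(object@provenance), object@genes))
      msg <- c(msg, "provenance must be named by exactly the signature genes")
    else if (any(lengths(object@provenance[object@genes]) == 0L))
      msg <- c(msg, "every member needs non-empty provenance")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn SignatureSet the ordered member ids.
#' @param x a `SignatureSet`
#' @export
setMethod("signatureGenes", "SignatureSet", function(x) x@genes)

#' @describeIn SignatureSet per-member provenance list.
#' @export
setMethod("provenance", "SignatureSet", function(x) x@provenance)

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet (", object@omics, ", ", object@stage, "): ",
      length(object@genes), " members\n", sep = "")
  if (length(object@genes))
    cat(" e.g.", paste(head(object@genes, 6), collapse = ", "), "\n")
})

#' GeneSetCollection: a flat gene-set (GMT) collection
#'
#' Flat term -> member lists as read from a GMT file; no ontology-hierarchy
#' propagation is performed anywhere in the package.
#'
#' @slot sets named list of character member vectors; names are term ids.
#' @slot termNames named character of human-readable term names.
#' @export
#' @exportClass GeneSetCollection
GeneSetCollection <- setClass("GeneSetCollection",
  slots = c(sets = "list", termNames = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "term ids must be present and unique")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "every term must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSetCollection the named list of member vectors.
#' @param x a `GeneSetCollection`
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "terms, sizes",
      if (length(object@sets))
        paste0("[", min(lengths(object@sets)), ", ",
               max(lengths(object@sets)), "]") else "[]", "\n")
})

#' @describeIn GeneSetCollection number of terms.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' EnrichmentResult: hypergeometric gene-set enrichment statistics
#'
#' @slot table `DataFrame` with one row per tested term: `term_id`,
#'   `term_name`, `k` (hits in query), `K` (term size in universe), `n`
#'   (query size), `N` (universe size), `p` (upper-tail hypergeometric),
#'   `q` (BH).
#' @export
#' @exportClass EnrichmentResult
EnrichmentResult <- setClass("EnrichmentResult",
  slots = c(table = "DataFrame"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("term_id", "term_name", "k", "K", "n", "N", "p", "q")
  if (!all(need %in% colnames(tb)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$k > pmin(tb$K, tb$n)))
      msg <- c(msg, "k cannot exceed min(K, n)")
    if (any(tb$p <= 0 | tb$p > 1))
      msg <- c(msg, "p must lie in (0, 1]")
    if (any(tb$q < tb$p - 1e-12))
      msg <- c(msg, "q must be >= p")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentResult the per-term statistics table.
#' @param x an `EnrichmentResult`
#' @export
setMethod("enrichTable", "EnrichmentResult", function(x) x@table)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", nrow(object@table), "terms tested,",
      sum(object@table$q <= 0.05), "at q <= 0.05\n")
})

#' EnrichmentNetwork: enrichment-map network of significant terms
#'
#' Nodes are terms passing the FDR cutoff; edges connect term pairs whose
#' membership Jaccard similarity reaches the threshold.
#'
#' @slot nodes data.frame: `term_id`, `term_name`, `q`, `k`.
#' @slot edges data.frame: `from`, `to`, `jaccard`.
#' @slot params list(jaccardMin, qCutoff).
#' @export
#' @exportClass EnrichmentNetwork
EnrichmentNetwork <- setClass("EnrichmentNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame", params = "list"))

setValidity("EnrichmentNetwork", function(object) {
  msg <- character()
  if (nrow(object@nodes) && !is.null(object@params$qCutoff) &&
      any(object@nodes$q > object@params$qCutoff + 1e-12))
    msg <- c(msg, "all nodes must pass the q cutoff")
  if (nrow(object@edges)) {
    if (!is.null(object@params$jaccardMin) &&
        any(object@edges$jaccard < object@params$jaccardMin - 1e-12))
      msg <- c(msg, "all edges must reach the Jaccard threshold")
    if (!all(c(object@edges$from, object@edges$to) %in% object@nodes$term_id))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentNetwork the node table.
#' @param x an `EnrichmentNetwork`
#' @export
setMethod("networkNodes", "EnrichmentNetwork", function(x) x@nodes)

#' @describeIn EnrichmentNetwork the edge table.
#' @export
setMethod("networkEdges", "EnrichmentNetwork", function(x) x@edges)

setMethod("show", "EnrichmentNetwork", function(object) {
  cat("EnrichmentNetwork:", nrow(object@nodes), "terms,",
      nrow(object@edges), "edges (Jaccard >=",
      object@params$jaccardMin, ", q <=", object@params$qCutoff, ")\n")
})
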