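## On-disk formats: TSV matrices, MaxQuant-style protein tables, GMT gene
## sets, accession->symbol maps, signature tables, network node/edge lists.
## All files are tab-separated, UTF-8, '.' decimal; identifiers are
## case-sensitive opaque strings matched exactly.

readTSV <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    ...)
}

#' Read a count matrix and its sample labels
#'
#' The matrix file is a TSV with a header row of sample ids and gene ids in
#' the first column; the labels file is a two-column TSV `sample`,
#' `population` with labels from [cxPopulations()].
#'
#' @param path count matrix TSV.
#' @param labels_path sample label TSV.
#' @return a [CXExperiment] with `scale = "counts"`.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, labels_path) {
  df <- readTSV(path)
  if (ncol(df) < 2L) stop("count matrix needs gene ids plus >= 1 sample")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric count entries in ", path)
  bad <- which(vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count at gene '", genes[bad[1, 1]],
         "', sample '", samples[bad[1, 2]], "' (value ",
         vals[bad[1, , drop = FALSE]], ")")
  dimnames(vals) <- list(genes, samples)
  lab <- readTSV(labels_path)
  if (!all(c("sample", "population") %in% colnames(lab)))
    stop("labels file needs columns 'sample' and 'population'")
  lookup <- setNames(as.character(lab$population), as.character(lab$sample))
  missing_lab <- setdiff(samples, names(lookup))
  if (length(missing_lab))
    stop("unlabeled sample(s): ", paste(missing_lab, collapse = ", "))
  CXExperiment(vals, lookup[samples], scale = "counts")
}

#' @rdname readCountMatrix
#' @param x a [CXExperiment]
#' @export
writeCountMatrix <- function(x, path, labels_path) {
  stopifnot(is(x, "CXExperiment"))
  df <- data.frame(gene = rownames(x), assay(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample = colnames(x),
                    population = as.character(populations(x)))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a MaxQuant proteinGroups-style intensity table
#'
#' Expects label-free quantification columns named
#' `"LFQ intensity <sample>"` and flag columns `"Potential contaminant"`,
#' `"Reverse"`, `"Only identified by site"` holding `"+"` or empty. Zero
#' intensities mean "not quantified" and become `NA`. Column names are
#' configurable for other dialects.
#'
#' @param path proteinGroups TSV.
#' @param labels_path optional sample label TSV (as in
#'   [readCountMatrix()]); without it, populations are `NA` and group-wise
#'   operations will refuse to run.
#' @param intensity_prefix,accession_col,gene_col,contaminant_col,
#'   reverse_col,site_col dialect configuration.
#' @return a [ProteinExperiment] with `scale = "linear"`.
#' @export
readProteinTable <- function(path, labels_path = NULL,
                             intensity_prefix = "LFQ intensity ",
                             accession_col = "Majority protein IDs",
                             gene_col = "Gene names",
                             contaminant_col = "Potential contaminant",
                             reverse_col = "Reverse",
                             site_col = "Only identified by site") {
  df <- readTSV(path)
  icols <- grep(paste0("^", intensity_prefix), colnames(df), value = TRUE)
  if (!length(icols))
    stop("no intensity columns found (expected prefix '",
         intensity_prefix, "')")
  samples <- sub(paste0("^", intensity_prefix), "", icols)
  vals <- as.matrix(df[, icols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[vals == 0] <- NA_real_  # MaxQuant convention: zero = not quantified
  colnames(vals) <- samples
  parseFlag <- function(col) {
    if (!col %in% colnames(df)) return(logical(nrow(df)))
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    bad <- !v %in% c("", "+")
    if (any(bad))
      stop("malformed flag value(s) in column '", col, "' at line(s) ",
           paste(which(bad) + 1L, collapse = ", "))
    v == "+"
  }
  acc <- if (accession_col %in% colnames(df)) as.character(df[[accession_col]])
         else paste0("PG", seq_len(nrow(df)))
  gn <- if (gene_col %in% colnames(df)) as.character(df[[gene_col]])
        else rep("", nrow(df))
  gn[is.na(gn)] <- ""
  pop <- rep(NA_character_, length(samples))
  if (!is.null(labels_path)) {
    lab <- readTSV(labels_path)
    lookup <- setNames(as.character(lab$population), as.character(lab$sample))
    missing_lab <- setdiff(samples, names(lookup))
    if (length(missing_lab))
      stop("unlabeled sample(s): ", paste(missing_lab, collapse = ", "))
    pop <- lookup[samples]
  }
  ProteinExperiment(vals, accession = acc, population = pop, gene_name = gn,
                    contaminant = parseFlag(contaminant_col),
                    reverse = parseFlag(reverse_col),
                    site_only = parseFlag(site_col))
}

#' @rdname readProteinTable
#' @param x a [ProteinExperiment] on the linear scale
#' @export
writeProteinTable <- function(x, path, labels_path = NULL,
                              intensity_prefix = "LFQ intensity ") {
  stopifnot(is(x, "ProteinExperiment"), scaleType(x) == "linear")
  vals <- assay(x)
  vals[is.na(vals)] <- 0
  colnames(vals) <- paste0(intensity_prefix, colnames(vals))
  rd <- rowData(x)
  df <- data.frame(
    `Majority protein IDs` = rd$accession,
    `Gene names` = rd$gene_name,
    vals,
    `Potential contaminant` = ifelse(rd$contaminant, "+", ""),
    `Reverse` = ifelse(rd$reverse, "+", ""),
    `Only identified by site` = ifelse(rd$site_only, "+", ""),
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(sample = colnames(assay(x)),
                      population = as.character(populations(x)))
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one term per line, `term_id<TAB>description<TAB>gene...`.
#' An empty file yields an empty collection.
#'
#' @param path GMT file.
#' @return [GeneSetCollection]
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GeneSetCollection(sets = list(), termNames = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need id, description, >=1 gene): line ",
         paste(bad, collapse = ", "))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  nms <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  GeneSetCollection(sets = sets, termNames = setNames(nms, ids))
}

#' @rdname readGMT
#' @param x a [GeneSetCollection]
#' @export
writeGMT <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(names(x@sets), function(id) {
    paste(c(id, unname(x@termNames[id]), x@sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a protein-accession to gene-symbol map
#'
#' Two-column TSV `accession`, `symbol`. Many accessions may map to one
#' symbol; an accession must not map to two symbols and symbols must be
#' non-empty.
#'
#' @param path map TSV.
#' @return named character vector: `symbol` named by `accession`.
#' @export
readIDMap <- function(path) {
  df <- readTSV(path)
  if (!all(c("accession", "symbol") %in% colnames(df)))
    stop("id map needs columns 'accession' and 'symbol'")
  acc <- as.character(df$accession)
  sym <- as.character(df$symbol)
  if (any(!nzchar(sym) | is.na(sym)))
    stop("empty symbol(s) at line(s) ",
         paste(which(!nzchar(sym) | is.na(sym)) + 1L, collapse = ", "))
  dup <- unique(acc[duplicated(acc)])
  conflict <- dup[vapply(dup, function(a)
    length(unique(sym[acc == a])) > 1L, logical(1))]
  if (length(conflict))
    stop("accession(s) mapped to multiple symbols: ",
         paste(conflict, collapse = ", "))
  keep <- !duplicated(acc)
  setNames(sym[keep], acc[keep])
}

#' @rdname readIDMap
#' @param x named character vector as returned by `readIDMap`
#' @export
writeIDMap <- function(x, path) {
  utils::write.table(
    data.frame(accession = names(x), symbol = unname(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write signature tables
#'
#' TSV with columns `gene`, `provenance` (comma-joined routes), `stage`,
#' `omics`; member order is preserved.
#'
#' @param x a [SignatureSet]
#' @param path TSV path.
#' @export
writeSignature <- function(x, path) {
  stopifnot(is(x, "SignatureSet"))
  df <- data.frame(
    gene = x@genes,
    provenance = vapply(x@provenance[x@genes], paste, "", collapse = ","),
    stage = x@stage, omics = x@omics)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignature
#' @return `readSignature` returns the [SignatureSet].
#' @export
readSignature <- function(path) {
  df <- readTSV(path)
  need <- c("gene", "provenance", "stage", "omics")
  if (!all(need %in% colnames(df)))
    stop("signature file needs columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(SignatureSet(genes = character(), provenance = list(),
                        stage = "pre", omics = "rna"))
  SignatureSet(
    genes = as.character(df$gene),
    provenance = setNames(strsplit(as.character(df$provenance), ",",
                                   fixed = TRUE),
                          as.character(df$gene)),
    stage = unique(as.character(df$stage)),
    omics = unique(as.character(df$omics)))
}

#' Write an enrichment-map network as node and edge tables
#'
#' @param x an [EnrichmentNetwork]
#' @param node_path,edge_path output TSV paths.
#' @export
writeNetwork <- function(x, node_path, edge_path) {
  stopifnot(is(x, "EnrichmentNetwork"))
  utils::write.table(x@nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x@edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(node_path)
}
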