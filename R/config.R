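#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one validated list. Defaults
#' are the published operating point of the analysis:
#' \itemize{
#'   \item microarray background log2 intensity 6.7886; SOM 25 units /
#'     20,000 iterations
#'   \item RNA floor 1; present filter: group mean normalized count > 10;
#'     variable filter: ANOVA p < 0.05
#'   \item DE thresholds FC > 2, BH FDR < 0.05
#'   \item MCL: Pearson >= 0.85 (RNA) / 0.8 (protein), inflation 2.2
#'   \item network modules: soft power 7 (RNA) / 18 (protein), minimum
#'     module size 30, eigengene merge threshold 0.3 (RNA) / 0.5 (protein)
#'   \item refinement: remove genes with CX3CR1+/CX3CR1- FC < 1.5 AND
#'     absolute difference < 50 (RNA); proteins with absolute linear
#'     intensity difference < 1e6; MHC class II blocklist applied last
#'   \item proteome: >= 3 valid quantifications in at least one group;
#'     downshifted-normal imputation (mean shift 1.8 sd, width 0.3 sd)
#'   \item enrichment: hypergeometric FDR 0.05; map at Jaccard 0.25 /
#'     q 0.025
#' }
#'
#' @param ... named overrides of any default listed above.
#' @return a `PipelineConfig`: a validated named list.
#' @examples
#' cfg <- pipelineConfig(de_fdr = 0.01)
#' cfg$de_fdr
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    microarray_background = 6.7886,
    som_clusters = 25L,
    som_iterations = 20000L,
    rna_floor = 1,
    present_min_mean_count = 10,
    variable_alpha = 0.05,
    variable_adjust = FALSE,
    de_fc = 2,
    de_fdr = 0.05,
    welch = FALSE,
    mcl_min_r_rna = 0.85,
    mcl_min_r_protein = 0.8,
    mcl_inflation = 2.2,
    wcna_power_rna = 7,
    wcna_power_protein = 18,
    wcna_min_module = 30L,
    wcna_mediss_rna = 0.3,
    wcna_mediss_protein = 0.5,
    refine_fc = 1.5,
    refine_abs_diff_rna = 50,
    refine_abs_diff_protein = 1e6,
    refine_rule = "AND",
    subtract_cx3neg = FALSE,
    mhc2_blocklist = defaultMHC2Blocklist(),
    protein_min_valid = 3L,
    impute_shift = 1.8,
    impute_width = 0.3,
    impute_per_column = TRUE,
    goea_fdr = 0.05,
    goea_universe = "present",
    map_jaccard = 0.25,
    map_q = 0.025,
    rng_seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validateConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

validateConfig <- function(cfg) {
  num_pos <- c("microarray_background", "rna_floor",
               "present_min_mean_count", "variable_alpha", "de_fc", "de_fdr",
               "mcl_min_r_rna", "mcl_min_r_protein", "mcl_inflation",
               "wcna_power_rna", "wcna_power_protein", "wcna_mediss_rna",
               "wcna_mediss_protein", "refine_fc", "refine_abs_diff_rna",
               "refine_abs_diff_protein", "impute_shift", "impute_width",
               "goea_fdr", "map_jaccard", "map_q")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop("config field '", f, "' must be a single non-negative number")
  for (f in c("som_clusters", "som_iterations", "wcna_min_module",
              "protein_min_valid"))
    if (cfg[[f]] < 1) stop("config field '", f, "' must be >= 1")
  if (!cfg$refine_rule %in% c("AND", "OR"))
    stop("refine_rule must be 'AND' or 'OR'")
  if (!cfg$goea_universe %in% c("present", "all"))
    stop("goea_universe must be 'present' or 'all'")
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param x a `PipelineConfig`
#' @param path file path for YAML serialization
#' @export
writeConfig <- function(x, path) {
  stopifnot(inherits(x, "PipelineConfig"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' Default MHC class II blocklist
#'
#' Classical (polymorphic) HLA class II loci excluded from refined
#' signatures; users analysing their own data should supply their
#' annotation's symbols instead if they differ.
#'
#' @return character vector of gene symbols.
#' @export
defaultMHC2Blocklist <- function() {
  c("HLA-DRA", "HLA-DRB1", "HLA-DRB3", "HLA-DRB4", "HLA-DRB5",
    "HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DQB2",
    "HLA-DPA1", "HLA-DPB1", "HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB")
}
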