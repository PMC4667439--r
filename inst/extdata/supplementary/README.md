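# Published supplementary tables (user-supplied)

Three anchored checks in `tests/testthat/test-acceptance.R` reproduce
published headline counts from the study's supplementary material and the
GEO microarray series. Those tables are third-party data and are not
redistributed with this package; the checks fail with a pointer to this
file until you place the following TSVs here:

- `supplementary_data_2_transcriptome_signature.tsv` — the refined
  transcriptome core signature; one column `gene` (symbols).
- `supplementary_data_3_protein_profile.tsv` — the protein profile table
  in MaxQuant proteinGroups format (`Majority protein IDs`, `Gene names`,
  `LFQ intensity <sample>` columns, flag columns), plus
  `supplementary_data_3_labels.tsv` mapping `sample` to `population`
  (labels: NAIVE, CX3CR1P_CD62LHI, CX3CR1P_CD62LLO, CX3CR1N_CD62LHI,
  CX3CR1N_CD62LLO).
- `supplementary_data_5_proteome_signature.tsv` — the refined proteome
  core signature; columns `accession` and `symbol`.
- `gse63118_processed_log2.tsv` — the GEO series GSE63118 processed
  matrix (23 samples), probes in rows, plus `gse63118_labels.tsv`
  (`sample`, `population`). Values are linear-scale processed
  intensities; the check log2-transforms and quantile-normalizes them.
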