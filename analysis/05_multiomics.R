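#!/usr/bin/env Rscript

# Does the peptidome shift track the transcriptome or proteome? Differential
# expression per layer (log-CPM / log-intensity Welch t + BH), transcript vs
# protein fold-change correlation, integration of peptides-per-protein fold
# changes with both layers (decreased/unchanged/increased binning), and
# protein half-life correlations including the fastest/most stable subsets.

suppressPackageStartupMessages(library(hlaRemodel))
suppressPackageStartupMessages(library(dplyr))

rc <- read_run_config("results/inputs/config.yaml")
pep <- bind_peptide_records(lapply(seq_len(nrow(rc$peptide_files)), function(i) {
  f <- rc$peptide_files[i, ]
  read_peptide_table(f$path, f$hla_class, f$condition, f$replicate)
}))
proteome <- read_fasta_proteome(rc$proteome)
tr <- read_omics_matrix(rc$transcripts, "transcript", rc$design)
pr <- read_omics_matrix(rc$proteins, "protein", rc$design)
hl <- read_half_life(rc$half_life)

de_t <- simple_de(tr, rc$fdr_threshold)
de_p <- simple_de(pr, rc$fdr_threshold)
cat(sprintf("significant at FDR < %.2f: %d transcripts, %d proteins\n",
            rc$fdr_threshold, sum(de_t$significant), sum(de_p$significant)))
print(omics_correlation(de_t, de_p))

pep_i <- pep[pep$hla_class == "I", ]
mp <- map_peptides(pep_i, proteome, rc$il_equivalent)
su <- protein_summaries(pep_i, mp$mapping, proteome, "untreated",
                        rc$n_replicates)
st <- protein_summaries(pep_i, mp$mapping, proteome, "treated",
                        rc$n_replicates)
integ <- integrate_peptidome(su, st, de_t, de_p, bin_edges = rc$bin_edges)
cat("peptides-per-protein fold-change bins:\n")
print(table(integ$records$pep_bin))
pep_fc <- select(integ$records, feature = accession, log2fc = pep_log2fc)
cat("peptidome vs transcriptome / proteome fold-change correlations:\n")
print(bind_rows(omics_correlation(pep_fc, de_t),
                omics_correlation(pep_fc, de_p)))

half <- bind_rows(lapply(list(su, st), function(s)
  bind_rows(lapply(c("all", "top100_fast", "top100_stable"),
                   function(ss) half_life_analysis(hl, s, ss)))))
print(half)

dir.create("results/multiomics", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(de_t, "results/multiomics/diffexpr_transcript.tsv")
readr::write_tsv(de_p, "results/multiomics/diffexpr_protein.tsv")
readr::write_tsv(integ$records, "results/multiomics/integration.tsv")
readr::write_tsv(integ$bin_summary, "results/multiomics/bin_summary.tsv")
readr::write_tsv(half, "results/multiomics/half_life.tsv")
cat("tables written to results/multiomics/\n")
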