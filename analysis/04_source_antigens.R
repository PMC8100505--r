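#!/usr/bin/env Rscript

# The source-protein view: map every peptide into the proteome (I/L
# equivalent), summarize per-protein peptide counts, interval-union coverage
# and label-free intensity per condition, compare source-protein overlap and
# the peptides-per-protein histogram, and cross-reference the antigen panel
# against the class I (both conditions) and class II (treated) repertoires.

suppressPackageStartupMessages(library(hlaRemodel))
suppressPackageStartupMessages(library(dplyr))

rc <- read_run_config("results/inputs/config.yaml")
pep <- bind_peptide_records(lapply(seq_len(nrow(rc$peptide_files)), function(i) {
  f <- rc$peptide_files[i, ]
  read_peptide_table(f$path, f$hla_class, f$condition, f$replicate)
}))
proteome <- read_fasta_proteome(rc$proteome)
panel <- read_antigen_panel(rc$antigen_panel)

pep_i <- pep[pep$hla_class == "I", ]
pep_ii <- pep[pep$hla_class == "II", ]
mp <- map_peptides(pep_i, proteome, rc$il_equivalent)
cat(sprintf("unmapped class I peptides: %d\n", length(mp$unmapped)))

su <- protein_summaries(pep_i, mp$mapping, proteome, "untreated",
                        rc$n_replicates)
st <- protein_summaries(pep_i, mp$mapping, proteome, "treated",
                        rc$n_replicates)
so <- source_overlap(su, st)
cat(sprintf("source proteins: %d untreated, %d treated, %d shared\n",
            nrow(su), nrow(st), so$n_common))
common <- intersect(su$accession, st$accession)
cov_u <- mean(su$coverage_pct[su$accession %in% common])
cov_t <- mean(st$coverage_pct[st$accession %in% common])
cat(sprintf("mean coverage of shared proteins: %.2f%% -> %.2f%% (%.2f-fold)\n",
            cov_u, cov_t, cov_t / cov_u))

mp_ii <- map_peptides(pep_ii, proteome, rc$il_equivalent)
sii <- protein_summaries(pep_ii, mp_ii$mapping, proteome, "treated",
                         rc$n_replicates)
xr <- antigen_crossref(panel, su, st, sii, proteome)
cat(sprintf("antigen panel: %d resolved, %d unresolved\n",
            nrow(xr$table), length(xr$unresolved)))
print(xr$peptide_partition)

dir.create("results/sources", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(peptides_per_protein_histogram(su, st),
                 "results/sources/histogram.tsv")
su$peptide_list <- NULL
st$peptide_list <- NULL
readr::write_tsv(bind_rows(su, st), "results/sources/protein_summaries.tsv")
readr::write_tsv(so, "results/sources/source_overlap.tsv")
readr::write_tsv(xr$table, "results/sources/antigen_crossref.tsv")
cat("tables written to results/sources/\n")
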