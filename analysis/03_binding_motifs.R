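#!/usr/bin/env Rscript

# Which allotypes carry the repertoire, and does the HLA-B share rise under
# treatment? Builds the anchor-derived PSSM rank source for the six typed
# class I alleles, assigns every distinct 8-12-mer a best allele and binder
# status at percentile-rank cutoff 2, and deconvolves 9-mer motifs by Gibbs
# sampling on a subsample.

suppressPackageStartupMessages(library(hlaRemodel))
suppressPackageStartupMessages(library(dplyr))

rc <- read_run_config("results/inputs/config.yaml")
pep <- bind_peptide_records(lapply(seq_len(nrow(rc$peptide_files)), function(i) {
  f <- rc$peptide_files[i, ]
  read_peptide_table(f$path, f$hla_class, f$condition, f$replicate)
}))
calls <- call_presence(pep[pep$hla_class == "I", ], rc$n_replicates)

models <- anchor_motif_models(rc$alleles, seed = rc$seed + 101L)
seqs <- calls$sequence[nchar(calls$sequence) %in% 8:12]
binders <- assign_binders(seqs, models, rank_cutoff = rc$rank_cutoff)
cat(sprintf("binders at rank <= %s: %.1f%%\n", rc$rank_cutoff,
            100 * mean(binders$is_binder)))
for (cond_col in c("n_reps_untreated", "n_reps_treated")) {
  present <- calls$sequence[calls[[cond_col]] >= 1]
  share <- binders %>% filter(sequence %in% present) %>% count(locus) %>%
    mutate(fraction = n / sum(n))
  cat(sub("n_reps_", "", cond_col), "locus shares:\n"); print(share)
}

nine <- unique(seqs[nchar(seqs) == 9])
set.seed(rc$seed + 103L)
nine <- sort(sample(nine, min(length(nine), rc$gibbs$max_peptides)))
gc_res <- gibbs_cluster(nine, g_range = rc$gibbs$g_range,
                        iterations = rc$gibbs$iterations,
                        seed = rc$seed + 104L)
print(gc_res)

dir.create("results/binding", showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(binders, "results/binding/binder_calls.tsv")
readr::write_tsv(gc_res$runs, "results/binding/gibbs_runs.tsv")
readr::write_tsv(motif_probabilities(models[["B*40:02"]][["9"]]),
                 "results/binding/motif_B4002_9mer.tsv")
cat("tables written to results/binding/\n")
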