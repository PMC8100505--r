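# Small study configurations used across tests. Sizes are chosen so each
# fixture builds in well under a second.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 150, protein_length_range = c(100, 180),
         n_peptides_untreated = 120, n_peptides_class_ii = 80, seed = 11L),
    list(...)
  )
  do.call(synthetic_config, args)
}

tiny_sim <- function(...) {
  cfg <- tiny_cfg(...)
  proteome <- generate_proteome(cfg)
  c(list(config = cfg), generate_peptidome(cfg, proteome))
}

# Independent per-residue boolean-marking coverage oracle (brute force).
coverage_oracle <- function(protein_length, starts0, ends0) {
  hit <- rep(FALSE, protein_length)
  for (i in seq_along(starts0)) {
    hit[(starts0[i] + 1):ends0[i]] <- TRUE
  }
  100 * sum(hit) / protein_length
}

# Two planted non-overlapping anchor motifs (x2=L/x9=V vs x2=E/x9=K).
planted_motif_peptides <- function(n_per, seed = 1) {
  set.seed(seed)
  bg <- hlaRemodel:::aa_background(NULL)
  a <- hlaRemodel:::random_peptides(n_per, 9, bg)
  substr(a, 2, 2) <- "L"; substr(a, 9, 9) <- "V"
  b <- hlaRemodel:::random_peptides(n_per, 9, bg)
  substr(b, 2, 2) <- "E"; substr(b, 9, 9) <- "K"
  list(peptides = c(a, b), truth = rep(1:2, each = n_per))
}

# One peptide record row for hand-built tables.
pep_row <- function(sequence, condition, replicate, hla_class = "I",
                    intensity = 0) {
  tibble::tibble(sequence = sequence, hla_class = hla_class,
                 condition = condition, replicate = as.integer(replicate),
                 intensity = intensity,
                 source_accessions = list(character(0)))
}
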