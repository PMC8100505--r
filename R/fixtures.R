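#' Write a complete set of synthetic study inputs
#'
#' Emits exactly the file dialects the readers consume: per-replicate peptide
#' TSVs (`Peptide`/`Area` columns), the anchor-patched proteome FASTA, the
#' transcript and protein matrices, the half-life table, an antigen panel
#' drawn from the synthetic proteome, and the ground-truth sidecars
#' (`truth_peptides.tsv`, `truth_omics.tsv`) that all recovery tests key on.
#'
#' @param sim Output of [generate_peptidome()].
#' @param omics Output of [generate_omics()].
#' @param dir Output directory (created if needed).
#' @param panel Optional antigen panel tibble (see
#'   [synthetic_antigen_panel()]); omitted from the manifest when `NULL`.
#' @return A manifest list: `peptide_files` (tibble `path`, `hla_class`,
#'   `condition`, `replicate`), `proteome`, `transcripts`, `proteins`,
#'   `half_life`, `antigen_panel`, `truth_peptides`, `truth_omics`, `design`.
#' @export
write_synthetic_inputs <- function(sim, omics, dir, panel = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pep <- sim$peptides
  groups <- pep %>% distinct(.data$hla_class, .data$condition, .data$replicate)
  files <- character(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- pep %>%
      filter(.data$hla_class == g$hla_class, .data$condition == g$condition,
             .data$replicate == g$replicate)
    files[i] <- file.path(dir, sprintf("peptides_class%s_%s_rep%d.tsv",
                                       g$hla_class, g$condition, g$replicate))
    write_peptide_table(sub, files[i])
  }
  proteome_path <- file.path(dir, "proteome.fasta")
  write_fasta_proteome(sim$proteome, proteome_path)
  tr_path <- file.path(dir, "transcripts.tsv")
  pr_path <- file.path(dir, "proteins.tsv")
  write_omics_matrix(omics$transcript, tr_path)
  write_omics_matrix(omics$protein, pr_path)
  hl_path <- file.path(dir, "half_life.tsv")
  readr::write_tsv(omics$half_life, hl_path, progress = FALSE)
  panel_path <- NULL
  if (!is.null(panel)) {
    panel_path <- file.path(dir, "antigen_panel.tsv")
    readr::write_tsv(panel, panel_path, progress = FALSE)
  }
  truth_pep_path <- file.path(dir, "truth_peptides.tsv")
  readr::write_tsv(sim$truth, truth_pep_path, progress = FALSE)
  truth_om_path <- file.path(dir, "truth_omics.tsv")
  readr::write_tsv(omics$truth, truth_om_path, progress = FALSE)
  list(
    peptide_files = tibble::tibble(
      path = files, hla_class = groups$hla_class,
      condition = groups$condition, replicate = groups$replicate
    ),
    proteome = proteome_path,
    transcripts = tr_path,
    proteins = pr_path,
    half_life = hl_path,
    antigen_panel = panel_path,
    truth_peptides = truth_pep_path,
    truth_omics = truth_om_path,
    design = omics$transcript$design
  )
}

#' Draw a synthetic antigen panel from the proteome
#'
#' Samples `n` proteins and labels a fraction as breast-specific, the rest
#' cancer-associated; ids alternate between accession and gene symbol (with
#' occasional case changes) to exercise the resolution order.
#'
#' @param proteome Proteome tibble.
#' @param n Panel size.
#' @param breast_fraction Fraction labeled `breast_specific`.
#' @param seed Seed for the draw.
#' @return An antigen panel tibble (columns `id`, `label`, `subset`).
#' @export
synthetic_antigen_panel <- function(proteome, n = 598,
                                    breast_fraction = 41 / 598, seed = 1) {
  set.seed(seed)
  n <- min(n, nrow(proteome))
  pick <- sort(sample.int(nrow(proteome), n))
  use_symbol <- seq_len(n) %% 2 == 0
  id <- ifelse(use_symbol, proteome$gene_symbol[pick],
               proteome$accession[pick])
  lower <- use_symbol & (seq_len(n) %% 6 == 0)
  id[lower] <- tolower(id[lower])
  tibble::tibble(
    id = id,
    label = paste("synthetic antigen", proteome$accession[pick]),
    subset = ifelse(seq_len(n) <= round(breast_fraction * n),
                    "breast_specific", "cancer_associated")
  )
}

#' Generate a full synthetic input directory
#'
#' `tiny` is a seconds-scale preset for tests (~150 class I peptides per
#' untreated replicate); `paper_like` mirrors the study regime: ~15,000
#' class I peptides per untreated replicate, a 1.85-fold treated increase,
#' 37.5% shared class I sequences, HLA-B share 0.33 to 0.60, ~22,300 class II
#' peptides per treated replicate, three replicates.
#'
#' @param preset `"tiny"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A [run_config()] pointing at the written inputs (also serialized
#'   to `config.yaml` in `dir`).
#' @export
make_fixtures <- function(preset = c("tiny", "paper_like"), seed = 1,
                          dir = tempfile("fixtures"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "tiny") {
    list(n_proteins = 200, protein_length_range = c(120, 200),
         n_peptides_untreated = 150, n_peptides_class_ii = 100, seed = seed)
  } else {
    list(seed = seed)
  }
  args <- utils::modifyList(args, list(...))
  cfg <- do.call(synthetic_config, args)
  proteome <- generate_proteome(cfg)
  sim <- generate_peptidome(cfg, proteome)
  omics <- generate_omics(cfg, sim$truth, sim$proteome)
  panel <- synthetic_antigen_panel(
    sim$proteome, n = if (preset == "tiny") 20 else 598,
    seed = cfg$seed + 3L
  )
  manifest <- write_synthetic_inputs(sim, omics, dir, panel = panel)
  rc <- run_config(
    peptide_files = manifest$peptide_files,
    proteome = manifest$proteome,
    transcripts = manifest$transcripts,
    proteins = manifest$proteins,
    design = manifest$design,
    half_life = manifest$half_life,
    antigen_panel = manifest$antigen_panel,
    alleles = cfg$alleles,
    n_replicates = cfg$n_replicates,
    seed = seed,
    out_dir = file.path(dir, "out")
  )
  if (preset == "tiny") {
    rc$gibbs <- list(g_range = 1:2, iterations = 10, max_peptides = 200)
    rc$motif <- list(n_train = 100, n_background = 1000, pseudocount = 1)
  }
  write_run_config(rc, file.path(dir, "config.yaml"))
  rc
}
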