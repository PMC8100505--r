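#' Build a pipeline run configuration
#'
#' Consolidates input paths and analysis settings. Defaults follow the study
#' settings: percentile-rank binder cutoff 2, presence threshold of one
#' replicate, fold-change bin edges 0.5/1.5, FDR threshold 0.05. Every
#' threshold is echoed into the run report.
#'
#' @param peptide_files Data frame with columns `path`, `hla_class`,
#'   `condition`, `replicate`.
#' @param proteome,transcripts,proteins Input paths (FASTA / TSV matrices).
#' @param design Sample annotation for the omics matrices (`sample`,
#'   `condition`, `replicate`).
#' @param half_life,antigen_panel Optional input paths.
#' @param alleles Class I allele anchor specs for the built-in predictor.
#' @param external_predictions Optional TSV of external percentile ranks
#'   (used instead of the built-in models when given).
#' @param rank_cutoff,min_replicates,bin_edges,fdr_threshold Analysis
#'   thresholds.
#' @param n_replicates Replicates per condition in the peptide tables.
#' @param gibbs List: `g_range`, `iterations`, `max_peptides` (9-mers are
#'   subsampled to this size for motif deconvolution).
#' @param motif List: `n_train`, `n_background`, `pseudocount` for the
#'   built-in predictor.
#' @param il_equivalent Treat I/L as identical when mapping.
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(peptide_files, proteome, transcripts, proteins,
                       design, half_life = NULL, antigen_panel = NULL,
                       alleles = default_allele_specs(),
                       external_predictions = NULL,
                       rank_cutoff = 2, min_replicates = 1,
                       bin_edges = c(0.5, 1.5), fdr_threshold = 0.05,
                       n_replicates = 3,
                       gibbs = list(g_range = 1:6, iterations = 20,
                                    max_peptides = 1000),
                       motif = list(n_train = 200, n_background = 5000,
                                    pseudocount = 1),
                       il_equivalent = TRUE, seed = 1L,
                       out_dir = "remodel_out") {
  cfg <- list(
    peptide_files = tibble::as_tibble(peptide_files),
    proteome = proteome, transcripts = transcripts, proteins = proteins,
    design = tibble::as_tibble(design),
    half_life = half_life, antigen_panel = antigen_panel,
    alleles = alleles, external_predictions = external_predictions,
    rank_cutoff = rank_cutoff, min_replicates = min_replicates,
    bin_edges = bin_edges, fdr_threshold = fdr_threshold,
    n_replicates = as.integer(n_replicates),
    gibbs = gibbs, motif = motif,
    il_equivalent = isTRUE(il_equivalent), seed = as.integer(seed),
    out_dir = out_dir
  )
  stopifnot(all(c("path", "hla_class", "condition", "replicate") %in%
                  names(cfg$peptide_files)))
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$peptide_files <- as.data.frame(x$peptide_files)
  x$design <- as.data.frame(x$design)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path; relative input paths are resolved against its
#'   directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  base <- dirname(path)
  fix_path <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  pf <- tibble::as_tibble(as.data.frame(x$peptide_files))
  pf$path <- fix_path(pf$path)
  run_config(
    peptide_files = pf,
    proteome = fix_path(x$proteome),
    transcripts = fix_path(x$transcripts),
    proteins = fix_path(x$proteins),
    design = tibble::as_tibble(as.data.frame(x$design)),
    half_life = fix_path(x$half_life),
    antigen_panel = fix_path(x$antigen_panel),
    alleles = x$alleles,
    external_predictions = fix_path(x$external_predictions),
    rank_cutoff = x$rank_cutoff, min_replicates = x$min_replicates,
    bin_edges = unlist(x$bin_edges), fdr_threshold = x$fdr_threshold,
    n_replicates = x$n_replicates, gibbs = x$gibbs, motif = x$motif,
    il_equivalent = x$il_equivalent, seed = x$seed, out_dir = x$out_dir
  )
}

config_hash <- function(config) {
  x <- unclass(config)
  # identity of the analysis, not of file locations
  x$out_dir <- NULL
  x$peptide_files$path <- basename(x$peptide_files$path)
  for (f in c("proteome", "transcripts", "proteins", "half_life",
              "antigen_panel", "external_predictions")) {
    if (!is.null(x[[f]])) x[[f]] <- basename(x[[f]])
  }
  x$peptide_files <- as.data.frame(x$peptide_files)
  x$design <- as.data.frame(x$design)
  # hash the canonical YAML text so the hash survives serialization quirks
  rlang::hash(yaml::as.yaml(x))
}

write_output_tsv <- function(tb, path, hash) {
  for (col in names(tb)) {
    if (is.list(tb[[col]])) {
      tb[[col]] <- vapply(tb[[col]], paste, character(1), collapse = ";")
    }
  }
  writeLines(paste0("# config_hash: ", hash), path)
  readr::write_tsv(tb, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  req <- c(config$peptide_files$path, config$proteome, config$transcripts,
           config$proteins)
  opt <- c(config$half_life, config$antigen_panel,
           config$external_predictions)
  missing <- c(req, opt)[!file.exists(c(req, opt))]
  if (length(missing) > 0) {
    stop("config validation: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_condition(unique(config$peptide_files$condition))
  invisible(config)
}

#' Run the full remodeling analysis
#'
#' Executes, in order: input reading; replicate-aware presence calling and
#' condition-overlap summaries; length distributions with two-way ANOVA;
#' binder assignment and Gibbs motif deconvolution; peptide-to-protein
#' mapping, coverage, source-protein overlap and antigen cross-reference;
#' differential expression, tri-omics integration and half-life correlation.
#' All stage tables are written as TSV (with a config-hash header comment)
#' into `config$out_dir` together with a machine-readable `summary.json`
#' holding every headline statistic. A stage failure halts the run with a
#' stage-named error and leaves a `FAILED` marker next to any partial
#' outputs. Identical config and inputs give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The report (invisible list): all stage objects plus `summary`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste0("stage: ", name), conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  R <- config$n_replicates

  ## io ----------------------------------------------------------------
  io <- run_stage("io", {
    pep <- bind_peptide_records(lapply(seq_len(nrow(config$peptide_files)),
      function(i) {
        f <- config$peptide_files[i, ]
        read_peptide_table(f$path, f$hla_class, f$condition, f$replicate)
      }))
    list(
      peptides = pep,
      proteome = read_fasta_proteome(config$proteome),
      transcripts = read_omics_matrix(config$transcripts, "transcript",
                                      config$design),
      proteins = read_omics_matrix(config$proteins, "protein", config$design),
      half_life = if (!is.null(config$half_life))
        read_half_life(config$half_life),
      panel = if (!is.null(config$antigen_panel))
        read_antigen_panel(config$antigen_panel)
    )
  })
  note("io: ", nrow(io$peptides), " peptide records, ",
       nrow(io$proteome), " proteins")

  ## presence / overlap -------------------------------------------------
  ov <- run_stage("overlap", {
    calls_i <- call_presence(io$peptides[io$peptides$hla_class == "I", ], R,
                             config$min_replicates)
    calls_ii <- call_presence(io$peptides[io$peptides$hla_class == "II", ], R,
                              config$min_replicates)
    list(calls_i = calls_i, calls_ii = calls_ii,
         overlap_i = summarize_overlap(calls_i))
  })
  write_output_tsv(bind_rows(ov$calls_i, ov$calls_ii),
                   file.path(out_dir, "presence_calls.tsv"), hash)
  write_output_tsv(ov$overlap_i, file.path(out_dir, "overlap_summary.tsv"),
                   hash)
  note("overlap: ", ov$overlap_i$n_union, " distinct class I sequences, ",
       round(ov$overlap_i$pct_common, 1), "% common")

  ## lengths / ANOVA ----------------------------------------------------
  len <- run_stage("lengths", {
    dist_i <- length_distribution(io$peptides, "I", by = "condition")
    dist_ii <- if (nrow(ov$calls_ii) > 0)
      length_distribution(io$peptides, "II", by = "condition")
    anova_i <- two_way_anova(as.data.frame(dist_i$replicate),
                             value = "proportion", factor_a = "length",
                             factor_b = "group")
    list(dist_i = dist_i, dist_ii = dist_ii, anova_i = anova_i)
  })
  write_output_tsv(bind_rows(len$dist_i$group,
                             if (!is.null(len$dist_ii)) len$dist_ii$group),
                   file.path(out_dir, "length_distribution.tsv"), hash)
  write_output_tsv(len$anova_i$anova, file.path(out_dir, "anova.tsv"), hash)
  write_output_tsv(len$anova_i$contrasts,
                   file.path(out_dir, "anova_contrasts.tsv"), hash)

  ## binders / motifs ---------------------------------------------------
  bm <- run_stage("binders", {
    rank_source <- if (!is.null(config$external_predictions)) {
      read_external_predictions(config$external_predictions)
    } else {
      anchor_motif_models(
        config$alleles, lengths = 8:12,
        n_train = config$motif$n_train,
        n_background = config$motif$n_background,
        pseudocount = config$motif$pseudocount,
        seed = config$seed + 101L
      )
    }
    seqs_i <- ov$calls_i$sequence
    keep <- nchar(seqs_i) >= 8 & nchar(seqs_i) <= 12
    binders <- assign_binders(seqs_i[keep], rank_source,
                              rank_cutoff = config$rank_cutoff)
    nine <- unique(seqs_i[nchar(seqs_i) == 9])
    set.seed(config$seed + 103L)
    if (length(nine) > config$gibbs$max_peptides) {
      nine <- sort(sample(nine, config$gibbs$max_peptides))
    }
    gr <- config$gibbs$g_range
    gr <- gr[gr * 20 <= length(nine)]
    gibbs <- if (length(gr) > 0) {
      gibbs_cluster(nine, g_range = gr,
                    iterations = config$gibbs$iterations,
                    seed = config$seed + 104L)
    }
    list(binders = binders, gibbs = gibbs, n_gibbs = length(nine))
  })
  write_output_tsv(bm$binders, file.path(out_dir, "binder_calls.tsv"), hash)
  if (!is.null(bm$gibbs)) {
    write_output_tsv(bm$gibbs$runs, file.path(out_dir, "gibbs_runs.tsv"),
                     hash)
  }
  note("binders: ", round(100 * mean(bm$binders$is_binder), 1),
       "% of 8-12-mers at rank <= ", config$rank_cutoff)

  ## mapping / coverage / antigens --------------------------------------
  src <- run_stage("mapping", {
    pep_i <- io$peptides[io$peptides$hla_class == "I", ]
    pep_ii <- io$peptides[io$peptides$hla_class == "II", ]
    mp_i <- map_peptides(pep_i, io$proteome, config$il_equivalent)
    mp_ii <- if (nrow(pep_ii) > 0)
      map_peptides(pep_ii, io$proteome, config$il_equivalent)
    sum_u <- protein_summaries(pep_i, mp_i$mapping, io$proteome, "untreated", R)
    sum_t <- protein_summaries(pep_i, mp_i$mapping, io$proteome, "treated", R)
    sum_ii_t <- if (!is.null(mp_ii))
      protein_summaries(pep_ii, mp_ii$mapping, io$proteome, "treated", R)
    hist <- peptides_per_protein_histogram(sum_u, sum_t)
    so <- source_overlap(sum_u, sum_t)
    xref <- if (!is.null(io$panel))
      antigen_crossref(io$panel, sum_u, sum_t, sum_ii_t, io$proteome)
    list(map_i = mp_i, map_ii = mp_ii, sum_u = sum_u, sum_t = sum_t,
         sum_ii_t = sum_ii_t, hist = hist, source_overlap = so, xref = xref)
  })
  write_output_tsv(bind_rows(src$sum_u, src$sum_t, src$sum_ii_t),
                   file.path(out_dir, "protein_summaries.tsv"), hash)
  write_output_tsv(src$hist, file.path(out_dir, "histogram.tsv"), hash)
  write_output_tsv(src$source_overlap,
                   file.path(out_dir, "source_overlap.tsv"), hash)
  if (!is.null(src$xref)) {
    write_output_tsv(src$xref$table,
                     file.path(out_dir, "antigen_crossref.tsv"), hash)
  }
  note("mapping: ", length(src$map_i$unmapped), " unmapped class I peptides")

  ## DE / integration / half-life ---------------------------------------
  om <- run_stage("multiomics", {
    de_t <- simple_de(io$transcripts, config$fdr_threshold)
    de_p <- simple_de(io$proteins, config$fdr_threshold)
    rna_prot <- omics_correlation(de_t, de_p)
    rna_prot_sig <- tryCatch(
      omics_correlation(de_t, de_p, only_significant = TRUE),
      error = function(e) NULL)
    integ <- integrate_peptidome(src$sum_u, src$sum_t, de_t, de_p,
                                 bin_edges = config$bin_edges)
    pep_rna <- omics_correlation(
      integ$records %>% select(feature = "accession", log2fc = "pep_log2fc"),
      de_t)
    pep_prot <- omics_correlation(
      integ$records %>% select(feature = "accession", log2fc = "pep_log2fc"),
      de_p)
    hl <- if (!is.null(io$half_life)) {
      bind_rows(lapply(list(src$sum_u, src$sum_t), function(s) {
        bind_rows(lapply(c("all", "top100_fast", "top100_stable"),
                         function(ss) half_life_analysis(io$half_life, s, ss)))
      }))
    }
    list(de_t = de_t, de_p = de_p, rna_prot = rna_prot,
         rna_prot_sig = rna_prot_sig, integ = integ, pep_rna = pep_rna,
         pep_prot = pep_prot, half_life = hl)
  })
  write_output_tsv(om$de_t, file.path(out_dir, "diffexpr_transcript.tsv"),
                   hash)
  write_output_tsv(om$de_p, file.path(out_dir, "diffexpr_protein.tsv"), hash)
  write_output_tsv(om$integ$records, file.path(out_dir, "integration.tsv"),
                   hash)
  correlations <- bind_rows(
    om$rna_prot %>% mutate(pair = "transcript_vs_protein"),
    if (!is.null(om$rna_prot_sig))
      om$rna_prot_sig %>% mutate(pair = "transcript_vs_protein"),
    om$pep_rna %>% mutate(pair = "peptidome_vs_transcript"),
    om$pep_prot %>% mutate(pair = "peptidome_vs_protein")
  )
  write_output_tsv(correlations, file.path(out_dir, "correlations.tsv"), hash)
  if (!is.null(om$half_life)) {
    write_output_tsv(om$half_life, file.path(out_dir, "half_life.tsv"), hash)
  }

  ## summary -------------------------------------------------------------
  summary <- run_stage("summary", {
    pep_counts <- io$peptides %>%
      count(.data$hla_class, .data$condition, .data$replicate) %>%
      group_by(.data$hla_class, .data$condition) %>%
      summarise(mean_per_replicate = mean(.data$n), .groups = "drop")
    mean_i <- function(cond) {
      v <- pep_counts$mean_per_replicate[pep_counts$hla_class == "I" &
                                           pep_counts$condition == cond]
      if (length(v) == 0) NA_real_ else v
    }
    binder_share <- function(cond_col) {
      seqs <- ov$calls_i$sequence[ov$calls_i[[cond_col]] >= 1]
      b <- bm$binders[bm$binders$sequence %in% seqs, ]
      list(binder_fraction = mean(b$is_binder),
           locus_share = as.list(table(b$locus) / nrow(b)))
    }
    common_acc <- intersect(src$sum_u$accession, src$sum_t$accession)
    cov_u <- mean(src$sum_u$coverage_pct[src$sum_u$accession %in% common_acc])
    cov_t <- mean(src$sum_t$coverage_pct[src$sum_t$accession %in% common_acc])
    int_u <- mean(src$sum_u$log2_intensity[src$sum_u$accession %in% common_acc])
    int_t <- mean(src$sum_t$log2_intensity[src$sum_t$accession %in% common_acc])

    hist_tot <- src$hist %>% group_by(.data$condition) %>%
      summarise(n = sum(.data$n_proteins), .groups = "drop")
    invariants <- list(
      overlap_partition = with(ov$overlap_i, n_unique_untreated +
                                 n_unique_treated + n_common == n_union),
      overlap_pct_sum = abs(with(ov$overlap_i, pct_unique_untreated +
                                   pct_unique_treated + pct_common) - 100) <
        0.01,
      histogram_partition =
        hist_tot$n[hist_tot$condition == "untreated"] == nrow(src$sum_u) &&
        hist_tot$n[hist_tot$condition == "treated"] == nrow(src$sum_t),
      bin_partition = sum(table(om$integ$records$pep_bin)) ==
        nrow(om$integ$records)
    )
    if (!all(unlist(invariants))) {
      stop("partition invariant violated: ",
           paste(names(invariants)[!unlist(invariants)], collapse = ", "))
    }

    list(
      package_version = as.character(utils::packageVersion("hlaRemodel")),
      config_hash = hash,
      settings = list(rank_cutoff = config$rank_cutoff,
                      min_replicates = config$min_replicates,
                      bin_edges = config$bin_edges,
                      fdr_threshold = config$fdr_threshold,
                      seed = config$seed),
      peptide_counts = list(
        mean_per_replicate = pep_counts,
        class_i_ratio_treated_untreated = mean_i("treated") /
          mean_i("untreated")
      ),
      overlap_class_i = as.list(ov$overlap_i),
      lengths = list(
        anova_condition_p = len$anova_i$anova$p_value[
          len$anova_i$anova$term == "group"],
        prop_10_11_untreated = sum(len$dist_i$group$proportion[
          len$dist_i$group$group == "untreated" &
            len$dist_i$group$length %in% c(10, 11)]),
        prop_10_11_treated = sum(len$dist_i$group$proportion[
          len$dist_i$group$group == "treated" &
            len$dist_i$group$length %in% c(10, 11)])
      ),
      binders = list(
        untreated = binder_share("n_reps_untreated"),
        treated = binder_share("n_reps_treated"),
        gibbs_selected_g = if (!is.null(bm$gibbs)) bm$gibbs$selected_g,
        gibbs_n_peptides = bm$n_gibbs
      ),
      source_proteins = list(
        n_untreated = nrow(src$sum_u),
        n_treated = nrow(src$sum_t),
        overlap = as.list(src$source_overlap),
        mean_coverage_common_untreated = cov_u,
        mean_coverage_common_treated = cov_t,
        coverage_ratio = cov_t / cov_u,
        mean_log2_intensity_shift_common = int_t - int_u
      ),
      antigens = if (!is.null(src$xref)) list(
        n_resolved = nrow(src$xref$table),
        n_unresolved = length(src$xref$unresolved),
        peptide_partition = src$xref$peptide_partition
      ),
      diffexpr = list(
        transcript_significant = sum(om$de_t$significant),
        transcript_up = sum(om$de_t$significant & om$de_t$log2fc > 0),
        transcript_down = sum(om$de_t$significant & om$de_t$log2fc < 0),
        protein_significant = sum(om$de_p$significant),
        protein_up = sum(om$de_p$significant & om$de_p$log2fc > 0),
        protein_down = sum(om$de_p$significant & om$de_p$log2fc < 0)
      ),
      correlations = correlations,
      half_life = om$half_life,
      integration_bins = as.list(table(om$integ$records$pep_bin)),
      invariants = invariants
    )
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(log_lines, log_path)
  note("pipeline complete: ", out_dir)
  invisible(list(io = io, overlap = ov, lengths = len, binders = bm,
                 sources = src, multiomics = om, summary = summary))
}
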