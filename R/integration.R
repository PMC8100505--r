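#' Integrate peptidome fold changes with transcript and protein fold changes
#'
#' Over all proteins represented in at least one condition's class I
#' summaries, the peptides-per-protein fold change is
#' `(n_treated + 1) / (n_untreated + 1)` (the +1 pseudocount keeps proteins
#' absent from one condition analyzable). Each protein is binned by that
#' fold change: `decreased` (< 0.5), `unchanged` (0.5 to 1.5, closed
#' interval), `increased` (> 1.5), and joined to the transcript and protein
#' log2 fold changes where available; missing layers stay `NA` and are
#' excluded pairwise from correlations.
#'
#' @param summaries_untreated,summaries_treated Class I
#'   [protein_summaries()] per condition.
#' @param de_transcript,de_protein Optional [simple_de()] results keyed by
#'   protein accession.
#' @param bin_edges Length-2 fold-change bin edges (default `c(0.5, 1.5)`).
#' @return List with `records` (tibble `accession`, `n_untreated`,
#'   `n_treated`, `pep_fc`, `pep_log2fc`, `pep_bin`, `rna_log2fc`,
#'   `prot_log2fc`) and `bin_summary` (per-bin count and per-layer mean /
#'   median log2 fold change).
#' @export
integrate_peptidome <- function(summaries_untreated, summaries_treated,
                                de_transcript = NULL, de_protein = NULL,
                                bin_edges = c(0.5, 1.5)) {
  stopifnot(length(bin_edges) == 2, bin_edges[1] < bin_edges[2])
  acc <- sort(union(summaries_untreated$accession,
                    summaries_treated$accession))
  n_of <- function(s) {
    i <- match(acc, s$accession)
    ifelse(is.na(i), 0L, s$n_peptides[i])
  }
  n_u <- n_of(summaries_untreated)
  n_t <- n_of(summaries_treated)
  fc <- (n_t + 1) / (n_u + 1)
  rec <- tibble::tibble(
    accession = acc,
    n_untreated = n_u,
    n_treated = n_t,
    pep_fc = fc,
    pep_log2fc = log2(fc),
    pep_bin = dplyr::case_when(
      fc < bin_edges[1] ~ "decreased",
      fc <= bin_edges[2] ~ "unchanged",
      TRUE ~ "increased"
    )
  )
  join_layer <- function(rec, de, col) {
    rec[[col]] <- if (is.null(de)) NA_real_ else
      de$log2fc[match(rec$accession, de$feature)]
    rec
  }
  rec <- join_layer(rec, de_transcript, "rna_log2fc")
  rec <- join_layer(rec, de_protein, "prot_log2fc")

  bin_summary <- rec %>%
    tidyr::pivot_longer(c("rna_log2fc", "prot_log2fc"), names_to = "layer",
                        values_to = "log2fc") %>%
    filter(!is.na(.data$log2fc)) %>%
    group_by(.data$pep_bin, .data$layer) %>%
    summarise(n = n(), mean_log2fc = mean(.data$log2fc),
              median_log2fc = stats::median(.data$log2fc), .groups = "drop")
  list(records = rec, bin_summary = bin_summary)
}

#' Correlate protein half-life with peptide representation
#'
#' Pearson correlation between protein half-life (hours) and the number of
#' distinct peptides per protein in one condition, over the joined proteins,
#' for all proteins or for the 100 fastest-degrading (smallest half-life) or
#' 100 most stable (largest) proteins present in the join. If fewer than
#' `n_top` proteins are available the subset uses all of them with a
#' warning.
#'
#' @param half_life Tibble from [read_half_life()].
#' @param summaries A condition's [protein_summaries()].
#' @param subset `"all"`, `"top100_fast"` or `"top100_stable"`.
#' @param n_top Subset size (default 100).
#' @return One-row tibble `condition`, `subset`, `r`, `p_value`, `n`.
#' @export
half_life_analysis <- function(half_life, summaries,
                               subset = c("all", "top100_fast",
                                          "top100_stable"),
                               n_top = 100) {
  subset <- match.arg(subset)
  joined <- dplyr::inner_join(
    summaries[, c("accession", "condition", "n_peptides")],
    half_life, by = "accession"
  )
  if (subset != "all") {
    if (nrow(joined) < n_top) {
      warning("only ", nrow(joined), " joined proteins available for ",
              subset, "; using all of them", call. = FALSE)
    }
    ord <- order(joined$half_life_hours,
                 decreasing = (subset == "top100_stable"))
    joined <- joined[head(ord, n_top), ]
  }
  if (nrow(joined) < 3) {
    stop("fewer than 3 joined proteins after subsetting", call. = FALSE)
  }
  ct <- cor.test(joined$half_life_hours, joined$n_peptides,
                 method = "pearson")
  tibble::tibble(
    condition = joined$condition[1],
    subset = subset,
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(joined)
  )
}
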