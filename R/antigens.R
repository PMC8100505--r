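resolve_panel_ids <- function(ids, proteome) {
  acc <- proteome$accession
  sym <- proteome$gene_symbol
  out <- character(length(ids))
  ambiguous <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    if (id %in% acc) {
      out[i] <- id
      next
    }
    hit <- acc[!is.na(sym) & sym == id]
    if (length(hit) == 0) {
      hit <- acc[!is.na(sym) & tolower(sym) == tolower(id)]
    }
    if (length(hit) > 1) {
      ambiguous <- c(ambiguous, id)
      hit <- sort(hit)[1]
    }
    out[i] <- if (length(hit) == 1) hit else NA_character_
  }
  list(accession = out, ambiguous = ambiguous)
}

#' Cross-reference an antigen panel against the immunopeptidomes
#'
#' Resolves panel ids against the proteome (exact accession, then gene
#' symbol, then case-insensitive symbol; first hit wins and ambiguity is
#' logged), then reports per-antigen peptide counts in the HLA-I untreated,
#' HLA-I treated and HLA-II treated repertoires, the 3-set membership, and
#' the log2 fold change of HLA-I peptide count
#' (`log2((n_treated + 1) / (n_untreated + 1))`, a documented pseudocount
#' convention) for antigens represented under both conditions. A
#' peptide-level unique/common partition restricted to the panel is also
#' returned.
#'
#' @param panel Antigen panel tibble from [read_antigen_panel()].
#' @param summaries_i_untreated,summaries_i_treated Class I
#'   [protein_summaries()] per condition.
#' @param summaries_ii_treated Class II treated summaries (optional).
#' @param proteome Proteome tibble used for id resolution.
#' @return List with `table` (per-antigen counts, membership flags,
#'   `log2fc_i`), `peptide_partition` (panel-restricted class I peptide
#'   categories), `unresolved` and `ambiguous` id vectors.
#' @export
antigen_crossref <- function(panel, summaries_i_untreated,
                             summaries_i_treated, summaries_ii_treated = NULL,
                             proteome) {
  if (nrow(panel) == 0) stop("empty antigen panel", call. = FALSE)
  res <- resolve_panel_ids(panel$id, proteome)
  unresolved <- panel$id[is.na(res$accession)]

  count_of <- function(summaries, acc) {
    if (is.null(summaries)) return(rep(0L, length(acc)))
    i <- match(acc, summaries$accession)
    ifelse(is.na(i), 0L, summaries$n_peptides[i])
  }
  tb <- tibble::tibble(
    id = panel$id,
    label = panel$label,
    subset = panel$subset,
    accession = res$accession
  ) %>% filter(!is.na(.data$accession))
  tb$n_hla_i_untreated <- count_of(summaries_i_untreated, tb$accession)
  tb$n_hla_i_treated <- count_of(summaries_i_treated, tb$accession)
  tb$n_hla_ii_treated <- count_of(summaries_ii_treated, tb$accession)
  tb$in_hla_i_untreated <- tb$n_hla_i_untreated > 0
  tb$in_hla_i_treated <- tb$n_hla_i_treated > 0
  tb$in_hla_ii_treated <- tb$n_hla_ii_treated > 0
  tb$log2fc_i <- ifelse(
    tb$in_hla_i_untreated & tb$in_hla_i_treated,
    log2((tb$n_hla_i_treated + 1) / (tb$n_hla_i_untreated + 1)),
    NA_real_
  )

  peptides_of <- function(summaries, acc) {
    if (is.null(summaries)) return(character(0))
    unique(unlist(summaries$peptide_list[summaries$accession %in% acc]))
  }
  pu <- peptides_of(summaries_i_untreated, tb$accession)
  pt <- peptides_of(summaries_i_treated, tb$accession)
  partition <- tibble::tibble(
    category = c("unique_untreated", "common", "unique_treated"),
    n_peptides = c(length(setdiff(pu, pt)), length(intersect(pu, pt)),
                   length(setdiff(pt, pu)))
  )
  list(table = tb, peptide_partition = partition,
       unresolved = unresolved, ambiguous = res$ambiguous)
}
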