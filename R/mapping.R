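#' Map peptides to source proteins by exact substring search
#'
#' Every occurrence of every distinct peptide in every protein is reported;
#' a multi-mapped peptide counts toward each matching protein (no
#' razor/parsimony logic). With `il_equivalent = TRUE` (default) isoleucine
#' and leucine are treated as identical, as they are indistinguishable by
#' their residue mass in the eluted-peptide identifications. Match
#' coordinates are 0-based half-open intervals. Unmapped peptides are
#' reported, never silently dropped.
#'
#' @param peptides Peptide record table or character vector of sequences.
#' @param proteome Proteome tibble (see [read_fasta_proteome()]).
#' @param il_equivalent Treat I and L as identical (default `TRUE`).
#' @return A list with `mapping` (tibble `sequence`, `accession`, `start`,
#'   `end`) and `unmapped` (character vector).
#' @export
map_peptides <- function(peptides, proteome, il_equivalent = TRUE) {
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  seqs <- if (is.character(peptides)) peptides else peptides$sequence
  seqs <- unique(seqs)
  if (length(seqs) == 0) {
    return(list(mapping = tibble::tibble(sequence = character(),
                                         accession = character(),
                                         start = integer(), end = integer()),
                unmapped = character(0)))
  }
  needles <- if (il_equivalent) il_collapse(seqs) else seqs
  hay <- if (il_equivalent) il_collapse(proteome$sequence) else
    proteome$sequence
  hits <- cpp_match_peptides(hay, needles)
  mapping <- tibble::tibble(
    sequence = seqs[hits$peptide],
    accession = proteome$accession[hits$protein],
    start = hits$start,
    end = hits$start + nchar(seqs[hits$peptide])
  ) %>% arrange(.data$sequence, .data$accession, .data$start)
  unmapped <- setdiff(seqs, mapping$sequence)
  list(mapping = mapping, unmapped = unmapped)
}

#' Fill peptide records' source accessions from a mapping
#'
#' @param records Peptide record table.
#' @param mapping Mapping tibble from [map_peptides()].
#' @return The records with `source_accessions` replaced by the mapped
#'   accessions (empty for unmapped peptides).
#' @export
fill_source_accessions <- function(records, mapping) {
  by_seq <- split(mapping$accession, mapping$sequence)
  records$source_accessions <- lapply(records$sequence, function(s) {
    unique(by_seq[[s]]) %||% character(0)
  })
  records
}

#' Per-protein peptidome summaries for one condition
#'
#' For every protein with at least one mapped peptide present in the given
#' condition: the number of distinct peptides, the percent of residues
#' covered by at least one mapped peptide (interval union, no double
#' counting), and the label-free intensity summary
#' `mean over replicates of log2(1 + sum of that replicate's mapped peptide
#' intensities)` --- the `+1` tolerates unquantified peptides and replicates
#' with no detection.
#'
#' @param peptides Peptide record table (one HLA class).
#' @param mapping Mapping tibble from [map_peptides()].
#' @param proteome Proteome tibble.
#' @param condition Condition to summarize.
#' @param n_replicates Number of replicates of that condition.
#' @param unique_mappers_only Drop peptides mapping to more than one protein
#'   (sensitivity-analysis mode, default `FALSE`).
#' @return Tibble `accession`, `condition`, `n_peptides`, `coverage_pct`,
#'   `log2_intensity`, `peptide_list` (list column).
#' @export
protein_summaries <- function(peptides, mapping, proteome, condition,
                              n_replicates, unique_mappers_only = FALSE) {
  check_condition(condition)
  recs <- peptides[peptides$condition == condition, ]
  present <- unique(recs$sequence)
  map <- mapping[mapping$sequence %in% present, ]
  if (unique_mappers_only) {
    n_prot <- map %>% distinct(.data$sequence, .data$accession) %>%
      count(.data$sequence)
    multi <- n_prot$sequence[n_prot$n > 1]
    map <- map[!map$sequence %in% multi, ]
  }
  if (nrow(map) == 0) {
    return(tibble::tibble(accession = character(), condition = character(),
                          n_peptides = integer(), coverage_pct = double(),
                          log2_intensity = double(), peptide_list = list()))
  }
  prot_len <- setNames(nchar(proteome$sequence), proteome$accession)

  ir <- IRanges::IRanges(start = map$start + 1L, end = map$end)
  covered <- sum(IRanges::width(IRanges::reduce(
    S4Vectors::split(ir, map$accession))))
  cov <- map %>%
    group_by(.data$accession) %>%
    summarise(
      n_peptides = n_distinct(.data$sequence),
      peptide_list = list(sort(unique(.data$sequence))),
      .groups = "drop"
    ) %>%
    mutate(coverage_pct = 100 * unname(covered[.data$accession]) /
             unname(prot_len[.data$accession]))

  # replicate-level intensity sums per protein, averaged over all replicates
  pep_prot <- map %>% distinct(.data$sequence, .data$accession)
  int_tb <- recs %>%
    select("sequence", "replicate", "intensity") %>%
    dplyr::inner_join(pep_prot, by = "sequence",
                      relationship = "many-to-many") %>%
    group_by(.data$accession, .data$replicate) %>%
    summarise(total = sum(.data$intensity), .groups = "drop") %>%
    group_by(.data$accession) %>%
    summarise(
      log2_intensity = sum(log2(1 + .data$total)) / n_replicates,
      .groups = "drop"
    )

  cov %>%
    left_join(int_tb, by = "accession") %>%
    mutate(condition = condition,
           log2_intensity = dplyr::coalesce(.data$log2_intensity, 0)) %>%
    select("accession", "condition", "n_peptides", "coverage_pct",
           "log2_intensity", "peptide_list") %>%
    arrange(.data$accession)
}

#' Peptides-per-protein histogram
#'
#' Bins each condition's proteins by their distinct peptide count into
#' `1, 2, 3, 4, 5, 6-20, 21+`.
#'
#' @param summaries_untreated,summaries_treated Outputs of
#'   [protein_summaries()].
#' @return Tibble `bin`, `condition`, `n_proteins`; per condition the bin
#'   totals equal the number of represented proteins.
#' @export
peptides_per_protein_histogram <- function(summaries_untreated,
                                           summaries_treated) {
  bin_one <- function(s) {
    bins <- cut(s$n_peptides, breaks = c(0, 1, 2, 3, 4, 5, 20, Inf),
                labels = c("1", "2", "3", "4", "5", "6-20", "21+"))
    tibble::tibble(condition = s$condition[1] %||% NA_character_,
                   bin = bins) %>%
      count(.data$condition, .data$bin, name = "n_proteins", .drop = FALSE)
  }
  bind_rows(bin_one(summaries_untreated), bin_one(summaries_treated)) %>%
    filter(!is.na(.data$condition))
}

#' Source-protein overlap between conditions
#'
#' @param summaries_untreated,summaries_treated Outputs of
#'   [protein_summaries()].
#' @return One-row tibble of unique/common counts and percentages of the
#'   union (same conventions as [summarize_overlap()]).
#' @export
source_overlap <- function(summaries_untreated, summaries_treated) {
  su <- unique(summaries_untreated$accession)
  st <- unique(summaries_treated$accession)
  n_common <- length(intersect(su, st))
  n_uu <- length(setdiff(su, st))
  n_ut <- length(setdiff(st, su))
  union <- n_common + n_uu + n_ut
  tibble::tibble(
    n_unique_untreated = n_uu, n_unique_treated = n_ut, n_common = n_common,
    n_union = union,
    pct_unique_untreated = 100 * n_uu / union,
    pct_unique_treated = 100 * n_ut / union,
    pct_common = 100 * n_common / union
  )
}
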