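#' Read a reference proteome FASTA
#'
#' Parses a protein FASTA into an accession-keyed table. Headers in the
#' UniProt dialect (`>sp|ACC|NAME description GN=SYMBOL`) yield the accession
#' from the second pipe field and the gene symbol from the `GN=` tag; bare
#' headers (`>ACC description`) use the first whitespace token. Sequences
#' containing non-canonical residues (e.g. U, X) are tolerated but flagged.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `accession`, `sequence`, `description`,
#'   `gene_symbol`, `nonstandard` (logical flag).
#' @export
read_fasta_proteome <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  seqs <- as.character(ss)
  token1 <- sub("\\s.*$", "", headers)
  uniprot <- grepl("^(sp|tr)\\|", token1)
  accession <- ifelse(
    uniprot,
    vapply(strsplit(token1, "|", fixed = TRUE),
           function(p) if (length(p) >= 2) p[[2]] else p[[1]], character(1)),
    token1
  )
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("zero-length sequence for record(s): ",
         paste(accession[empty], collapse = ", "), call. = FALSE)
  }
  gene_symbol <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  description <- sub("^\\S+\\s*", "", headers)
  description <- trimws(gsub("GN=\\S+", "", description))
  nonstandard <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), seqs)
  if (any(nonstandard)) {
    warning("non-canonical residues (U/X/...) in: ",
            paste(head(accession[nonstandard], 10), collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    accession = accession,
    sequence = unname(seqs),
    description = description,
    gene_symbol = gene_symbol,
    nonstandard = nonstandard
  )
}

#' Write a proteome table as FASTA
#'
#' Emits headers as `>ACC description GN=SYMBOL` (the `GN=` tag only when a
#' gene symbol is present), the bare dialect [read_fasta_proteome()] parses,
#' so writing and re-reading round-trips.
#'
#' @param proteome A proteome tibble (see [read_fasta_proteome()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteome <- function(proteome, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteome)))
  desc <- proteome$description %||% rep("", nrow(proteome))
  gene <- proteome$gene_symbol %||% rep(NA_character_, nrow(proteome))
  hdr <- trimws(paste(
    proteome$accession,
    ifelse(is.na(desc) | !nzchar(desc), "", desc),
    ifelse(is.na(gene), "", paste0("GN=", gene))
  ))
  hdr <- gsub("\\s+", " ", hdr)
  ss <- Biostrings::AAStringSet(proteome$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
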