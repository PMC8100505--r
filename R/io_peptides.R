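#' Clean a peptide sequence string
#'
#' Strips modification annotations in parentheses or square brackets (as
#' written by search-engine exports, e.g. `"AL(+15.99)DPHSGHFV"`), removes
#' whitespace and terminal dots, and upper-cases the result. The operation is
#' idempotent: `clean_peptide_sequence(clean_peptide_sequence(x))` equals
#' `clean_peptide_sequence(x)`.
#'
#' @param x Character vector of raw peptide strings.
#' @return Character vector of bare upper-case sequences.
#' @export
#' @examples
#' clean_peptide_sequence("AL(+15.99)DPHSGHFV")
clean_peptide_sequence <- function(x) {
  y <- as.character(x)
  repeat {
    z <- gsub("\\([^()]*\\)|\\[[^][]*\\]", "", y)
    if (identical(z, y)) break
    y <- z
  }
  y <- gsub("[[:space:].]", "", y)
  toupper(y)
}

peptide_table_cols <- function() {
  c("sequence", "hla_class", "condition", "replicate", "intensity",
    "source_accessions")
}

empty_peptide_table <- function() {
  tibble::tibble(
    sequence = character(),
    hla_class = character(),
    condition = character(),
    replicate = integer(),
    intensity = double(),
    source_accessions = list()
  )
}

#' Read a peptide identification table
#'
#' Reads one replicate's exported peptide identifications (TSV or CSV) into a
#' typed record table. Sequences are cleaned with [clean_peptide_sequence()],
#' validated against the 20-letter amino-acid alphabet, restricted to 7-30
#' residues, and deduplicated within the file keeping the maximum intensity
#' (a duplicate identification arises from the same eluted species split
#' across fractions, so intensities are not summed).
#'
#' @param path Path to a TSV/CSV file with a header. The sequence column may
#'   be named `Peptide`/`peptide`/`Sequence`/`sequence` (or given via
#'   `sequence_col`); intensity `Area`/`area`/`Intensity`/`intensity`;
#'   accessions `Accession`/`accession`/`Protein Accession`.
#' @param hla_class `"I"` or `"II"`.
#' @param condition `"untreated"` or `"treated"`.
#' @param replicate Positive integer replicate number.
#' @param sequence_col,intensity_col,accession_col Optional explicit column
#'   names overriding the recognised dialects.
#' @return A tibble with columns `sequence`, `hla_class`, `condition`,
#'   `replicate`, `intensity`, `source_accessions` (list column).
#' @export
read_peptide_table <- function(path, hla_class, condition, replicate,
                               sequence_col = NULL, intensity_col = NULL,
                               accession_col = NULL) {
  stopifnot(length(path) == 1, file.exists(path))
  hla_class <- match.arg(hla_class, c("I", "II"))
  check_condition(condition)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1) stop("replicate must be >= 1", call. = FALSE)

  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, comment = "#")

  pick <- function(given, candidates, what, required = FALSE) {
    if (!is.null(given)) {
      if (!given %in% names(raw)) stop("column '", given, "' not found", call. = FALSE)
      return(given)
    }
    hit <- intersect(candidates, names(raw))
    if (length(hit) == 0) {
      if (required) {
        stop("no ", what, " column found; expected one of: ",
             paste(candidates, collapse = ", "), call. = FALSE)
      }
      return(NULL)
    }
    hit[[1]]
  }
  seq_col <- pick(sequence_col, c("Peptide", "peptide", "Sequence", "sequence"),
                  "peptide-sequence", required = TRUE)
  int_col <- pick(intensity_col, c("Area", "area", "Intensity", "intensity"),
                  "intensity")
  acc_col <- pick(accession_col, c("Accession", "accession", "Protein Accession",
                                   "Protein", "protein"), "accession")

  if (nrow(raw) == 0) {
    warning("empty peptide table: ", path, call. = FALSE)
    return(empty_peptide_table())
  }

  sequence <- clean_peptide_sequence(raw[[seq_col]])
  bad <- which(!grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), sequence))
  if (length(bad) > 0) {
    stop("non-canonical residues after cleaning in rows: ",
         paste(head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "", call. = FALSE)
  }
  len <- nchar(sequence)
  out_of_range <- len < 7 | len > 30
  if (any(out_of_range)) {
    warning(sum(out_of_range), " peptide(s) outside 7-30 residues dropped",
            call. = FALSE)
  }

  intensity <- if (is.null(int_col)) rep(0, nrow(raw)) else {
    v <- suppressWarnings(as.numeric(raw[[int_col]]))
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative intensity value", call. = FALSE)
    v
  }
  accessions <- if (is.null(acc_col)) rep(NA_character_, nrow(raw)) else
    as.character(raw[[acc_col]])

  tb <- tibble::tibble(sequence = sequence, intensity = intensity,
                       accession = accessions)[!out_of_range, ]
  tb <- tb %>%
    group_by(.data$sequence) %>%
    summarise(
      intensity = max(.data$intensity),
      accession = paste(unique(.data$accession[!is.na(.data$accession)]),
                        collapse = ";"),
      .groups = "drop"
    ) %>%
    arrange(.data$sequence)

  tibble::tibble(
    sequence = tb$sequence,
    hla_class = hla_class,
    condition = condition,
    replicate = replicate,
    intensity = tb$intensity,
    source_accessions = lapply(strsplit(tb$accession, ";", fixed = TRUE),
                               function(a) a[nzchar(a)])
  )
}

#' Write a peptide record table
#'
#' Writes one replicate's records in the TSV dialect [read_peptide_table()]
#' reads (columns `Peptide`, `Area`, `Accession`), so a written table
#' round-trips to an identical in-memory object.
#'
#' @param records A peptide record tibble for a single class/condition/replicate.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  stopifnot(all(peptide_table_cols() %in% names(records)))
  out <- tibble::tibble(
    Peptide = records$sequence,
    Area = records$intensity,
    Accession = vapply(records$source_accessions,
                       function(a) paste(a, collapse = ";"), character(1))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Bind and validate peptide record tables
#'
#' Stacks per-replicate record tables and enforces the record invariants:
#' canonical alphabet, 7-30 residue length, and uniqueness of
#' (sequence, class, condition, replicate).
#'
#' @param ... Peptide record tibbles (or a single list of them).
#' @return A single validated tibble.
#' @export
bind_peptide_records <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  rec <- bind_rows(parts)
  if (nrow(rec) == 0) return(empty_peptide_table())
  stopifnot(all(nchar(rec$sequence) >= 7), all(nchar(rec$sequence) <= 30))
  key <- paste(rec$sequence, rec$hla_class, rec$condition, rec$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (sequence, class, condition, replicate) records", call. = FALSE)
  }
  rec
}
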