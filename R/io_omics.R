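new_omics_table <- function(values, design, layer) {
  stopifnot(is.matrix(values), nrow(design) == ncol(values))
  structure(
    list(values = values, design = tibble::as_tibble(design), layer = layer,
         all_zero = rownames(values)[rowSums(values) == 0]),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat("<omics_table> layer:", x$layer, "-", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  cat("  conditions:", paste(sprintf(
    "%s(%d)", names(table(x$design$condition)), table(x$design$condition)),
    collapse = ", "), "\n")
  if (length(x$all_zero) > 0) {
    cat("  all-zero features flagged:", length(x$all_zero), "\n")
  }
  invisible(x)
}

normalize_design <- function(design, samples) {
  if (is.vector(design) && !is.null(names(design))) {
    design <- tibble::tibble(sample = names(design),
                             condition = unname(design))
  }
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample", "condition") %in% names(design)))
  check_condition(design$condition)
  if (anyDuplicated(design$sample)) stop("duplicate sample in design", call. = FALSE)
  missing <- setdiff(samples, design$sample)
  if (length(missing) > 0) {
    stop("sample(s) in file absent from design: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  design <- design[match(samples, design$sample), ]
  if (!"replicate" %in% names(design)) {
    design <- design %>%
      group_by(.data$condition) %>%
      mutate(replicate = seq_len(n())) %>%
      ungroup()
  }
  design
}

#' Read a feature x sample quantification matrix
#'
#' Reads a TSV whose first column holds feature IDs (gene or protein
#' accessions) and remaining columns one sample each. Values must be
#' non-negative reals; all-zero rows are retained but flagged.
#'
#' @param path TSV file path.
#' @param layer `"transcript"` or `"protein"`.
#' @param design Sample annotation: a data frame with columns
#'   `sample`, `condition` (and optionally `replicate`), or a named character
#'   vector `sample -> condition`. Must cover every sample column in the file.
#' @return An `omics_table`: list with `values` (numeric matrix, features in
#'   rownames), `design`, `layer`, and `all_zero` (flagged feature IDs).
#' @export
read_omics_matrix <- function(path, layer, design) {
  stopifnot(file.exists(path))
  layer <- match.arg(layer, c("transcript", "protein"))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  if (ncol(raw) < 2) stop("matrix must have a feature column and >=1 sample", call. = FALSE)
  features <- as.character(raw[[1]])
  if (anyDuplicated(features)) {
    stop("duplicate feature ID(s): ",
         paste(unique(features[duplicated(features)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric or missing value in matrix", call. = FALSE)
  if (any(vals < 0)) stop("negative value in matrix", call. = FALSE)
  rownames(vals) <- features
  design <- normalize_design(design, colnames(vals))
  out <- new_omics_table(vals, design, layer)
  if (length(out$all_zero) > 0) {
    message(length(out$all_zero), " all-zero feature(s) flagged in ", layer,
            " matrix")
  }
  out
}

#' Write an omics table as TSV
#' @param omics An `omics_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(omics, path) {
  tb <- tibble::as_tibble(omics$values, rownames = "feature")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read an antigen panel table
#'
#' @param path TSV with columns `id` (accession or gene symbol), `label`,
#'   `subset` (`breast_specific` or `cancer_associated`).
#' @return A tibble with unique ids.
#' @export
read_antigen_panel <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  stopifnot(all(c("id", "label", "subset") %in% names(tb)))
  if (anyDuplicated(tb$id)) stop("duplicate antigen panel id", call. = FALSE)
  bad <- setdiff(unique(tb$subset), c("breast_specific", "cancer_associated"))
  if (length(bad) > 0) {
    stop("unknown antigen subset: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(tb) == 0) warning("empty antigen panel", call. = FALSE)
  tb
}

#' Read a protein half-life table
#'
#' @param path TSV with columns `accession` and `half_life_hours`.
#' @return A tibble with positive half-lives.
#' @export
read_half_life <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  stopifnot(all(c("accession", "half_life_hours") %in% names(tb)))
  if (any(tb$half_life_hours <= 0)) stop("non-positive half-life", call. = FALSE)
  tb
}
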