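#' Build a position-specific scoring matrix model for one allele and length
#'
#' The log-odds matrix is
#' `log2(((count[p, a] + pseudocount * bg[a]) / (n + pseudocount)) / bg[a])`
#' per position `p` and residue `a`. The model carries a calibration sample:
#' the sorted scores of `n_background` random peptides drawn from the
#' background frequencies, against which [percent_rank()] is computed.
#'
#' @param allele Allele name (e.g. `"B*40:02"`).
#' @param training_peptides At least 20 peptides of one common length.
#' @param background_freqs Residue background (default uniform).
#' @param n_background Size of the calibration sample.
#' @param pseudocount Pseudocount weight (default 1).
#' @param seed Seed for the calibration draw.
#' @return A `motif_model`: list with `allele`, `length`, `log_odds`
#'   (length x 20 matrix), `background_scores` (sorted), `background_freqs`,
#'   `pseudocount`.
#' @export
build_motif_model <- function(allele, training_peptides,
                              background_freqs = NULL, n_background = 5000,
                              pseudocount = 1, seed = 1) {
  if (length(training_peptides) < 20) {
    stop("need at least 20 training peptides", call. = FALSE)
  }
  if (length(unique(nchar(training_peptides))) != 1) {
    stop("training peptides have mixed lengths", call. = FALSE)
  }
  bg <- aa_background(background_freqs)
  idx <- peptide_index_matrix(training_peptides)
  L <- ncol(idx)
  n <- nrow(idx)
  counts <- vapply(seq_len(L), function(j) tabulate(idx[, j], 20), numeric(20))
  counts <- t(counts)                       # L x 20
  colnames(counts) <- AA20
  log_odds <- log2(sweep(counts, 2, pseudocount * bg, "+") / (n + pseudocount))
  log_odds <- sweep(log_odds, 2, log2(bg), "-")
  model <- structure(
    list(allele = allele, length = L, log_odds = log_odds,
         background_scores = numeric(0), background_freqs = bg,
         pseudocount = pseudocount),
    class = "motif_model"
  )
  set.seed(seed)
  bg_pep <- random_peptides(n_background, L, bg)
  model$background_scores <- sort(score_peptides(model, bg_pep))
  model
}

random_peptides <- function(n, length, bg) {
  m <- matrix(sample(AA20, n * length, replace = TRUE, prob = bg),
              nrow = n, ncol = length)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Score peptides against a motif model
#'
#' Sum of per-position log-odds. All peptides must match the model length.
#'
#' @param model A `motif_model`.
#' @param peptides Character vector of peptides.
#' @return Numeric score vector.
#' @export
score_peptides <- function(model, peptides) {
  if (length(peptides) == 0) return(numeric(0))
  if (any(nchar(peptides) != model$length)) {
    stop("peptide length does not match model length ", model$length,
         call. = FALSE)
  }
  idx <- peptide_index_matrix(peptides)
  sc <- numeric(nrow(idx))
  for (j in seq_len(model$length)) {
    sc <- sc + model$log_odds[j, idx[, j]]
  }
  sc
}

#' Percentile rank of peptides under a motif model
#'
#' `100 * (1 + k) / (1 + N)` where `k` is the number of the model's `N`
#' calibration scores strictly greater than the peptide's score. Lower is a
#' stronger predicted binder; the value is a monotone decreasing transform of
#' the score, and for background-distributed peptides it is uniform on
#' (0, 100].
#'
#' @param model A `motif_model`.
#' @param peptides Character vector of peptides (model length).
#' @return Numeric vector of percentile ranks in (0, 100].
#' @export
percent_rank <- function(model, peptides) {
  if (length(model$background_scores) == 0) {
    stop("model has no calibration sample", call. = FALSE)
  }
  sc <- score_peptides(model, peptides)
  n_bg <- length(model$background_scores)
  greater <- n_bg - findInterval(sc, model$background_scores)
  100 * (1 + greater) / (1 + n_bg)
}

#' Train anchor-derived motif models for the typed alleles
#'
#' Builds a self-contained rank source for [assign_binders()]: for each
#' allele and each class I length, training peptides are simulated from the
#' background with the P2 and C-terminal anchors drawn from the allele's
#' preferred residue sets, and a [build_motif_model()] PSSM is fitted.
#'
#' @param alleles Allele anchor specs (see [default_allele_specs()]).
#' @param lengths Peptide lengths to model (default 8:12).
#' @param n_train Training peptides per model.
#' @param background_freqs Residue background (default uniform).
#' @param n_background Calibration sample size per model.
#' @param pseudocount Pseudocount weight.
#' @param seed Base seed; each model derives its own.
#' @return Nested list: `models[[allele]][[as.character(length)]]`.
#' @export
anchor_motif_models <- function(alleles, lengths = 8:12, n_train = 200,
                                background_freqs = NULL, n_background = 5000,
                                pseudocount = 1, seed = 1) {
  bg <- aa_background(background_freqs)
  out <- list()
  k <- 0L
  for (a in alleles) {
    per_len <- list()
    for (L in lengths) {
      k <- k + 1L
      set.seed(seed + 13L * k)
      pep <- random_peptides(n_train, L, bg)
      substr(pep, 2, 2) <- sample(rep_len(a$p2, 2), n_train, replace = TRUE)
      substr(pep, L, L) <- sample(rep_len(a$pomega, 2), n_train, replace = TRUE)
      per_len[[as.character(L)]] <- build_motif_model(
        a$name, pep, background_freqs = background_freqs,
        n_background = n_background, pseudocount = pseudocount,
        seed = seed + 13L * k + 7L
      )
    }
    out[[a$name]] <- per_len
  }
  out
}

#' Read external binding predictions
#'
#' Bridge to an external predictor: a TSV with columns `peptide`, `allele`,
#' `percent_rank`. Fed identical rank tables, the external route and the
#' built-in scorer produce identical binder calls.
#'
#' @param path TSV path.
#' @return Tibble `peptide`, `allele`, `percent_rank`.
#' @export
read_external_predictions <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  stopifnot(all(c("peptide", "allele", "percent_rank") %in% names(tb)))
  if (any(tb$percent_rank <= 0 | tb$percent_rank > 100)) {
    stop("percent_rank must lie in (0, 100]", call. = FALSE)
  }
  tb
}

#' Assign each class I peptide a best allele and binder status
#'
#' For every distinct 8-12-mer, the percentile rank against each typed
#' allele is computed (from built-in motif models or an external prediction
#' table) and the best (lowest-rank) allele chosen, ties broken by allele
#' name order. A peptide is a binder when its best rank is at or below
#' `rank_cutoff` (default 2). Non-binders are retained with
#' `is_binder = FALSE`; peptides outside 8-12 residues are excluded and
#' counted in attribute `n_excluded`.
#'
#' @param peptides Character vector of peptide sequences (distinct sequences
#'   are assessed once).
#' @param rank_source Either nested models from [anchor_motif_models()] or an
#'   external prediction tibble from [read_external_predictions()].
#' @param rank_cutoff Binder threshold on percentile rank (default 2).
#' @return Tibble `sequence`, `best_allele`, `percent_rank`, `is_binder`,
#'   `locus`, with attributes `n_excluded` and `locus_fractions`.
#' @export
assign_binders <- function(peptides, rank_source, rank_cutoff = 2) {
  peptides <- unique(peptides)
  len <- nchar(peptides)
  keep <- len >= 8 & len <= 12
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warning(n_excluded, " peptide(s) outside 8-12 residues excluded",
            call. = FALSE)
  }
  peptides <- peptides[keep]
  len <- len[keep]
  if (length(peptides) == 0) stop("no 8-12-mer peptides to assign", call. = FALSE)

  external <- is.data.frame(rank_source)
  allele_names <- if (external) sort(unique(rank_source$allele)) else
    sort(names(rank_source))
  rank_mat <- matrix(NA_real_, nrow = length(peptides),
                     ncol = length(allele_names),
                     dimnames = list(NULL, allele_names))
  if (external) {
    for (al in allele_names) {
      sub <- rank_source[rank_source$allele == al, ]
      rank_mat[, al] <- sub$percent_rank[match(peptides, sub$peptide)]
    }
    if (anyNA(rank_mat)) {
      stop("external predictions missing for some peptide/allele pairs",
           call. = FALSE)
    }
  } else {
    for (al in allele_names) {
      for (L in unique(len)) {
        model <- rank_source[[al]][[as.character(L)]]
        if (is.null(model)) {
          stop("no rank source for allele ", al, " at length ", L,
               call. = FALSE)
        }
        sel <- len == L
        rank_mat[sel, al] <- percent_rank(model, peptides[sel])
      }
    }
  }
  best_idx <- max.col(-rank_mat, ties.method = "first")
  best_allele <- allele_names[best_idx]
  best_rank <- rank_mat[cbind(seq_along(best_idx), best_idx)]
  out <- tibble::tibble(
    sequence = peptides,
    best_allele = best_allele,
    percent_rank = best_rank,
    is_binder = best_rank <= rank_cutoff,
    locus = sub("\\*.*$", "", best_allele)
  )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "locus_fractions") <- out %>%
    count(.data$locus) %>%
    mutate(fraction = .data$n / sum(.data$n))
  out
}

#' Export a motif model as a position x residue probability table
#'
#' @param model A `motif_model`.
#' @return Tibble `position`, `residue`, `probability` (render-ready for a
#'   sequence logo).
#' @export
motif_probabilities <- function(model) {
  bg <- model$background_freqs
  prob <- sweep(2^model$log_odds, 2, bg, "*")
  prob <- prob / rowSums(prob)
  tibble::tibble(
    position = rep(seq_len(model$length), times = 20),
    residue = rep(AA20, each = model$length),
    probability = as.vector(prob)
  ) %>% arrange(.data$position, .data$residue)
}
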