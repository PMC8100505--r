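#' Replicate-aware presence calling
#'
#' Collapses per-replicate peptide records to one call per distinct
#' (sequence, class): in how many replicates of each condition the sequence
#' was identified, and whether it is `common` (present in at least
#' `min_replicates` replicates of both conditions), `unique_untreated`, or
#' `unique_treated`. The default presence threshold is detection in at least
#' one replicate; `min_replicates = 2` gives the stricter mode.
#'
#' @param peptides Peptide record table (both conditions).
#' @param n_replicates Number of replicates per condition.
#' @param min_replicates Presence threshold (default 1).
#' @return A tibble `sequence`, `hla_class`, `n_reps_untreated`,
#'   `n_reps_treated`, `category`. Sequences below the threshold in both
#'   conditions are dropped; their number is in attribute
#'   `n_below_threshold`.
#' @export
call_presence <- function(peptides, n_replicates, min_replicates = 1) {
  stopifnot(n_replicates >= 1, min_replicates >= 1,
            min_replicates <= n_replicates)
  check_condition(unique(peptides$condition))
  if (nrow(peptides) == 0) {
    out <- tibble::tibble(sequence = character(), hla_class = character(),
                          n_reps_untreated = integer(),
                          n_reps_treated = integer(), category = character())
    attr(out, "n_below_threshold") <- 0L
    return(out)
  }
  if (any(peptides$replicate > n_replicates)) {
    stop("record with replicate > n_replicates", call. = FALSE)
  }
  calls <- peptides %>%
    distinct(.data$sequence, .data$hla_class, .data$condition, .data$replicate) %>%
    group_by(.data$sequence, .data$hla_class) %>%
    summarise(
      n_reps_untreated = sum(.data$condition == "untreated"),
      n_reps_treated = sum(.data$condition == "treated"),
      .groups = "drop"
    ) %>%
    arrange(.data$hla_class, .data$sequence)
  in_u <- calls$n_reps_untreated >= min_replicates
  in_t <- calls$n_reps_treated >= min_replicates
  calls$category <- dplyr::case_when(
    in_u & in_t ~ "common",
    in_u ~ "unique_untreated",
    in_t ~ "unique_treated",
    TRUE ~ NA_character_
  )
  dropped <- sum(is.na(calls$category))
  calls <- calls[!is.na(calls$category), ]
  attr(calls, "n_below_threshold") <- dropped
  calls
}

#' Summarize condition overlap of a peptide repertoire
#'
#' Counts the three presence categories and expresses them as percentages of
#' the union of distinct sequences (the three percentages sum to 100). The
#' shared count is additionally expressed relative to each condition's own
#' repertoire (`pct_common_of_untreated`, `pct_common_of_treated`), since
#' overlap figures quoted against different denominators differ; both
#' conventions are reported and labeled rather than conflated.
#'
#' @param calls Presence calls from [call_presence()].
#' @return One-row tibble of counts and percentages.
#' @export
summarize_overlap <- function(calls) {
  if (nrow(calls) == 0) stop("no presence calls to summarize", call. = FALSE)
  n_common <- sum(calls$category == "common")
  n_uu <- sum(calls$category == "unique_untreated")
  n_ut <- sum(calls$category == "unique_treated")
  union <- n_common + n_uu + n_ut
  tibble::tibble(
    n_unique_untreated = n_uu,
    n_unique_treated = n_ut,
    n_common = n_common,
    n_union = union,
    pct_unique_untreated = 100 * n_uu / union,
    pct_unique_treated = 100 * n_ut / union,
    pct_common = 100 * n_common / union,
    pct_common_of_untreated = 100 * n_common / (n_common + n_uu),
    pct_common_of_treated = 100 * n_common / (n_common + n_ut)
  )
}
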