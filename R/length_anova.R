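class_length_range <- function(hla_class) {
  if (hla_class == "I") 8:12 else 13:30
}

#' Peptide length distributions
#'
#' Tabulates peptide lengths by condition or by overlap category. Class I
#' summaries are restricted to 8-12-mers and class II to 13-mers and longer
#' (dropped counts are reported in attribute `n_out_of_range`). Group
#' proportions are over distinct sequences and sum to 1 within each group;
#' for `by = "condition"` a per-replicate proportion table is also returned
#' for replicate-level statistics.
#'
#' @param peptides Peptide record table.
#' @param hla_class `"I"` or `"II"`.
#' @param by `"condition"` or `"category"`.
#' @param calls Presence calls (required for `by = "category"`).
#' @return A list with `group` (tibble `group`, `length`, `n`, `proportion`)
#'   and, for `by = "condition"`, `replicate` (tibble `group`, `replicate`,
#'   `length`, `n`, `proportion`).
#' @export
length_distribution <- function(peptides, hla_class = "I",
                                by = c("condition", "category"),
                                calls = NULL) {
  by <- match.arg(by)
  hla_class <- match.arg(hla_class, c("I", "II"))
  lens <- class_length_range(hla_class)
  pep <- peptides[peptides$hla_class == hla_class, ]
  pep$length <- nchar(pep$sequence)
  n_out <- length(unique(pep$sequence[!pep$length %in% lens]))
  pep <- pep[pep$length %in% lens, ]

  tab_group <- function(df, group) {
    counts <- df %>%
      distinct(.data$sequence, group = .data[[group]]) %>%
      mutate(length = nchar(.data$sequence)) %>%
      count(.data$group, .data$length)
    grid <- tidyr::expand_grid(group = unique(counts$group), length = lens)
    grid %>%
      left_join(counts, by = c("group", "length")) %>%
      mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
      group_by(.data$group) %>%
      mutate(proportion = .data$n / sum(.data$n)) %>%
      ungroup()
  }

  if (by == "condition") {
    group <- tab_group(pep, "condition")
    rep_counts <- pep %>%
      distinct(group = .data$condition, .data$replicate, .data$sequence,
               .data$length) %>%
      count(.data$group, .data$replicate, .data$length)
    grid <- tidyr::expand_grid(
      rep_counts %>% distinct(.data$group, .data$replicate),
      length = lens
    )
    replicate <- grid %>%
      left_join(rep_counts, by = c("group", "replicate", "length")) %>%
      mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
      group_by(.data$group, .data$replicate) %>%
      mutate(proportion = .data$n / sum(.data$n)) %>%
      ungroup()
    out <- list(group = group, replicate = replicate)
  } else {
    if (is.null(calls)) stop("calls required for by = 'category'", call. = FALSE)
    joined <- pep %>%
      distinct(.data$sequence, .data$length) %>%
      dplyr::inner_join(calls[, c("sequence", "category")], by = "sequence") %>%
      rename(group = "category")
    out <- list(group = tab_group(
      joined %>% mutate(condition = .data$group), "condition"))
  }
  attr(out, "n_out_of_range") <- n_out
  out
}

#' Two-way fixed-effects ANOVA with per-level contrasts
#'
#' Computes the standard two-way fixed-effects sums of squares (factors A and
#' B plus interaction) on a replicate-level response --- typically per-replicate
#' length proportions with A = length and B = condition --- followed by
#' per-A-level Welch contrasts between the two B levels, Bonferroni-corrected
#' across A levels. Implemented from the sums-of-squares definitions; it
#' agrees with `stats::aov` on balanced designs.
#'
#' @param data Data frame with the response and factor columns.
#' @param value,factor_a,factor_b Column names (default `proportion`,
#'   `length`, `condition`).
#' @param alpha Significance level for flagging contrasts (default 0.05,
#'   applied to Bonferroni-corrected p-values).
#' @return List with `anova` (term, df, sumsq, meansq, statistic, p_value)
#'   and `contrasts` (per-A-level Welch t, Bonferroni-corrected).
#' @export
two_way_anova <- function(data, value = "proportion", factor_a = "length",
                          factor_b = "condition", alpha = 0.05) {
  y <- data[[value]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  stopifnot(length(y) == length(a), length(a) == length(b))
  cell_n <- table(a, b)
  if (any(cell_n < 2)) stop("insufficient replication", call. = FALSE)

  grand <- mean(y)
  m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  n_a <- tapply(y, a, length)
  n_b <- tapply(y, b, length)

  ss_a <- sum(n_a * (m_a - grand)^2)
  ss_b <- sum(n_b * (m_b - grand)^2)
  ss_ab <- sum(cell_n * (sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_e <- sum((y - m_ab[cbind(a, b)])^2)

  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(a) * nlevels(b)
  ms <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab)
  mse <- ss_e / df_e
  f <- if (mse > 0) ms / mse else ifelse(ms > 0, Inf, 0)
  p <- ifelse(is.infinite(f), 0, pf(f, c(df_a, df_b, df_ab), df_e,
                                    lower.tail = FALSE))
  anova_tb <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residuals"),
    df = c(df_a, df_b, df_ab, df_e),
    sumsq = c(ss_a, ss_b, ss_ab, ss_e),
    meansq = c(ms, mse),
    statistic = c(f, NA),
    p_value = c(p, NA)
  )

  lev_b <- levels(b)
  if (length(lev_b) != 2) {
    stop("per-level contrasts require exactly two levels of ", factor_b,
         call. = FALSE)
  }
  contrasts <- lapply(levels(a), function(la) {
    y1 <- y[a == la & b == lev_b[1]]
    y2 <- y[a == la & b == lev_b[2]]
    wt <- welch_t(mean(y2), mean(y1), stats::var(y2), stats::var(y1),
                  length(y2), length(y1))
    tibble::tibble(level = la, estimate = mean(y2) - mean(y1),
                   statistic = wt$t, df = wt$df, p_value = wt$p)
  }) %>% bind_rows()
  contrasts$p_bonferroni <- pmin(1, contrasts$p_value * nlevels(a))
  contrasts$significant <- contrasts$p_bonferroni < alpha
  list(anova = anova_tb, contrasts = contrasts)
}

# Welch two-sample t from summary statistics; identical values give p = 1.
welch_t <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  if (is.na(se2) || se2 == 0) {
    return(list(t = 0, df = NA_real_, p = if (isTRUE(d == 0)) 1 else 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
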