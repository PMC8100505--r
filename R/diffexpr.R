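# Vectorized pooled-variance two-sample t-test across the rows of two
# matrices. At the study's 3 vs 3 replicate design the Welch approximation
# is measurably conservative (empirical size ~3.5% at nominal 5%), so the
# equal-variance Student t (exact under the generator's equal-variance
# log-normal noise) is used instead; see the methods vignette.
row_ttest <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t), n1 + n2 - 2)
  # zero variance in both groups: p = 1 when means agree, -> 0 otherwise
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(estimate = unname(m1 - m2), p = unname(p))
}

#' Simple differential expression between conditions
#'
#' A fully specified, dependency-light procedure: transcript counts are
#' transformed to `log2` counts-per-million with a +0.5 offset
#' (`log2((count + 0.5) / library_size * 1e6)`), protein intensities to
#' `log2(1 + intensity)`; each feature is tested with a pooled-variance
#' two-sample t-test between conditions (exact at the small balanced
#' replicate designs this pipeline targets, where the Welch approximation
#' is measurably conservative) and p-values are Benjamini-Hochberg adjusted
#' across features
#' within the layer. `log2fc` is the treated-minus-untreated mean on the log
#' scale. This deliberately does not reproduce a negative-binomial GLM
#' analysis; it is a defined substitute with known type-I behaviour on
#' log-normal data.
#'
#' @param omics An `omics_table` (see [read_omics_matrix()]).
#' @param fdr_threshold Significance threshold on the adjusted p (default
#'   0.05).
#' @return Tibble `feature`, `layer`, `log2fc`, `p_value`, `fdr`,
#'   `significant`.
#' @export
simple_de <- function(omics, fdr_threshold = 0.05) {
  stopifnot(inherits(omics, "omics_table"))
  design <- omics$design
  for (cond in CONDITIONS) {
    if (sum(design$condition == cond) < 2) {
      stop("condition '", cond, "' has fewer than 2 replicates", call. = FALSE)
    }
  }
  vals <- omics$values
  if (omics$layer == "transcript") {
    lib <- colSums(vals)
    if (any(lib == 0)) stop("sample with zero library size", call. = FALSE)
    y <- log2(sweep(vals + 0.5, 2, lib, "/") * 1e6)
  } else {
    y <- log2(1 + vals)
  }
  yt <- y[, design$condition == "treated", drop = FALSE]
  yu <- y[, design$condition == "untreated", drop = FALSE]
  wt <- row_ttest(yt, yu)
  fdr <- p.adjust(wt$p, method = "BH")
  tibble::tibble(
    feature = rownames(vals),
    layer = omics$layer,
    log2fc = wt$estimate,
    p_value = wt$p,
    fdr = fdr,
    significant = fdr < fdr_threshold
  )
}

#' Correlate fold changes between two differential-expression results
#'
#' Pearson correlation of `log2fc` over the joined features. Whether such a
#' correlation should be computed over all joined features or only the
#' significant ones is a reporting choice; both are supported via
#' `only_significant` and the pipeline labels each.
#'
#' @param de_a,de_b Tibbles with `feature` and `log2fc` columns (e.g. from
#'   [simple_de()]).
#' @param feature_map Optional two-column data frame mapping `de_a` features
#'   (column 1) to `de_b` features (column 2).
#' @param only_significant Restrict to features significant in both inputs.
#' @return One-row tibble `r`, `p_value`, `n_joined`, `only_significant`.
#' @export
omics_correlation <- function(de_a, de_b, feature_map = NULL,
                              only_significant = FALSE) {
  a <- de_a
  if (only_significant) {
    a <- a[a$significant, ]
    de_b <- de_b[de_b$significant, ]
  }
  if (!is.null(feature_map)) {
    key <- setNames(as.character(feature_map[[2]]),
                    as.character(feature_map[[1]]))
    a$feature <- unname(key[a$feature])
  }
  joined <- dplyr::inner_join(
    a[!is.na(a$feature), c("feature", "log2fc")],
    de_b[, c("feature", "log2fc")],
    by = "feature", suffix = c("_a", "_b")
  )
  if (nrow(joined) < 3) stop("fewer than 3 joined features", call. = FALSE)
  ct <- cor.test(joined$log2fc_a, joined$log2fc_b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_joined = nrow(joined), only_significant = only_significant)
}
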