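#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random amino-acid sequences from the background residue
#' frequency (uniform unless `config$background_freqs` is set), with lengths
#' uniform over `protein_length_range`. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A proteome tibble as returned by [read_fasta_proteome()].
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_proteins < 1) stop("empty proteome", call. = FALSE)
  set.seed(config$seed)
  bg <- aa_background(config$background_freqs)
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]),
                 config$n_proteins, replace = TRUE)
  chars <- sample(AA20, sum(lens), replace = TRUE, prob = bg)
  idx <- rep.int(seq_along(lens), lens)
  seqs <- vapply(split(chars, idx), paste, character(1), collapse = "")
  tibble::tibble(
    accession = sprintf("SYNP%05d", seq_along(lens)),
    sequence = unname(seqs),
    description = "synthetic protein",
    gene_symbol = sprintf("GENE%05d", seq_along(lens)),
    nonstandard = FALSE
  )
}

# Distinct-sequence category sizes implied by the config. With per-replicate
# detection probability p, a per-replicate mean of n peptides needs a
# condition repertoire of n/p distinct sequences. Writing f for the shared
# fraction of the union U and m for the count multiplier:
#   N_untreated = U (1 + f) / (1 + m),  common = f U,
#   unique_untreated = U (1 - m f) / (1 + m).
peptidome_category_sizes <- function(config) {
  f <- config$shared_fraction
  m <- config$count_multiplier
  n_u <- max(1, round(config$n_peptides_untreated / config$detect_prob))
  u <- round(n_u * (1 + m) / (1 + f))
  n_common <- round(f * u)
  if (1 - m * f < 0) {
    warning("shared_fraction * count_multiplier > 1: no untreated-unique ",
            "peptides can satisfy both targets; setting unique_untreated = 0",
            call. = FALSE)
  }
  n_uu <- max(0, round(u * (1 - m * f) / (1 + m)))
  n_ut <- max(0, u - n_common - n_uu)
  list(union = n_common + n_uu + n_ut, common = n_common,
       unique_untreated = n_uu, unique_treated = n_ut)
}

# Place K peptides into non-overlapping windows of the proteome. Proteins are
# drawn proportional to length; overflowing peptides are re-drawn among
# proteins with spare capacity. Returns protein index and 1-based start.
assign_windows <- function(pep_len, prot_len) {
  k <- length(pep_len)
  n <- length(prot_len)
  if (max(pep_len) > max(prot_len)) {
    stop("requested peptide length exceeds every protein length", call. = FALSE)
  }
  if (sum(pep_len) > 0.8 * sum(prot_len)) {
    stop("proteome capacity insufficient for requested peptidome", call. = FALSE)
  }
  prot <- sample.int(n, k, replace = TRUE, prob = prot_len)
  for (iter in 1:50) {
    cum <- stats::ave(pep_len, prot, FUN = cumsum)
    ok <- cum <= prot_len[prot]
    if (all(ok)) break
    placed <- tapply(pep_len[ok], prot[ok], sum)
    rem <- prot_len
    rem[as.integer(names(placed))] <- rem[as.integer(names(placed))] - placed
    w <- pmax(rem - max(pep_len), 0)
    if (sum(w) == 0) stop("proteome capacity insufficient", call. = FALSE)
    prot[!ok] <- sample.int(n, sum(!ok), replace = TRUE, prob = w)
  }
  if (!all(ok)) stop("proteome capacity insufficient", call. = FALSE)
  list(protein = prot, start = cum - pep_len + 1)
}

sample_lengths <- function(n, law) {
  sample(as.integer(names(law)), n, replace = TRUE, prob = law)
}

# HLA-B probability for treatment-induced peptides that makes the overall
# treated B share hit its target given that shared peptides keep their
# untreated-regime motif.
unique_treated_b_share <- function(config, sizes) {
  b_u <- config$hlab_share[["untreated"]]
  b_t <- config$hlab_share[["treated"]]
  if (sizes$unique_treated == 0) return(b_u)
  n_treated <- sizes$common + sizes$unique_treated
  bb <- (b_t * n_treated - b_u * sizes$common) / sizes$unique_treated
  if (bb < 0 || bb > 1) {
    warning("treated HLA-B share target unattainable given shared fraction; ",
            "clamping", call. = FALSE)
    bb <- min(1, max(0, bb))
  }
  bb
}

sample_class_i_alleles <- function(n, b_prob, alleles) {
  locus_of <- vapply(alleles, `[[`, character(1), "locus")
  # A:C split of the non-B mass is a documented placeholder (no per-allele
  # shares are reported for untreated cells).
  p_locus <- c(A = 0.6 * (1 - b_prob), B = b_prob, C = 0.4 * (1 - b_prob))
  locus <- sample(names(p_locus), n, replace = TRUE, prob = p_locus)
  vapply(locus, function(l) {
    cand <- names(alleles)[locus_of == l]
    if (length(cand) == 1) cand else sample(cand, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic immunopeptidome with ground truth
#'
#' Builds the distinct-sequence repertoires of both conditions (sizes set by
#' `n_peptides_untreated`, `count_multiplier`, `shared_fraction` and the
#' per-replicate detection probability), assigns each peptide a
#' non-overlapping window of a source protein, a class I allele (with the
#' HLA-B share rising under treatment) and a length from the class length
#' law (treatment-induced peptides get the 10/11-mer boost), rewrites the P2
#' and C-terminal anchor residues to the allele's preferred set --- writing
#' the anchor residues back into the source protein so that every peptide is
#' an exact substring of the returned proteome --- and then emits
#' per-replicate observation tables with detection noise and a treated
#' intensity shift. Class II peptides (13-17-mers) are emitted only under
#' treatment by default.
#'
#' @param config A [synthetic_config()].
#' @param proteome A proteome tibble from [generate_proteome()].
#' @return A list:
#'   * `peptides`: per-replicate record table (see [read_peptide_table()]),
#'   * `truth`: one row per distinct sequence with `category`
#'     (`common`/`unique_untreated`/`unique_treated`), true `allele`, `locus`,
#'     source `accession` and 0-based half-open `start`/`end`,
#'   * `proteome`: the anchor-patched proteome (write this one to FASTA).
#' @export
generate_peptidome <- function(config, proteome) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  set.seed(config$seed + 1L)

  sizes <- peptidome_category_sizes(config)
  n_ii <- if (config$n_peptides_class_ii > 0) {
    max(1, round(config$n_peptides_class_ii / config$detect_prob))
  } else 0L

  law_boost <- config$length_law_i
  law_boost[["9"]] <- law_boost[["9"]] - config$long_mer_boost
  law_boost[["10"]] <- law_boost[["10"]] + config$long_mer_boost / 2
  law_boost[["11"]] <- law_boost[["11"]] + config$long_mer_boost / 2

  category <- c(rep("common", sizes$common),
                rep("unique_untreated", sizes$unique_untreated),
                rep("unique_treated", sizes$unique_treated),
                rep(if (config$class_ii_on_treated_only) "unique_treated"
                    else "common", n_ii))
  hla_class <- c(rep("I", sizes$union), rep("II", n_ii))
  pep_len <- c(
    sample_lengths(sizes$common + sizes$unique_untreated, config$length_law_i),
    sample_lengths(sizes$unique_treated, law_boost),
    sample_lengths(n_ii, config$length_law_ii)
  )

  win <- assign_windows(pep_len, nchar(proteome$sequence))

  is_i <- hla_class == "I"
  b_ut <- unique_treated_b_share(config, sizes)
  allele <- character(length(pep_len))
  base_cat <- is_i & category != "unique_treated"
  indu_cat <- is_i & category == "unique_treated"
  allele[base_cat] <- sample_class_i_alleles(
    sum(base_cat), config$hlab_share[["untreated"]], config$alleles)
  allele[indu_cat] <- sample_class_i_alleles(
    sum(indu_cat), b_ut, config$alleles)
  allele[!is_i] <- sample(config$class_ii_alleles, sum(!is_i), replace = TRUE)

  # Anchor rewriting for class I: pick P2 / C-terminal residues per allele and
  # patch them into the source protein, then read the peptide back out.
  patch_pos <- integer(0); patch_res <- character(0); patch_prot <- integer(0)
  if (any(is_i)) {
    ii <- which(is_i)
    p2 <- vapply(allele[ii], function(a) {
      s <- config$alleles[[a]]$p2
      if (length(s) == 1) s else sample(s, 1)
    }, character(1), USE.NAMES = FALSE)
    pom <- vapply(allele[ii], function(a) {
      s <- config$alleles[[a]]$pomega
      if (length(s) == 1) s else sample(s, 1)
    }, character(1), USE.NAMES = FALSE)
    patch_prot <- rep(win$protein[ii], 2)
    patch_pos <- c(win$start[ii] + 1L, win$start[ii] + pep_len[ii] - 1L)
    patch_res <- c(p2, pom)
  }
  seqs <- proteome$sequence
  if (length(patch_pos) > 0) {
    for (j in unique(patch_prot)) {
      sel <- patch_prot == j
      ch <- strsplit(seqs[[j]], "", fixed = TRUE)[[1]]
      ch[patch_pos[sel]] <- patch_res[sel]
      seqs[[j]] <- paste(ch, collapse = "")
    }
  }
  proteome$sequence <- seqs

  sequence <- substr(seqs[win$protein], win$start, win$start + pep_len - 1L)

  truth <- tibble::tibble(
    sequence = sequence,
    hla_class = hla_class,
    category = category,
    allele = allele,
    locus = sub("\\*.*$", "", allele),
    accession = proteome$accession[win$protein],
    start = win$start - 1L,                  # 0-based half-open
    end = win$start - 1L + pep_len,
    length = pep_len
  )
  truth <- truth[!duplicated(paste(truth$sequence, truth$hla_class)), ]

  # Per-sequence base abundance; shared sequences keep one base value so the
  # treated shift is the only systematic intensity difference.
  truth$base_log2_intensity <- rnorm(nrow(truth), config$intensity_log2_mean,
                                     config$intensity_log2_sd)

  emit <- function(rows, condition) {
    if (nrow(rows) == 0) return(empty_peptide_table())
    shift <- if (condition == "treated") config$intensity_log2_shift else 0
    out <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      hit <- runif(nrow(rows)) < config$detect_prob
      sub <- rows[hit, ]
      out[[r]] <- tibble::tibble(
        sequence = sub$sequence,
        hla_class = sub$hla_class,
        condition = condition,
        replicate = r,
        intensity = 2^(sub$base_log2_intensity + shift +
                         rnorm(nrow(sub), 0, config$intensity_rep_log2_sd)),
        source_accessions = as.list(sub$accession)
      )
    }
    bind_rows(out)
  }
  in_untreated <- truth$category %in% c("common", "unique_untreated")
  in_treated <- truth$category %in% c("common", "unique_treated")
  peptides <- bind_rows(
    emit(truth[in_untreated, ], "untreated"),
    emit(truth[in_treated, ], "treated")
  )
  truth$base_log2_intensity <- NULL
  list(peptides = peptides, truth = truth, proteome = proteome)
}

#' Generate matched transcript/protein matrices and a half-life table
#'
#' For every protein, the realized peptide-count log2 fold change is computed
#' from the truth table (`log2((n_treated + 1)/(n_untreated + 1))` over
#' distinct class I sequences) and standardized to `z_pep`. The true omics
#' log2 fold change of each layer is `s * (r * z_pep + sqrt(1 - r^2) * z)`,
#' where `r` is `omics_peptidome_r[layer]`, `s` is `de_log2fc_sd`, and `z` an
#' independent standard-normal `z`; a `1 - de_fraction` random subset is
#' masked to exactly zero. Replicate measurements are drawn around
#' `2^(baseline + log2fc * treated)` with log2 noise `noise_sd`; transcript
#' values are rounded to counts. Half-lives are log-normal and independent of
#' peptide counts.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth table from [generate_peptidome()].
#' @param proteome Optional proteome tibble; when given, every protein is a
#'   feature (otherwise only proteins appearing in the truth table).
#' @return A list with `transcript` and `protein` (`omics_table`s keyed by
#'   protein accession), `half_life` (tibble), and `truth` (per-accession true
#'   fold changes and DE masks).
#' @export
generate_omics <- function(config, truth, proteome = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  acc <- if (is.null(proteome)) sort(unique(truth$accession)) else
    proteome$accession
  t1 <- truth[truth$hla_class == "I", ]
  n_u <- table(factor(t1$accession[t1$category != "unique_treated"], levels = acc))
  n_t <- table(factor(t1$accession[t1$category != "unique_untreated"], levels = acc))
  pep_log2fc <- log2((as.numeric(n_t) + 1) / (as.numeric(n_u) + 1))
  z_pep <- if (sd(pep_log2fc) > 0) as.numeric(scale(pep_log2fc)) else
    rep(0, length(pep_log2fc))

  n <- length(acc)
  # Joint standardized draw: each layer couples to the peptidome at its own
  # r, and the transcript/protein residuals share a coupling chosen so the
  # overall transcript-protein correlation hits rna_protein_r.
  r_t <- config$omics_peptidome_r[["transcript"]]
  r_p <- config$omics_peptidome_r[["protein"]]
  e_t <- rnorm(n)
  e_p <- rnorm(n)
  resid_scale <- sqrt(1 - r_t^2) * sqrt(1 - r_p^2)
  rho <- if (resid_scale > 0) {
    (config$rna_protein_r - r_t * r_p) / resid_scale
  } else 0
  rho <- min(1, max(-1, rho))
  z_layer <- list(
    transcript = r_t * z_pep + sqrt(1 - r_t^2) * e_t,
    protein = r_p * z_pep + sqrt(1 - r_p^2) *
      (rho * e_t + sqrt(1 - rho^2) * e_p)
  )
  draw_layer <- function(layer) {
    de <- runif(n) < config$de_fraction
    lfc <- config$de_log2fc_sd * z_layer[[layer]]
    lfc[!de] <- 0
    base <- rnorm(n, config$base_log2_expression[[layer]],
                  config$expression_log2_sd[[layer]])
    reps <- config$n_replicates
    mk <- function(shifted) {
      m <- matrix(2^(base + shifted + rnorm(n * reps, 0, config$noise_sd)),
                  nrow = n, ncol = reps)
      if (layer == "transcript") m <- round(m)
      m
    }
    vals <- cbind(mk(0), mk(lfc))
    rownames(vals) <- acc
    colnames(vals) <- c(paste0("u", seq_len(reps)), paste0("t", seq_len(reps)))
    design <- tibble::tibble(
      sample = colnames(vals),
      condition = rep(CONDITIONS, each = reps),
      replicate = rep(seq_len(reps), 2)
    )
    list(table = new_omics_table(vals, design, layer), log2fc = lfc, de = de)
  }
  tr <- draw_layer("transcript")
  pr <- draw_layer("protein")
  half_life <- tibble::tibble(
    accession = acc,
    half_life_hours = rlnorm(n, config$half_life_log_mean,
                             config$half_life_log_sd)
  )
  list(
    transcript = tr$table,
    protein = pr$table,
    half_life = half_life,
    truth = tibble::tibble(
      accession = acc,
      n_untreated = as.integer(n_u),
      n_treated = as.integer(n_t),
      pep_log2fc = pep_log2fc,
      rna_log2fc = tr$log2fc,
      prot_log2fc = pr$log2fc,
      rna_de = tr$de,
      prot_de = pr$de
    )
  )
}
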