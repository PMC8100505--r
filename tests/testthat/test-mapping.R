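mini_proteome <- function(seqs) {
  tibble::tibble(
    accession = paste0("P", seq_along(seqs)),
    sequence = seqs,
    description = "x",
    gene_symbol = paste0("G", seq_along(seqs)),
    nonstandard = FALSE
  )
}

test_that("substring mapping records 0-based half-open intervals", {
  db <- mini_proteome(c("ABCDEFG", "QQQCDEQQQ"))
  mp <- map_peptides("CDE", db)
  expect_equal(nrow(mp$mapping), 2)  # multi-mapped: counts toward every hit
  m1 <- mp$mapping[mp$mapping$accession == "P1", ]
  expect_equal(m1$start, 2)
  expect_equal(m1$end, 5)
  expect_equal(substr("ABCDEFG", m1$start + 1, m1$end), "CDE")
  expect_length(mp$unmapped, 0)

  # I/L equivalence on by default, exact when disabled
  db2 <- mini_proteome("AAXLXAA")
  expect_equal(nrow(map_peptides("XIX", db2)$mapping), 1)
  off <- map_peptides("XIX", db2, il_equivalent = FALSE)
  expect_equal(nrow(off$mapping), 0)
  expect_equal(off$unmapped, "XIX")

  # overlapping self-matches are all reported
  rep_db <- mini_proteome("AAAAA")
  expect_equal(nrow(map_peptides("AAA", rep_db)$mapping), 3)
})

test_that("synthetic peptides map back to their truth proteins", {
  sim <- tiny_sim(n_peptides_untreated = 400, n_proteins = 300,
                  protein_length_range = c(150, 250))
  mp <- map_peptides(sim$peptides, sim$proteome)
  expect_length(mp$unmapped, 0)
  hit <- dplyr::inner_join(sim$truth, mp$mapping,
                           by = c("sequence", "accession", "start", "end"))
  expect_gte(nrow(hit) / nrow(sim$truth), 0.999)
})

test_that("coverage equals the brute-force per-residue oracle exactly", {
  # worked example: length 10 covered on [0,5) and [3,8) -> 80%
  db <- mini_proteome("ABCDEFGHIJ")
  pep <- dplyr::bind_rows(pep_row("ABCDEFG", "untreated", 1),
                          pep_row("DEFGHILL", "untreated", 1))
  mapping <- tibble::tibble(
    sequence = c("ABCDE", "DEFGH"), accession = "P1",
    start = c(0L, 3L), end = c(5L, 8L)
  )
  recs <- dplyr::bind_rows(pep_row("ABCDE", "untreated", 1, intensity = 2),
                           pep_row("DEFGH", "untreated", 1, intensity = 3))
  s <- protein_summaries(recs, mapping, db, "untreated", n_replicates = 1)
  expect_equal(s$coverage_pct, 80)
  expect_equal(s$n_peptides, 2)
  expect_equal(s$log2_intensity, log2(1 + 5))

  # randomized oracle equivalence
  set.seed(88)
  for (k in 1:50) {
    plen <- sample(30:80, 1)
    n_iv <- sample(1:8, 1)
    starts <- sample.int(plen - 5, n_iv, replace = TRUE) - 1L
    ends <- pmin(starts + sample(3:10, n_iv, replace = TRUE), plen)
    mapping <- tibble::tibble(sequence = paste0("S", seq_len(n_iv)),
                              accession = "P1", start = starts, end = ends)
    recs <- dplyr::bind_rows(lapply(mapping$sequence, function(s)
      pep_row(s, "untreated", 1)))
    db <- mini_proteome(paste(rep("A", plen), collapse = ""))
    got <- protein_summaries(recs, mapping, db, "untreated", 1)$coverage_pct
    expect_identical(got, coverage_oracle(plen, starts, ends))
  }
})

test_that("intensity summaries average log2 sums over all replicates", {
  db <- mini_proteome("ABCDEFGHIJ")
  mapping <- tibble::tibble(sequence = "ABCDE", accession = "P1",
                            start = 0L, end = 5L)
  recs <- dplyr::bind_rows(
    pep_row("ABCDE", "untreated", 1, intensity = 7),
    pep_row("ABCDE", "untreated", 2, intensity = 15)
  )
  s <- protein_summaries(recs, mapping, db, "untreated", n_replicates = 3)
  expect_equal(s$log2_intensity, (log2(8) + log2(16) + log2(1)) / 3)
})

test_that("peptides-per-protein histogram bins and conserves proteins", {
  mk <- function(counts, condition) tibble::tibble(
    accession = paste0("P", seq_along(counts)), condition = condition,
    n_peptides = counts, coverage_pct = 1, log2_intensity = 0,
    peptide_list = replicate(length(counts), "X", simplify = FALSE)
  )
  h <- peptides_per_protein_histogram(mk(c(1, 1, 2, 7), "untreated"),
                                      mk(c(3, 25), "treated"))
  hu <- h[h$condition == "untreated", ]
  expect_equal(hu$n_proteins[hu$bin == "1"], 2)
  expect_equal(hu$n_proteins[hu$bin == "2"], 1)
  expect_equal(hu$n_proteins[hu$bin == "6-20"], 1)
  expect_equal(sum(hu$n_proteins), 4)
  ht <- h[h$condition == "treated", ]
  expect_equal(ht$n_proteins[ht$bin == "21+"], 1)
  expect_equal(sum(ht$n_proteins), 2)
})

test_that("a count multiplier shifts the treated histogram toward higher bins", {
  sim <- tiny_sim(n_peptides_untreated = 1200, count_multiplier = 2,
                  n_proteins = 300, protein_length_range = c(200, 300),
                  n_peptides_class_ii = 0, seed = 41L)
  mp <- map_peptides(sim$peptides, sim$proteome)
  su <- protein_summaries(sim$peptides, mp$mapping, sim$proteome,
                          "untreated", 3)
  st <- protein_summaries(sim$peptides, mp$mapping, sim$proteome,
                          "treated", 3)
  # stochastic dominance of the treated per-protein count distribution
  qs <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(stats::quantile(st$n_peptides, qs) >=
                    stats::quantile(su$n_peptides, qs)))
  expect_gt(mean(st$n_peptides), mean(su$n_peptides))
})

test_that("source-protein overlap mirrors the sequence-level conventions", {
  mk <- function(acc, condition) tibble::tibble(
    accession = acc, condition = condition, n_peptides = 1,
    coverage_pct = 1, log2_intensity = 0,
    peptide_list = replicate(length(acc), "X", simplify = FALSE)
  )
  so <- source_overlap(mk(c("P1", "P2"), "untreated"),
                       mk(c("P2", "P3"), "treated"))
  expect_equal(c(so$n_unique_untreated, so$n_common, so$n_unique_treated),
               c(1, 1, 1))
  so2 <- source_overlap(mk(c("P1", "P2"), "untreated"),
                        mk(c("P1", "P2"), "treated"))
  expect_equal(c(so2$n_unique_untreated, so2$n_common, so2$n_unique_treated),
               c(0, 2, 0))
})

test_that("antigen cross-reference resolves ids and applies the pseudocount", {
  db <- mini_proteome(c("ABCDEFGHIJ", "KLMNPQRSTV", "WYACDEFGHK"))
  mk <- function(acc, n, condition) tibble::tibble(
    accession = acc, condition = condition, n_peptides = n,
    coverage_pct = 1, log2_intensity = 0,
    peptide_list = lapply(seq_along(acc), function(i)
      paste0(acc[i], "_pep", seq_len(n[i])))
  )
  panel <- tibble::tibble(id = c("P1", "G2", "g3", "NOPE"),
                          label = letters[1:4],
                          subset = c("breast_specific",
                                     rep("cancer_associated", 3)))
  su <- mk(c("P1"), 3, "untreated")
  st <- mk(c("P1", "P2"), c(8, 2), "treated")
  sii <- mk("P3", 4, "treated")
  xr <- antigen_crossref(panel, su, st, sii, db)
  t1 <- xr$table[xr$table$id == "P1", ]
  expect_equal(t1$log2fc_i, log2(9 / 4))
  t3 <- xr$table[xr$table$id == "g3", ]  # case-insensitive symbol resolution
  expect_equal(t3$accession, "P3")
  expect_true(t3$in_hla_ii_treated)
  expect_false(t3$in_hla_i_untreated || t3$in_hla_i_treated)
  expect_equal(xr$unresolved, "NOPE")
  expect_error(antigen_crossref(panel[0, ], su, st, NULL, db), "empty")
})

test_that("panel counts over synthetic truth proteins match the truth table", {
  sim <- tiny_sim(seed = 51L)
  mp <- map_peptides(sim$peptides, sim$proteome)
  su <- protein_summaries(sim$peptides[sim$peptides$hla_class == "I", ],
                          mp$mapping, sim$proteome, "untreated", 3)
  set.seed(52)
  acc <- sample(unique(sim$truth$accession), 10)
  panel <- tibble::tibble(id = acc, label = acc, subset = "cancer_associated")
  xr <- antigen_crossref(panel, su, su, NULL, sim$proteome)
  truth_counts <- vapply(acc, function(a) {
    present <- unique(sim$peptides$sequence[
      sim$peptides$condition == "untreated" &
        sim$peptides$hla_class == "I"])
    sum(sim$truth$accession == a & sim$truth$hla_class == "I" &
          sim$truth$sequence %in% present)
  }, numeric(1))
  expect_equal(xr$table$n_hla_i_untreated[match(acc, xr$table$id)],
               unname(truth_counts))
})
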