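make_omics <- function(values, layer = "protein") {
  colnames(values) <- c(paste0("u", 1:(ncol(values) / 2)),
                        paste0("t", 1:(ncol(values) / 2)))
  rownames(values) <- paste0("F", seq_len(nrow(values)))
  design <- tibble::tibble(
    sample = colnames(values),
    condition = rep(c("untreated", "treated"), each = ncol(values) / 2),
    replicate = rep(seq_len(ncol(values) / 2), 2)
  )
  hlaRemodel:::new_omics_table(values, design, layer)
}

test_that("simple_de null identity, symmetry and BH invariants hold", {
  set.seed(61)
  vals <- matrix(2^rnorm(50 * 6, 10, 1), nrow = 50)
  vals[1, ] <- 100  # identical in all samples
  om <- make_omics(vals)
  de <- simple_de(om)
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$p_value[1], 1)

  # swapping condition labels negates log2fc, keeps p
  om_swapped <- make_omics(vals[, c(4:6, 1:3)])
  de2 <- simple_de(om_swapped)
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-12)

  # BH: fdr monotone in p-value rank; fdr equals p at the largest p
  ord <- order(de$p_value)
  expect_true(all(diff(de$fdr[ord]) >= -1e-15))
  expect_equal(de$fdr[which.max(de$p_value)], max(de$p_value))
  expect_true(all(de$significant == (de$fdr < 0.05)))

  lopsided <- hlaRemodel:::new_omics_table(
    vals[, 1:4],
    tibble::tibble(sample = colnames(vals)[1:4],
                   condition = c("untreated", rep("treated", 3)),
                   replicate = c(1L, 1L, 2L, 3L)),
    "protein"
  )
  expect_error(simple_de(lopsided), "fewer than 2")
})

test_that("simple_de agrees with t.test on log-transformed data", {
  set.seed(62)
  vals <- matrix(2^rnorm(20 * 8, 8, 2), nrow = 20)
  om <- make_omics(vals, layer = "protein")
  de <- simple_de(om)
  y <- log2(1 + vals)
  for (i in seq_len(nrow(vals))) {
    tt <- t.test(y[i, 5:8], y[i, 1:4], var.equal = TRUE)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$log2fc[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-10)
  }
})

test_that("simple_de recovers planted transcript fold changes", {
  # symmetric planting, as in the generator: library sizes stay balanced
  set.seed(63)
  n <- 1000
  base <- rnorm(n, 9, 1)
  lfc <- rep(0, n); lfc[1:10] <- 2; lfc[11:20] <- -2
  mk <- function(shift) matrix(round(2^(base + shift +
                                          rnorm(n * 3, 0, 0.1))), nrow = n)
  vals <- cbind(mk(0), mk(lfc))
  om <- make_omics(vals, layer = "transcript")
  de <- simple_de(om)
  expect_lt(max(abs(de$log2fc[1:10] - 2)), 0.3)
  expect_lt(max(abs(de$log2fc[11:20] + 2)), 0.3)
  expect_true(all(de$significant[1:20]))
})

test_that("omics correlation handles exact, inverted and degenerate joins", {
  de_a <- tibble::tibble(feature = paste0("F", 1:30),
                         log2fc = rnorm(30), significant = TRUE)
  expect_equal(omics_correlation(de_a, de_a)$r, 1)
  de_b <- de_a; de_b$log2fc <- -de_b$log2fc
  expect_equal(omics_correlation(de_a, de_b)$r, -1)
  expect_error(omics_correlation(de_a[1:2, ], de_a[1:2, ]), "fewer than 3")
})

test_that("integration bins partition records with the stated edges", {
  mk <- function(acc, n, condition) tibble::tibble(
    accession = acc, condition = condition, n_peptides = n,
    coverage_pct = 1, log2_intensity = 0,
    peptide_list = replicate(length(acc), "X", simplify = FALSE)
  )
  su <- mk(c("P1", "P2", "P3"), c(4, 4, 9), "untreated")
  st <- mk(c("P1", "P2", "P4"), c(4, 1, 9), "treated")
  out <- integrate_peptidome(su, st)
  rec <- out$records
  expect_equal(rec$pep_bin[rec$accession == "P1"], "unchanged")  # fc = 1
  expect_equal(rec$pep_fc[rec$accession == "P2"], 0.4)
  expect_equal(rec$pep_bin[rec$accession == "P2"], "decreased")
  expect_equal(rec$pep_fc[rec$accession == "P3"], 0.1)
  expect_equal(rec$pep_bin[rec$accession == "P4"], "increased")
  # boundary: fold change exactly 0.5 is "unchanged" (closed interval)
  s2 <- integrate_peptidome(mk("P9", 9, "untreated"), mk("P9", 4, "treated"))
  expect_equal(s2$records$pep_fc, 0.5)
  expect_equal(s2$records$pep_bin, "unchanged")
  # partition: every record in exactly one bin
  expect_equal(sum(table(rec$pep_bin)), nrow(rec))
})

test_that("half-life correlations cover identity, null and clamped subsets", {
  mk <- function(acc, n) tibble::tibble(
    accession = acc, condition = "untreated", n_peptides = n,
    coverage_pct = 1, log2_intensity = 0,
    peptide_list = replicate(length(acc), "X", simplify = FALSE)
  )
  acc <- paste0("P", 1:50)
  s <- mk(acc, 1:50)
  hl_ident <- tibble::tibble(accession = acc, half_life_hours = 1:50)
  expect_equal(half_life_analysis(hl_ident, s, "all")$r, 1)

  set.seed(64)
  acc2 <- paste0("P", 1:1000)
  s2 <- mk(acc2, rpois(1000, 5) + 1)
  hl2 <- tibble::tibble(accession = acc2, half_life_hours = rlnorm(1000, 3, 1))
  out <- half_life_analysis(hl2, s2, "all")
  expect_lt(abs(out$r), 2 / sqrt(1000) + 0.02)
  expect_gt(out$p_value, 0.01)

  expect_warning(top <- half_life_analysis(hl_ident, s, "top100_fast"),
                 "using all")
  expect_equal(top$n, 50)
  expect_error(half_life_analysis(hl_ident[1:2, ], s[1:2, ], "all"),
               "fewer than 3")
})

test_that("half-life subsets select the extremes of the joined distribution", {
  mk <- function(acc, n) tibble::tibble(
    accession = acc, condition = "treated", n_peptides = n,
    coverage_pct = 1, log2_intensity = 0,
    peptide_list = replicate(length(acc), "X", simplify = FALSE)
  )
  acc <- paste0("P", 1:300)
  s <- mk(acc, rep(5, 300))
  hl <- tibble::tibble(accession = acc, half_life_hours = seq_len(300))
  # counts track half-life exactly in both tails, are flat in the middle
  s$n_peptides <- c(seq_len(100), rep(5, 100), 201:300)
  fast <- half_life_analysis(hl, s, "top100_fast")
  expect_equal(fast$n, 100)
  expect_equal(fast$r, 1)
  stable <- half_life_analysis(hl, s, "top100_stable")
  expect_equal(stable$n, 100)
  expect_equal(stable$r, 1)
  all_r <- half_life_analysis(hl, s, "all")$r
  expect_lt(all_r, 1)
})
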