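test_that("proteome generation is deterministic and validates", {
  cfg <- tiny_cfg(n_proteins = 10, protein_length_range = c(50, 60))
  db1 <- generate_proteome(cfg)
  db2 <- generate_proteome(cfg)
  expect_equal(nrow(db1), 10)
  expect_true(all(nchar(db1$sequence) >= 50 & nchar(db1$sequence) <= 60))
  expect_identical(db1, db2)
  expect_error(generate_proteome(tiny_cfg(n_proteins = 0)), "empty proteome")
})

test_that("every emitted peptide is an exact substring of its truth protein", {
  sim <- tiny_sim()
  seqs <- setNames(sim$proteome$sequence, sim$proteome$accession)
  found <- mapply(function(p, acc, s, e) {
    substr(seqs[[acc]], s + 1, e) == p
  }, sim$truth$sequence, sim$truth$accession, sim$truth$start, sim$truth$end)
  expect_true(all(found))
  # and lengths respect the class laws
  li <- sim$truth$length[sim$truth$hla_class == "I"]
  lii <- sim$truth$length[sim$truth$hla_class == "II"]
  expect_true(all(li >= 8 & li <= 12))
  expect_true(all(lii >= 13 & lii <= 17))
})

test_that("per-replicate counts recover the condition multiplier", {
  cfg <- tiny_cfg(n_peptides_untreated = 1000, count_multiplier = 2,
                  n_peptides_class_ii = 0, n_proteins = 600,
                  protein_length_range = c(200, 300), seed = 5L)
  sim <- generate_peptidome(cfg, generate_proteome(cfg))
  counts <- sim$peptides %>%
    dplyr::count(condition, replicate)
  m_u <- mean(counts$n[counts$condition == "untreated"])
  m_t <- mean(counts$n[counts$condition == "treated"])
  expect_lt(abs(m_t - 2000) / 2000, 0.10)
  expect_lt(abs(m_t / m_u - 2) / 2, 0.10)
})

test_that("shared_fraction and hlab_share are recovered from truth labels", {
  sim0 <- tiny_sim(shared_fraction = 0, n_peptides_untreated = 300,
                   n_proteins = 400, protein_length_range = c(150, 250))
  t0 <- sim0$truth[sim0$truth$hla_class == "I", ]
  expect_equal(sum(t0$category == "common"), 0)

  cfg <- tiny_cfg(n_peptides_untreated = 2000, n_proteins = 1500,
                  protein_length_range = c(200, 300),
                  hlab_share = c(untreated = 0.33, treated = 0.60),
                  n_peptides_class_ii = 0, seed = 3L)
  sim <- generate_peptidome(cfg, generate_proteome(cfg))
  tr <- sim$truth[sim$truth$hla_class == "I" &
                    sim$truth$category != "unique_untreated", ]
  share <- mean(tr$locus == "B")
  se <- sqrt(0.6 * 0.4 / nrow(tr))
  expect_lt(abs(share - 0.60), 3 * se + 0.005)
  un <- sim$truth[sim$truth$hla_class == "I" &
                    sim$truth$category != "unique_treated", ]
  expect_lt(abs(mean(un$locus == "B") - 0.33), 0.03)
})

test_that("class II peptides appear only under treatment by default", {
  sim <- tiny_sim()
  pep_ii <- sim$peptides[sim$peptides$hla_class == "II", ]
  expect_true(all(pep_ii$condition == "treated"))
  expect_gt(nrow(pep_ii), 0)
})

test_that("fixed seed gives byte-identical synthetic input files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_fixtures("tiny", seed = 42, dir = dir1)
  make_fixtures("tiny", seed = 42, dir = dir2)
  f1 <- sort(list.files(dir1, recursive = TRUE))
  f2 <- sort(list.files(dir2, recursive = TRUE))
  expect_equal(f1, f2)
  data_files <- setdiff(f1, "config.yaml")  # the yaml embeds absolute paths
  for (f in data_files) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("omics generator hits its correlation targets on truth values", {
  # r = 0: truth transcript log2FC uncorrelated with peptide log2FC
  cfg0 <- tiny_cfg(n_proteins = 500, n_peptides_untreated = 1500,
                   protein_length_range = c(200, 300),
                   omics_peptidome_r = c(transcript = 0, protein = 0),
                   seed = 9L)
  sim0 <- generate_peptidome(cfg0, generate_proteome(cfg0))
  om0 <- generate_omics(cfg0, sim0$truth, sim0$proteome)
  r0 <- cor(om0$truth$rna_log2fc, om0$truth$pep_log2fc)
  expect_lt(abs(r0), 2 / sqrt(nrow(om0$truth)) + 0.02)

  # r = 1 with no DE masking: exact correlation on truth values
  cfg1 <- tiny_cfg(omics_peptidome_r = c(transcript = 1, protein = 1),
                   de_fraction = 1)
  sim1 <- generate_peptidome(cfg1, generate_proteome(cfg1))
  om1 <- generate_omics(cfg1, sim1$truth, sim1$proteome)
  keep <- sd(om1$truth$pep_log2fc) > 0
  expect_equal(cor(om1$truth$rna_log2fc, om1$truth$pep_log2fc), 1,
               tolerance = 1e-12)

  # de_fraction = 0: all true fold changes exactly zero
  cfgz <- tiny_cfg(de_fraction = 0)
  simz <- generate_peptidome(cfgz, generate_proteome(cfgz))
  omz <- generate_omics(cfgz, simz$truth, simz$proteome)
  expect_true(all(omz$truth$rna_log2fc == 0))
  expect_true(all(omz$truth$prot_log2fc == 0))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(tiny_cfg(length_law_i = c(`8` = 0.5, `9` = 0.6)), "lengths")
  expect_error(tiny_cfg(shared_fraction = 1.2))
  expect_error(tiny_cfg(count_multiplier = 0))
  expect_error(tiny_cfg(omics_peptidome_r = 2))
  cfg <- tiny_cfg(protein_length_range = c(5, 6))
  expect_error(generate_peptidome(cfg, generate_proteome(cfg)),
               "peptide length exceeds|capacity")
})
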