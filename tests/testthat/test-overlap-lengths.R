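test_that("presence calling applies the category rule and bounds", {
  pep <- dplyr::bind_rows(
    pep_row("PEPTIDEA", "untreated", 1), pep_row("PEPTIDEA", "untreated", 2),
    pep_row("PEPTIDEA", "treated", 3),
    pep_row("PEPTIDEB", "treated", 1), pep_row("PEPTIDEB", "treated", 2),
    pep_row("PEPTIDEB", "treated", 3),
    pep_row("PEPTIDEC", "untreated", 2)
  )
  calls <- call_presence(pep, n_replicates = 3)
  expect_equal(calls$category[calls$sequence == "PEPTIDEA"], "common")
  expect_equal(calls$n_reps_untreated[calls$sequence == "PEPTIDEA"], 2)
  expect_equal(calls$category[calls$sequence == "PEPTIDEB"], "unique_treated")
  expect_equal(calls$category[calls$sequence == "PEPTIDEC"],
               "unique_untreated")

  expect_equal(nrow(call_presence(pep[0, ], 3)), 0)
  expect_error(call_presence(pep, n_replicates = 2), "replicate")

  # stricter >= 2-replicate mode drops singletons
  strict <- call_presence(pep, 3, min_replicates = 2)
  expect_false("PEPTIDEC" %in% strict$sequence)
  expect_equal(strict$category[strict$sequence == "PEPTIDEA"],
               "unique_untreated")
  expect_equal(attr(strict, "n_below_threshold"), 1L)
})

test_that("overlap summary partitions the union and sums to 100%", {
  pep <- dplyr::bind_rows(
    pep_row("AAAAAAAA", "untreated", 1),
    pep_row("BBBBBBBB", "untreated", 1), pep_row("BBBBBBBB", "treated", 1),
    pep_row("CCCCCCCC", "treated", 1),
    pep_row("DDDDDDDD", "treated", 2)
  )
  ov <- summarize_overlap(call_presence(pep, 3))
  expect_equal(ov$n_unique_untreated, 1)
  expect_equal(ov$n_common, 1)
  expect_equal(ov$n_unique_treated, 2)
  expect_equal(ov$pct_unique_untreated, 25)
  expect_equal(ov$pct_common, 25)
  expect_equal(ov$pct_unique_treated, 50)
  expect_equal(ov$pct_common + ov$pct_unique_treated +
                 ov$pct_unique_untreated, 100)
  expect_equal(ov$pct_common_of_untreated, 50)

  # partition invariant on a synthetic run, plus order invariance
  sim <- tiny_sim()
  pp <- sim$peptides[sim$peptides$hla_class == "I", ]
  calls <- call_presence(pp, 3)
  ov2 <- summarize_overlap(calls)
  expect_equal(ov2$n_unique_untreated + ov2$n_unique_treated + ov2$n_common,
               ov2$n_union)
  expect_equal(ov2$n_union, dplyr::n_distinct(pp$sequence))
  shuf <- pp[sample.int(nrow(pp)), ]
  expect_identical(call_presence(shuf, 3), calls)
})

test_that("length distributions give within-group proportions over 8-12", {
  pep <- dplyr::bind_rows(
    pep_row("AAAAAAAAA", "untreated", 1), pep_row("CCCCCCCCC", "untreated", 1),
    pep_row("DDDDDDDDD", "untreated", 1), pep_row("EEEEEEEEEE", "untreated", 1),
    pep_row("FFFFFFFFFFF", "untreated", 1), pep_row("GGGGGGGG", "untreated", 1)
  )
  d <- length_distribution(pep, "I", by = "condition")
  g <- d$group
  expect_equal(g$proportion[g$length == 9], 3 / 6)
  expect_equal(g$proportion[g$length == 8], 1 / 6)
  expect_equal(g$proportion[g$length == 12], 0)
  expect_equal(sum(g$proportion), 1)
})

test_that("treated 10/11-mer enrichment is detected iff the generator boosts it", {
  base <- list(n_peptides_untreated = 2500, n_proteins = 1500,
               protein_length_range = c(200, 300), n_peptides_class_ii = 0)
  run <- function(boost, seed) {
    cfg <- do.call(tiny_cfg, c(base, list(long_mer_boost = boost, seed = seed)))
    sim <- generate_peptidome(cfg, generate_proteome(cfg))
    d <- length_distribution(sim$peptides, "I", by = "condition")
    aov_out <- two_way_anova(as.data.frame(d$replicate), value = "proportion",
                             factor_a = "length", factor_b = "group")
    prop <- function(cond) sum(d$group$proportion[
      d$group$group == cond & d$group$length %in% c(10, 11)])
    list(diff = prop("treated") - prop("untreated"), anova = aov_out)
  }
  eff <- run(boost = 0.08, seed = 21)
  expect_gt(eff$diff, 0)
  sig1011 <- eff$anova$contrasts$significant[
    eff$anova$contrasts$level %in% c("10", "11")]
  expect_true(any(sig1011))

  null <- run(boost = 0, seed = 22)
  reps <- null$anova  # per-length contrasts under the null: none flagged
  expect_false(any(reps$contrasts$significant))
  expect_lt(abs(null$diff), 0.02)
})

test_that("two-way ANOVA matches aov on random balanced designs to 1e-8", {
  set.seed(404)
  for (k in 1:20) {
    na <- sample(3:6, 1)
    nr <- sample(2:4, 1)
    df <- expand.grid(length = paste0("L", seq_len(na)),
                      condition = c("untreated", "treated"),
                      replicate = seq_len(nr))
    df$proportion <- rnorm(nrow(df))
    mine <- two_way_anova(df)
    ref <- summary(stats::aov(proportion ~ length * condition, data = df))[[1]]
    expect_equal(mine$anova$statistic[1:3], ref[["F value"]][1:3],
                 tolerance = 1e-8)
    expect_equal(mine$anova$p_value[1:3], ref[["Pr(>F)"]][1:3],
                 tolerance = 1e-8)
    expect_equal(mine$anova$sumsq, ref[["Sum Sq"]], tolerance = 1e-8)
  }
})

test_that("ANOVA degenerate and error cases behave as specified", {
  df <- expand.grid(length = c("9", "10"), condition = c("untreated", "treated"),
                    replicate = 1:3)
  df$proportion <- rep(c(0.7, 0.3), 6)  # identical in both conditions
  out <- two_way_anova(df)
  expect_lt(out$anova$statistic[out$anova$term == "condition"], 1e-20)
  expect_gt(out$anova$p_value[out$anova$term == "condition"], 0.999)

  # zero within-cell variance with different condition means: maximal F, p -> 0
  df2 <- df
  df2$proportion <- ifelse(df2$condition == "treated",
                           ifelse(df2$length == "9", 0.9, 0.3),
                           ifelse(df2$length == "9", 0.6, 0.4))
  out2 <- two_way_anova(df2)
  expect_true(is.infinite(out2$anova$statistic[2]))
  expect_equal(out2$anova$p_value[2], 0)

  expect_error(two_way_anova(df[df$replicate == 1, ]),
               "insufficient replication")
})

test_that("ANOVA condition effect has ~5% type-I error on null data", {
  set.seed(777)
  n_sig <- 0L
  n_sim <- 1000
  grid <- expand.grid(length = paste0("L", 1:5),
                      condition = c("untreated", "treated"), replicate = 1:3)
  for (k in seq_len(n_sim)) {
    grid$proportion <- rnorm(nrow(grid))
    p <- two_way_anova(grid)$anova$p_value[2]
    n_sig <- n_sig + (p < 0.05)
  }
  expect_lt(abs(n_sig / n_sim - 0.05), 0.015)
})
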