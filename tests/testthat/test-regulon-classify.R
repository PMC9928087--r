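fc_row <- function(gene, fc, padj) {
  tibble::tibble(gene_id = gene, log2fc = fc, padj = padj)
}

test_that("the 2-fold rule classifies direction and regulation mode", {
  protein <- fc_row(c("a", "b", "c"), c(1.5, 0.0, -2.0), c(0.01, 0.9, 0.001))
  mrna <- fc_row(c("a", "b", "c"), c(0.1, 0.0, -2.0), c(0.8, 0.9, 0.001))
  cl <- classify_fold_changes(protein, mrna)
  expect_equal(cl$class, c("REPRESSED_BY_RSMQ", "UNCHANGED",
                           "ACTIVATED_BY_RSMQ"))
  expect_equal(cl$mode[cl$gene_id == "a"], "POST_TRANSCRIPTIONAL")
  expect_equal(cl$mode[cl$gene_id == "c"], "CONCORDANT")
  expect_match(attr(cl, "contrast"), "repressed")

  # genes in one layer only are classified there, mode UNDETERMINED
  p2 <- fc_row(c("a", "only_p"), c(1.5, 2.0), c(0.01, 0.01))
  m2 <- fc_row(c("a", "only_m"), c(0.1, -3.0), c(0.8, 0.001))
  cl2 <- classify_fold_changes(p2, m2)
  expect_equal(cl2$class[cl2$gene_id == "only_p"], "REPRESSED_BY_RSMQ")
  expect_equal(cl2$mode[cl2$gene_id == "only_p"], "UNDETERMINED")
  expect_equal(cl2$class[cl2$gene_id == "only_m"], "ACTIVATED_BY_RSMQ")

  expect_error(
    classify_fold_changes(fc_row(c("a", "a"), c(1, 1), c(0.1, 0.1)), mrna),
    "duplicate"
  )
})

test_that("classification partitions all genes and ignores row order", {
  cfg <- regulon_config(seed = 88)
  g <- sim_regulatory_genome(cfg)
  ex <- sim_expression_tables(g$truth, cfg)
  cl <- classify_fold_changes(ex$protein, ex$mrna)
  expect_equal(nrow(cl), nrow(g$truth))
  expect_true(all(cl$class %in% c("REPRESSED_BY_RSMQ", "ACTIVATED_BY_RSMQ",
                                  "UNCHANGED")))
  shuffled <- classify_fold_changes(
    ex$protein[sample(nrow(ex$protein)), ],
    ex$mrna[sample(nrow(ex$mrna)), ]
  )
  shuffled <- shuffled[match(cl$gene_id, shuffled$gene_id), ]
  expect_equal(shuffled$class, cl$class)
  expect_equal(shuffled$mode, cl$mode)
})

test_that("planted post-transcriptional targets are recovered at the 2-fold rule", {
  cfg <- regulon_config(n_targets = 50, n_background = 150, frac_full = 1,
                        frac_short = 0, effect_direct = 2, noise_sd = 0.1,
                        seed = 19)
  g <- sim_regulatory_genome(cfg)
  ex <- sim_expression_tables(g$truth, cfg)
  cl <- classify_fold_changes(ex$protein, ex$mrna)
  j <- dplyr::inner_join(cl, g$truth, by = "gene_id")
  recovered <- sum(j$class == "REPRESSED_BY_RSMQ" & j$is_target)
  expect_gte(recovered, 48)
  # closed-form sensitivity: P(N(2, 0.1) < 1) is ~0, so recovery ~100%
  pred_sens <- 1 - pnorm((1 - 2) / 0.1)
  expect_lt(abs(recovered / 50 - pred_sens), 0.03)
  # false positive rate on background matches the normal tail (~0)
  fp <- mean(j$class != "UNCHANGED" & !j$is_target)
  expect_lt(abs(fp - 2 * pnorm(-1 / 0.1)), 0.03)
  # discordance: regulated-but-mRNA-quiet fraction equals the target fraction
  post <- mean(j$mode == "POST_TRANSCRIPTIONAL")
  expect_equal(post, mean(j$is_target), tolerance = 0.05)
})

test_that("zero effect sizes yield zero regulated proteins", {
  cfg <- regulon_config(n_targets = 30, n_background = 30, effect_direct = 0,
                        effect_indirect = 0, seed = 5)
  g <- sim_regulatory_genome(cfg)
  ex <- sim_expression_tables(g$truth, cfg)
  cl <- classify_fold_changes(ex$protein, ex$mrna)
  expect_equal(sum(cl$class != "UNCHANGED"), 0)
  expect_error(
    sim_expression_tables(g$truth, regulon_config(noise_sd = 0)),
    "> 0"
  )
})

test_that("direct/indirect partition conserves counts and recovers fractions", {
  cfg <- regulon_config(n_targets = 100, n_background = 100, seed = 55)
  g <- sim_regulatory_genome(cfg)
  ex <- sim_expression_tables(g$truth, cfg)
  cl <- classify_fold_changes(ex$protein, ex$mrna)
  pr <- predict_regulon(g$genes, g$genome)
  part <- direct_indirect_partition(cl, pr$genes)
  expect_equal(sum(part$summary$n), part$n_regulated)
  expect_equal(sum(part$summary$fraction), 1)
  # generator plants 50% FULL / 25% SHORT among targets
  ci_hw <- 1.96 * sqrt(0.5 * 0.5 / part$n_regulated)
  expect_lt(abs(part$summary$fraction[part$summary$site_class == "FULL"] - 0.5),
            ci_hw + 0.02)
  expect_lt(
    abs(part$summary$fraction[part$summary$site_class == "SHORT_ONLY"] - 0.25),
    ci_hw + 0.02
  )

  # every regulated gene with a planted full site
  all_full <- direct_indirect_partition(
    cl[cl$gene_id %in% g$truth$gene_id[g$truth$motif_class == "FULL"], ],
    pr$genes
  )
  expect_equal(
    all_full$summary$fraction[all_full$summary$site_class == "FULL"], 1
  )

  # no regulated genes: empty summary, no division by zero
  none <- direct_indirect_partition(
    dplyr::mutate(cl, class = "UNCHANGED"), pr$genes
  )
  expect_equal(none$n_regulated, 0L)

  # missing predictions counted as no-site with a warning
  expect_warning(
    direct_indirect_partition(cl, pr$genes[1:10, ]),
    "no-site"
  )
})

test_that("COG tabulation preserves per-gene direction totals", {
  cl <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    class = c("REPRESSED_BY_RSMQ", "REPRESSED_BY_RSMQ", "ACTIVATED_BY_RSMQ")
  )
  cog <- tibble::tibble(gene_id = c("a", "b", "b"), cog = c("E", "E", "P"))
  tab <- cog_tabulate(cl, cog)
  expect_equal(tab$n[tab$cog == "E" & tab$class == "REPRESSED_BY_RSMQ"], 2L)
  expect_equal(tab$n[tab$cog == "P"], 1L) # multi-category gene counts per category
  expect_equal(tab$n[tab$cog == "unknown"], 1L) # unmapped gene
  single <- cog_tabulate(cl, tibble::tibble(gene_id = c("a", "b", "c"),
                                            cog = "E"))
  expect_equal(sum(single$n), 3L)
})

test_that("transcriptome summaries count and stay monotone in the threshold", {
  mrna <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    log2fc = c(rep(2, 5), rep(0, 5)),
    padj = c(rep(0.001, 5), rep(0.9, 5))
  )
  s <- transcriptome_summary(mrna)
  expect_equal(s$n[s$direction == "up"], 5L)
  expect_equal(s$n[s$direction == "down"], 0L)
  s4 <- transcriptome_summary(mrna, fc_threshold = 2)
  expect_true(all(s4$n <= s$n))

  # near-null after BH: planted null gives ~0 significant calls
  cfg <- regulon_config(n_targets = 0, n_background = 200, seed = 2)
  g <- sim_regulatory_genome(cfg)
  ex <- sim_expression_tables(g$truth, cfg)
  s0 <- transcriptome_summary(ex$mrna)
  expect_equal(sum(s0$n), 0L)
})
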