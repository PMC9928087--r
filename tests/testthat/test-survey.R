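published_table <- function() {
  tibble::tibble(
    family = c("Pseudomonadaceae", "Piscirickettsiaceae", "Legionellaceae",
               "Enterobacteriaceae"),
    carriers = c(41L, 12L, 21L, 0L),
    non_carriers = c(155L, 55L, 8L, 3621L)
  )
}

test_that("taxon contingency reproduces per-family carrier counts", {
  plasmids <- tidyr::uncount(
    tidyr::pivot_longer(published_table(), c("carriers", "non_carriers"),
                        names_to = "grp", values_to = "n"),
    weights = n
  )
  plasmids$carries_rsm <- plasmids$grp == "carriers"
  tab <- taxon_contingency(plasmids)
  tab <- tab[match(published_table()$family, tab$family), ]
  expect_equal(tab$carriers, published_table()$carriers)
  expect_equal(tab$non_carriers, published_table()$non_carriers)

  one <- taxon_contingency(
    tibble::tibble(family = "X", carries_rsm = c(TRUE, FALSE, FALSE))
  )
  expect_equal(nrow(one), 1)
  expect_equal(one$total, 3L)
  expect_error(taxon_contingency(tibble::tibble()), "empty")
})

test_that("two-sided 2x2 Fisher equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 0.4857143,
               tolerance = 1e-6)
  # label symmetry
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value,
               fisher_exact(matrix(c(0, 5, 5, 0), 2))$p_value)
  # random subset of tables with total <= 30 (the full sweep runs in the
  # acceptance suite)
  set.seed(8)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tab <- matrix(c(cuts[1], cuts[2] - cuts[1],
                    cuts[3] - cuts[2], n - cuts[3]), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, bf_fisher_2x2(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
})

test_that("Fisher on the published 2x4 family table is far below 0.0005", {
  res <- fisher_exact(published_table())
  expect_lt(res$p_value, 0.0005)
})

test_that("Monte Carlo Fisher converges to the exact enumeration p", {
  tab <- matrix(c(8, 3, 5, 9, 2, 7), nrow = 2)
  exact <- stats::fisher.test(tab)$p.value
  mc <- fisher_exact(tab, exact_total_max = 0, mc_replicates = 2e4)
  se <- sqrt(exact * (1 - exact) / 2e4)
  expect_lt(abs(mc$p_value - exact), 2 * se + 1e-4)
  expect_match(mc$method, "Monte Carlo")
})

test_that("mobility association flags, adjusts, and detects planted effects", {
  # all carriers (and only carriers) conjugative, 10 vs 10
  df <- tibble::tibble(
    family = "F",
    carries_rsm = rep(c(TRUE, FALSE), each = 10),
    mobility = rep(c("conjugative", "non_mobilizable"), each = 10)
  )
  res <- mobility_association(df)
  fam <- res[res$family == "F", ]
  expect_lt(fam$p_value, 0.01)
  # single family: Bonferroni with m = 1 leaves p unchanged
  expect_equal(fam$p_adjusted, fam$p_value)
  # one mobility class -> untestable
  df2 <- tibble::tibble(family = "G", carries_rsm = c(TRUE, FALSE),
                        mobility = "conjugative")
  expect_true(mobility_association(df2)$untestable[1])
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:4, 1:4)$statistic, 0)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.9, 1.0))$statistic, 1)
  expect_equal(ks_two_sample(1:4, 3:6)$statistic, 0.5)
  set.seed(13)
  for (i in 1:200) {
    x <- round(runif(sample(2:12, 1)), 2)
    y <- round(runif(sample(2:12, 1)), 2)
    expect_equal(ks_two_sample(x, y)$statistic, bf_ks_D(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("survey tests hold their size under a null simulation", {
  set.seed(2024)
  B <- 400
  p_fisher <- replicate(B, {
    x <- rbinom(1, 100, 0.5); y <- rbinom(1, 100, 0.5)
    fisher_exact(matrix(c(x, 100 - x, y, 100 - y), 2))$p_value
  })
  p_ks <- replicate(B, ks_two_sample(rnorm(100), rnorm(100))$p_value)
  ci_hw <- 1.96 * sqrt(0.05 * 0.95 / B)
  # Fisher: discrete but near-nominal at this n
  expect_lt(abs(mean(p_fisher <= 0.05) - 0.05), ci_hw + 0.01)
  # KS: conservative by construction; must never exceed nominal + CI
  expect_lt(mean(p_ks <= 0.05), 0.05 + ci_hw)
})

test_that("size summaries use the midrank-among-others convention", {
  pl <- tibble::tibble(
    family = "F", length_bp = c(10, 20, 30, 40) * 1e3,
    carries_rsm = c(FALSE, FALSE, FALSE, TRUE)
  )
  s <- size_summary(pl)
  expect_equal(s$families$min_carrier_kb, 40)
  expect_equal(s$carriers$quantile_rank, 1.0)

  same <- tibble::tibble(family = "F", length_bp = rep(5e4, 6),
                         carries_rsm = c(TRUE, rep(FALSE, 5)))
  expect_equal(size_summary(same)$carriers$quantile_rank, 0.5)

  # carriers planted at the top of the size distribution rank high
  set.seed(3)
  pl2 <- tibble::tibble(
    family = "F",
    length_bp = sort(stats::rlnorm(50, log(5e4), 0.5)),
    carries_rsm = c(rep(FALSE, 45), rep(TRUE, 5))
  )
  expect_gt(mean(size_summary(pl2)$carriers$quantile_rank), 0.9)
})

test_that("binding-site density comparison detects planted enrichment", {
  set.seed(6)
  n <- 50
  pl <- tibble::tibble(
    plasmid_id = sprintf("p%02d", 1:(2 * n)),
    carries_rsm = rep(c(TRUE, FALSE), each = n)
  )
  cds <- rpois(2 * n, 60) + 10
  rate <- ifelse(pl$carries_rsm, 0.30, 0.15) # doubled density in carriers
  sites <- tibble::tibble(
    plasmid_id = pl$plasmid_id,
    n_target_genes = rbinom(2 * n, cds, rate),
    n_cds = cds
  )
  res <- binding_density_comparison(pl, sites)
  expect_true(all(res$densities$density >= 0 & res$densities$density <= 1))
  expect_lt(res$tests$p_value[res$tests$comparison == "site_density"], 0.05)

  # identical distributions: D = 0, p = 1
  sites_same <- sites
  sites_same$n_target_genes <- 5L
  sites_same$n_cds <- 50L
  res2 <- binding_density_comparison(pl, sites_same)
  expect_equal(res2$tests$statistic[1], 0)
  expect_equal(res2$tests$p_value[1], 1)

  sites_zero <- sites
  sites_zero$n_cds[1] <- 0L
  expect_warning(binding_density_comparison(pl, sites_zero), "zero CDS")
})

test_that("homologue detection recovers planted homologues without false positives", {
  cfg <- survey_config(
    taxa = tibble::tibble(family = c("A", "B"), n_plasmids = c(10, 10),
                          carriage_prob = c(0.5, 0.5)),
    seed = 2
  )
  pl <- sim_plasmid_collection(cfg)
  pg <- sim_plasmid_proteins(pl, genes_per_plasmid = 3,
                             homologue_identity = 0.9, seed = 2)
  det <- detect_rsm_homologues(pl, pg)
  expect_equal(det$plasmids$carries_rsm, pl$carries_rsm)
  expect_true(all(det$hits$gene_id %in%
                    pg$gene_id[pg$is_homologue_truth]))

  # a self-match is perfect
  ref <- rsm_reference_proteins()
  self <- detect_rsm_homologues(
    tibble::tibble(plasmid_id = "p1"),
    tibble::tibble(plasmid_id = "p1", gene_id = "g1",
                   protein = ref$sequence[1]),
    ref
  )
  expect_equal(self$hits$identity, 1)
  expect_equal(self$hits$coverage, 1)

  # reversed protein of identical composition is not a hit
  rev_prot <- paste(rev(strsplit(ref$sequence[1], "")[[1]]), collapse = "")
  revd <- detect_rsm_homologues(
    tibble::tibble(plasmid_id = "p1"),
    tibble::tibble(plasmid_id = "p1", gene_id = "g1", protein = rev_prot),
    ref
  )
  expect_equal(nrow(revd$hits), 0)

  expect_error(
    detect_rsm_homologues(pl, pg, min_identity = 1.5),
    "\\(0, 1\\]"
  )
  expect_warning(
    detect_rsm_homologues(
      tibble::tibble(plasmid_id = c("p1", "p2")),
      tibble::tibble(plasmid_id = "p1", gene_id = "g1",
                     protein = ref$sequence[1])
    ),
    "no genes"
  )
})
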