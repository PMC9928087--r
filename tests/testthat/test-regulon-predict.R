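make_genome <- function(n = 2000) {
  withr::with_seed(5, random_rna(n))
}

test_that("search windows span 500 nt upstream plus the first 100 nt of the ORF", {
  genome <- gsub("U", "T", make_genome(3000))
  genes <- tibble::tibble(gene_id = "g1", start = 1001, end = 1600,
                          strand = "+")
  w <- extract_search_window(genes, genome)
  expect_equal(w$win_start, 501)
  expect_equal(w$win_end, 1100)
  expect_equal(nchar(w$window), 600)
  expect_equal(w$window, substr(genome, 501, 1100))

  # upstream truncation at the contig start
  g2 <- tibble::tibble(gene_id = "g2", start = 201, end = 800, strand = "+")
  w2 <- extract_search_window(g2, genome)
  expect_equal(c(w2$win_start, w2$win_end), c(1, 300))
  expect_equal(nchar(w2$window), 300)

  # short ORF truncates the ORF-side span
  g3 <- tibble::tibble(gene_id = "g3", start = 1001, end = 1050, strand = "+")
  expect_equal(nchar(extract_search_window(g3, genome)$window), 550)

  expect_error(
    extract_search_window(
      tibble::tibble(gene_id = "g", start = 2999, end = 3200, strand = "+"),
      genome
    ),
    "outside"
  )
})

test_that("minus-strand windows mirror plus-strand windows exactly", {
  genome <- gsub("U", "T", make_genome(3000))
  plus <- tibble::tibble(gene_id = "g", start = 1001, end = 1600,
                         strand = "+")
  w_plus <- extract_search_window(plus, genome)
  # mirror gene on the reverse-complemented contig
  rc <- rsmregulon:::revcomp(genome)
  minus <- tibble::tibble(
    gene_id = "g",
    start = nchar(genome) - 1600 + 1, end = nchar(genome) - 1001 + 1,
    strand = "-"
  )
  w_minus <- extract_search_window(minus, rc)
  expect_equal(w_minus$window, w_plus$window)
})

test_that("planted apex motifs are recovered and motif-free genes stay clean", {
  cfg <- regulon_config(n_targets = 24, n_background = 24, seed = 303)
  g <- sim_regulatory_genome(cfg)
  pr <- predict_regulon(g$genes, g$genome)
  j <- dplyr::inner_join(pr$genes, g$truth, by = "gene_id")

  planted <- j[j$motif_class != "NONE", ]
  expect_true(all(planted$direct_candidate))
  expect_true(all(planted$apex_anywhere))
  expect_equal(j$site_class[j$motif_class == "FULL"],
               rep("FULL", sum(j$motif_class == "FULL")))
  expect_equal(j$site_class[j$motif_class == "SHORT"],
               rep("SHORT_ONLY", sum(j$motif_class == "SHORT")))

  clean <- j[j$motif_class == "NONE", ]
  expect_equal(clean$site_class, rep("NONE", nrow(clean)))
  expect_false(any(clean$direct_candidate))
})

test_that("occluded planted motifs are never called exposed apex", {
  cfg <- regulon_config(n_targets = 10, n_background = 0,
                        frac_full = 1, frac_short = 0,
                        exposure = "occluded", seed = 17)
  g <- sim_regulatory_genome(cfg)
  pr <- predict_regulon(g$genes, g$genome)
  expect_false(any(pr$hits$exposure == "APEX"))
  expect_false(any(pr$genes$direct_candidate))
})

test_that("planted motif coordinates always fall inside the gene's search window", {
  cfg <- regulon_config(n_targets = 30, n_background = 0, seed = 21)
  g <- sim_regulatory_genome(cfg)
  w <- extract_search_window(g$genes, g$genome)
  tr <- dplyr::inner_join(g$truth[!is.na(g$truth$motif_start), ], w,
                          by = "gene_id")
  expect_true(all(tr$motif_start >= tr$win_start &
                    tr$motif_end <= tr$win_end))
})

test_that("a motif beyond the upstream window bound is not reported", {
  # 700 nt of inert upstream, motif 600 nt before the start codon
  up <- strrep("C", 700)
  substr(up, 96, 100) <- "ACGGA" # gene starts at 701 -> motif at -605..-601
  genome <- paste0(up, strrep("C", 600))
  genes <- tibble::tibble(gene_id = "g", start = 701, end = 1300,
                          strand = "+")
  pr <- predict_regulon(genes, genome)
  expect_equal(pr$genes$site_class, "NONE")
})

test_that("chance full-motif counts in uniform sequence match the closed form", {
  # P(AnGGA at a position) = (1/4)^4; expected hits per window = (L-4)/256
  set.seed(99)
  L <- 400
  counts <- replicate(300, {
    h <- scan_motifs(random_rna(L))
    sum(h$motif_class == "FULL")
  })
  expected <- (L - 4) / 256
  expect_lt(abs(mean(counts) - expected) / expected, 0.15)
})

test_that("regulon prediction is strand symmetric", {
  cfg <- regulon_config(n_targets = 10, n_background = 10, seed = 31)
  g <- sim_regulatory_genome(cfg)
  pr_fwd <- predict_regulon(g$genes, g$genome)
  L <- nchar(g$genome)
  mirrored <- tibble::tibble(
    gene_id = g$genes$gene_id,
    start = L - g$genes$end + 1,
    end = L - g$genes$start + 1,
    strand = "-"
  )
  pr_rev <- predict_regulon(mirrored, rsmregulon:::revcomp(g$genome))
  cols <- c("gene_id", "site_class", "n_full", "n_short", "apex_anywhere",
            "direct_candidate")
  expect_equal(pr_fwd$genes[cols], pr_rev$genes[cols])
})

test_that("ncRNA decomposition tiles, folds and calls segments", {
  seg_strong <- paste0("AAAA", "GCCCCC", "A", "GGA", "A", "GGGGGC", "AAAA")
  filler <- strrep("A", 25)
  d <- decompose_ncrna(paste0(seg_strong, filler), segment_length = 25)
  expect_equal(nrow(d), 2)
  expect_equal(d$call[1], "STRONG")
  expect_equal(d$call[2], "NONE") # poly-A segment
  expect_equal(d$exposure[2], "LINEAR")
  expect_error(decompose_ncrna(filler, segment_length = 5), ">= 10")
  expect_error(decompose_ncrna("ACGU", segment_length = 25), "shorter")
})
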