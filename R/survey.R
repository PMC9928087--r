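# Comparative statistics of regulator-homologue carriage across a plasmid
# collection: homologue detection, taxon contingency, Fisher exact tests,
# mobility association, size distributions, and binding-site-density
# comparisons.

#' Detect regulator homologues on plasmid gene sets
#'
#' Screens every plasmid protein against a set of reference regulator
#' sequences by local alignment (BLOSUM62, affine gaps: open 10, extend 1).
#' A gene is a hit when its best alignment reaches at least `min_identity`
#' over at least `min_coverage` of the reference; a plasmid carries the
#' regulator when it has at least one hit.
#'
#' @param plasmids Plasmid tibble (needs `plasmid_id`).
#' @param genes Tibble of plasmid proteins: `plasmid_id`, `gene_id`,
#'   `protein`.
#' @param reference Tibble of reference proteins: `name`, `sequence`.
#' @param min_identity Minimum fractional identity over the aligned region,
#'   in (0, 1].
#' @param min_coverage Minimum fraction of the reference covered by the
#'   alignment, in (0, 1].
#' @return List with `plasmids` (input plus logical `carries_rsm`; plasmids
#'   without genes are scored non-carriers with a warning) and `hits`
#'   (per-hit tibble: `plasmid_id`, `gene_id`, `reference`, `identity`,
#'   `coverage`, `score`).
#' @export
detect_rsm_homologues <- function(plasmids, genes,
                                  reference = rsm_reference_proteins(),
                                  min_identity = 0.35, min_coverage = 0.7) {
  if (nrow(reference) == 0) abort("reference set must be non-empty")
  if (min_identity <= 0 || min_identity > 1 ||
      min_coverage <= 0 || min_coverage > 1) {
    abort("`min_identity` and `min_coverage` must lie in (0, 1]")
  }
  empty <- setdiff(plasmids$plasmid_id, genes$plasmid_id)
  if (length(empty) > 0) {
    warn(sprintf("%d plasmid(s) have no genes and are scored non-carriers",
                 length(empty)))
  }

  mat <- "BLOSUM62"
  hits <- purrr::pmap_dfr(
    genes[c("plasmid_id", "gene_id", "protein")],
    function(plasmid_id, gene_id, protein) {
      best <- NULL
      for (r in seq_len(nrow(reference))) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(protein),
          Biostrings::AAString(reference$sequence[r]),
          type = "local", substitutionMatrix = mat,
          gapOpening = 10, gapExtension = 1
        )
        identity <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        coverage <- Biostrings::nchar(aln) / nchar(reference$sequence[r])
        if (is.null(best) || Biostrings::score(aln) > best$score) {
          best <- list(reference = reference$name[r], identity = identity,
                       coverage = coverage, score = Biostrings::score(aln))
        }
      }
      if (best$identity >= min_identity && best$coverage >= min_coverage) {
        tibble(plasmid_id = plasmid_id, gene_id = gene_id,
               reference = best$reference, identity = best$identity,
               coverage = best$coverage, score = best$score)
      } else {
        tibble()
      }
    }
  )
  if (nrow(hits) == 0) {
    hits <- tibble(plasmid_id = character(), gene_id = character(),
                   reference = character(), identity = numeric(),
                   coverage = numeric(), score = numeric())
  }
  plasmids$carries_rsm <- plasmids$plasmid_id %in% hits$plasmid_id
  list(plasmids = plasmids, hits = hits)
}

#' Carriage-by-taxon contingency table
#'
#' Tabulates carrier and non-carrier plasmid counts per family, pooling
#' families below a minimum plasmid count into `"other"`.
#'
#' @param plasmids Tibble with `family` and logical `carries_rsm`.
#' @param min_family_count Families with fewer plasmids are pooled.
#' @return Tibble with `family`, `carriers`, `non_carriers`, `total`.
#' @export
taxon_contingency <- function(plasmids, min_family_count = 1) {
  if (nrow(plasmids) == 0) abort("empty plasmid collection")
  tab <- plasmids %>%
    dplyr::count(.data$family, .data$carries_rsm) %>%
    tidyr::pivot_wider(names_from = "carries_rsm", values_from = "n",
                       values_fill = 0L)
  if (!"TRUE" %in% names(tab)) tab[["TRUE"]] <- 0L
  if (!"FALSE" %in% names(tab)) tab[["FALSE"]] <- 0L
  tab <- tab %>%
    dplyr::transmute(
      family = .data$family,
      carriers = .data[["TRUE"]],
      non_carriers = .data[["FALSE"]],
      total = .data$carriers + .data$non_carriers
    )
  small <- tab$total < min_family_count
  if (any(small)) {
    pooled <- tibble(
      family = "other",
      carriers = sum(tab$carriers[small]),
      non_carriers = sum(tab$non_carriers[small]),
      total = sum(tab$total[small])
    )
    tab <- dplyr::bind_rows(tab[!small, ], pooled)
  }
  dplyr::arrange(tab, dplyr::desc(.data$total))
}

#' Convert a carriage contingency tibble to a 2 x k matrix
#'
#' @param tab Tibble from [taxon_contingency()] (or any tibble with
#'   `family`, `carriers`, `non_carriers`).
#' @return Numeric matrix with rows `carrier`/`non_carrier` and one column
#'   per family.
#' @export
contingency_matrix <- function(tab) {
  non_carriers <- if ("non_carriers" %in% names(tab)) {
    tab$non_carriers
  } else {
    tab$total - tab$carriers
  }
  m <- rbind(carrier = tab$carriers, non_carrier = non_carriers)
  colnames(m) <- tab$family
  m
}

#' Fisher's exact test on a carriage table
#'
#' For a 2 x 2 table the two-sided p-value is the exact hypergeometric sum
#' of tables whose point probability does not exceed the observed table's.
#' For 2 x k tables the exact network algorithm is used when the table total
#' is small enough, and otherwise p is estimated by Monte Carlo permutation
#' with a fixed seed and the bias-corrected estimator (b + 1) / (B + 1).
#'
#' @param x A 2 x k matrix, a contingency tibble with `carriers` and
#'   `non_carriers` columns, or anything coercible to a matrix.
#' @param exact_total_max Largest table total for which the exact r x c
#'   algorithm is attempted (2 x 2 tables are always exact).
#' @param mc_replicates Monte Carlo replicate count.
#' @param mc_seed Fixed seed for the Monte Carlo path.
#' @return One-row tidy test result (statistic is the odds ratio for 2 x 2,
#'   `NA` otherwise).
#' @export
fisher_exact <- function(x, exact_total_max = 2000, mc_replicates = 1e5,
                         mc_seed = 12345) {
  if (is.data.frame(x)) x <- contingency_matrix(x)
  x <- as.matrix(x)
  if (any(x < 0)) abort("contingency cells must be non-negative")
  if (sum(x) == 0) abort("all-zero contingency table")
  if (any(x != round(x))) abort("contingency cells must be integer counts")

  if (all(dim(x) == c(2, 2))) {
    ft <- stats::fisher.test(x)
    return(test_result("odds_ratio", unname(ft$estimate), ft$p.value,
                       method = "exact hypergeometric, two-sided"))
  }
  if (sum(x) <= exact_total_max) {
    ft <- tryCatch(
      stats::fisher.test(x, workspace = 2e7),
      error = function(e) NULL
    )
    if (!is.null(ft)) {
      return(test_result("fisher_rxc", NA_real_, ft$p.value,
                         method = "exact network algorithm"))
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(mc_seed)
  ft <- stats::fisher.test(x, simulate.p.value = TRUE, B = mc_replicates)
  test_result(
    "fisher_rxc", NA_real_, ft$p.value,
    method = sprintf("Monte Carlo, B = %g, seed = %d, p = (b+1)/(B+1)",
                     mc_replicates, mc_seed)
  )
}

#' Association between carriage and conjugative mobility, per family
#'
#' Within each family, tests carriage against conjugative (vs any other)
#' mobility with Fisher's exact test, Bonferroni-adjusting over the number
#' of testable families; a pooled cross-taxa test is appended. Families with
#' fewer than two distinct mobility classes, or with carriage constant, are
#' flagged untestable.
#'
#' @param plasmids Tibble with `family`, `mobility`, `carries_rsm`.
#' @return Tibble with one row per family plus a `"pooled"` row: `family`,
#'   `n`, `odds_ratio`, `p_value`, `p_adjusted` (Bonferroni, m = testable
#'   families), `untestable`.
#' @export
mobility_association <- function(plasmids) {
  one_test <- function(df, label) {
    conj <- df$mobility == "conjugative"
    if (length(unique(df$mobility)) < 2 ||
        length(unique(df$carries_rsm)) < 2) {
      return(tibble(family = label, n = nrow(df), odds_ratio = NA_real_,
                    p_value = NA_real_, untestable = TRUE))
    }
    tab <- table(factor(df$carries_rsm, c(TRUE, FALSE)),
                 factor(conj, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    tibble(family = label, n = nrow(df),
           odds_ratio = unname(ft$estimate), p_value = ft$p.value,
           untestable = FALSE)
  }
  per_family <- plasmids %>%
    dplyr::group_by(.data$family) %>%
    dplyr::group_map(~one_test(.x, .y$family)) %>%
    dplyr::bind_rows()
  m <- sum(!per_family$untestable)
  per_family$p_adjusted <- pmin(1, per_family$p_value * max(m, 1))
  pooled <- one_test(plasmids, "pooled")
  pooled$p_adjusted <- pooled$p_value
  dplyr::bind_rows(per_family, pooled)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the exact distribution for small, tie-free samples and the
#' asymptotic Kolmogorov distribution otherwise (recorded in `method`).
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row tidy test result with `statistic` = D.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y))
  test_result("ks_D", unname(kt$statistic), kt$p.value,
              method = paste0("two-sided two-sample KS (", kt$method, ")"))
}

#' Plasmid size distributions for carriers and non-carriers
#'
#' Per family: size quantiles by carriage group, the minimum carrier size,
#' and for each carrier its quantile rank within the family's size
#' distribution (midrank among the other plasmids of the family, so a
#' carrier larger than all others ranks 1.0 and all-equal sizes rank 0.5).
#'
#' @param plasmids Tibble with `family`, `length_bp`, `carries_rsm`.
#' @return List with `families` (per-family summary) and `carriers`
#'   (per-carrier `quantile_rank`).
#' @export
size_summary <- function(plasmids) {
  fam <- plasmids %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_carriers = sum(.data$carries_rsm),
      median_carrier_kb = stats::median(.data$length_bp[.data$carries_rsm]) / 1e3,
      median_noncarrier_kb = stats::median(.data$length_bp[!.data$carries_rsm]) / 1e3,
      min_carrier_kb = if (any(.data$carries_rsm)) {
        min(.data$length_bp[.data$carries_rsm]) / 1e3
      } else NA_real_,
      .groups = "drop"
    )
  carriers <- plasmids %>%
    dplyr::group_by(.data$family) %>%
    dplyr::group_modify(function(df, key) {
      idx <- which(df$carries_rsm)
      if (length(idx) == 0) return(tibble())
      carr <- df[idx, , drop = FALSE]
      carr$quantile_rank <- vapply(idx, function(i) {
        s <- df$length_bp[i]
        others <- df$length_bp[-i] # midrank among the other family members
        if (length(others) == 0) return(NA_real_)
        (sum(others < s) + 0.5 * sum(others == s)) / length(others)
      }, numeric(1))
      carr
    }) %>%
    dplyr::ungroup()
  list(families = fam, carriers = carriers)
}

#' Compare predicted binding-site density between carriers and non-carriers
#'
#' Density is predicted-target genes divided by total CDS per plasmid;
#' plasmids with zero CDS are excluded with a warning. Carrier and
#' non-carrier density distributions are compared by the two-sample KS test,
#' and the absolute predicted-site counts are compared the same way.
#'
#' @param plasmids Tibble with `plasmid_id`, `carries_rsm`.
#' @param site_counts Tibble with `plasmid_id`, `n_target_genes`, `n_cds`.
#' @return List with `tests` (two tidy rows: density and absolute count)
#'   and `densities` (per-plasmid tibble).
#' @export
binding_density_comparison <- function(plasmids, site_counts) {
  df <- dplyr::inner_join(plasmids, site_counts, by = "plasmid_id")
  zero <- df$n_cds == 0
  if (any(zero)) {
    warn(sprintf("excluding %d plasmid(s) with zero CDS", sum(zero)))
    df <- df[!zero, , drop = FALSE]
  }
  df$density <- df$n_target_genes / df$n_cds
  carr <- df[df$carries_rsm, ]
  nonc <- df[!df$carries_rsm, ]
  tests <- dplyr::bind_rows(
    dplyr::mutate(ks_two_sample(carr$density, nonc$density),
                  comparison = "site_density"),
    dplyr::mutate(ks_two_sample(carr$n_target_genes, nonc$n_target_genes),
                  comparison = "site_count")
  )
  list(tests = tests, densities = df)
}
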