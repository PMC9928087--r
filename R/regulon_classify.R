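# Integration of mRNA and protein fold-change tables with binding
# predictions: the 2-fold regulation classification, post-transcriptional
# discordance, direct/indirect partition and COG tabulation.
#
# Sign convention: the contrast is regulator-deleted over regulator-present,
# so a POSITIVE protein log2 fold change means the protein is MORE abundant
# without the regulator, i.e. repressed by it.

#' Classify genes by fold change across the mRNA and protein layers
#'
#' A gene is `REPRESSED_BY_RSMQ` when its protein log2 fold change is at
#' least `+fc_threshold` (more protein once the regulator is lost) and
#' significant, `ACTIVATED_BY_RSMQ` for at most `-fc_threshold`, otherwise
#' `UNCHANGED`. The regulation mode compares the layers:
#' `POST_TRANSCRIPTIONAL` when the protein is regulated but the mRNA is not
#' (or moves oppositely), `CONCORDANT` when both move the same way,
#' `TRANSCRIPTIONAL` when only the mRNA is regulated, and `UNDETERMINED`
#' when a layer is missing (such genes are classified on the available
#' layer rather than dropped).
#'
#' @param protein,mrna Fold-change tibbles (`gene_id`, `log2fc`, `padj`);
#'   either may be missing genes present in the other (outer join).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1, the
#'   2-fold rule).
#' @param p_cutoff Adjusted-p significance cutoff (default 0.05, BH scale).
#' @param require_padj Set `FALSE` to classify on fold change alone.
#' @return Per-gene tibble: `gene_id`, layer values, `class`, `mode`,
#'   plus a `contrast` attribute recording the sign convention.
#' @export
classify_fold_changes <- function(protein, mrna, fc_threshold = 1,
                                  p_cutoff = 0.05, require_padj = TRUE) {
  for (tb in list(protein = protein, mrna = mrna)) {
    if (anyDuplicated(tb$gene_id)) {
      abort("duplicate gene ids within a layer")
    }
  }
  joined <- dplyr::full_join(
    dplyr::select(protein, "gene_id", protein_log2fc = "log2fc",
                  protein_padj = "padj"),
    dplyr::select(mrna, "gene_id", mrna_log2fc = "log2fc",
                  mrna_padj = "padj"),
    by = "gene_id"
  )
  regulated <- function(fc, padj) {
    !is.na(fc) & abs(fc) >= fc_threshold &
      (!require_padj | (!is.na(padj) & padj <= p_cutoff))
  }
  p_reg <- regulated(joined$protein_log2fc, joined$protein_padj)
  m_reg <- regulated(joined$mrna_log2fc, joined$mrna_padj)
  has_p <- !is.na(joined$protein_log2fc)
  has_m <- !is.na(joined$mrna_log2fc)
  # classify on the protein layer, falling back to mRNA when absent
  fc_used <- ifelse(has_p, joined$protein_log2fc, joined$mrna_log2fc)
  reg_used <- ifelse(has_p, p_reg, m_reg)
  joined$class <- dplyr::case_when(
    reg_used & fc_used >= fc_threshold ~ "REPRESSED_BY_RSMQ",
    reg_used & fc_used <= -fc_threshold ~ "ACTIVATED_BY_RSMQ",
    TRUE ~ "UNCHANGED"
  )
  same_dir <- sign(joined$protein_log2fc) == sign(joined$mrna_log2fc)
  joined$mode <- dplyr::case_when(
    !has_p | !has_m ~ "UNDETERMINED",
    p_reg & m_reg & same_dir ~ "CONCORDANT",
    p_reg ~ "POST_TRANSCRIPTIONAL",
    m_reg ~ "TRANSCRIPTIONAL",
    TRUE ~ "CONCORDANT" # both layers quiet
  )
  attr(joined, "contrast") <-
    "regulator-deleted / regulator-present (positive = repressed by regulator)"
  joined
}

#' Partition regulated genes by predicted binding-site class
#'
#' Among regulated genes, reports the fractions carrying a full `AnGGA`
#' site, only the minimal `GGA`, or no predicted site, overall and by
#' regulation direction. Counts are conserved (`FULL + SHORT_ONLY + NONE`
#' equals the regulated total); regulated genes absent from the prediction
#' table are counted as no-site with a warning.
#'
#' @param classes Tibble from [classify_fold_changes()].
#' @param predictions Per-gene tibble with `gene_id`, `site_class` (the
#'   `genes` element of [predict_regulon()]).
#' @return List with `summary` (site_class, n, fraction), `by_direction`,
#'   and `n_regulated`.
#' @export
direct_indirect_partition <- function(classes, predictions) {
  reg <- classes[classes$class != "UNCHANGED", , drop = FALSE]
  if (nrow(reg) == 0) {
    return(list(
      summary = tibble(site_class = character(), n = integer(),
                       fraction = numeric()),
      by_direction = tibble(),
      n_regulated = 0L
    ))
  }
  missing <- setdiff(reg$gene_id, predictions$gene_id)
  if (length(missing) > 0) {
    warn(sprintf("%d regulated gene(s) missing from predictions; counted as no-site",
                 length(missing)))
  }
  reg <- dplyr::left_join(
    reg, dplyr::select(predictions, "gene_id", "site_class"),
    by = "gene_id"
  )
  reg$site_class[is.na(reg$site_class)] <- "NONE"
  lvl <- c("FULL", "SHORT_ONLY", "NONE")
  summary <- reg %>%
    dplyr::count(site_class = factor(.data$site_class, lvl),
                 .drop = FALSE, name = "n") %>%
    dplyr::mutate(site_class = as.character(.data$site_class),
                  fraction = .data$n / sum(.data$n))
  by_direction <- reg %>%
    dplyr::count(.data$class, site_class = factor(.data$site_class, lvl),
                 .drop = FALSE, name = "n")
  list(summary = summary, by_direction = by_direction,
       n_regulated = nrow(reg))
}

#' Tabulate regulated genes by COG category and direction
#'
#' Counts genes per COG functional category and regulation direction.
#' Multi-category genes contribute once to each of their categories (the
#' per-gene direction totals are unaffected); unmapped genes fall into the
#' `"unknown"` bucket.
#'
#' @param classes Tibble from [classify_fold_changes()].
#' @param cog_map Tibble with `gene_id`, `cog` (multiple rows per gene
#'   allowed).
#' @return Tibble `cog` x `class` counts (regulated genes only), with
#'   attribute `counting` describing the multi-assignment convention.
#' @export
cog_tabulate <- function(classes, cog_map) {
  reg <- classes[classes$class != "UNCHANGED", c("gene_id", "class")]
  reg <- dplyr::left_join(reg, cog_map, by = "gene_id",
                          relationship = "many-to-many")
  reg$cog[is.na(reg$cog)] <- "unknown"
  out <- dplyr::count(reg, .data$cog, .data$class, name = "n")
  attr(out, "counting") <-
    "multi-category genes count once per category; direction totals are per gene"
  out
}

#' Summarise significant transcriptional changes
#'
#' Counts genes up- and down-regulated beyond the fold-change threshold at
#' the adjusted-p cutoff, per contrast when a `contrast` column is present.
#'
#' @param mrna Fold-change tibble (`gene_id`, `log2fc`, `padj`, optional
#'   `contrast`).
#' @param fc_threshold Absolute log2 threshold (default 1).
#' @param p_cutoff Adjusted-p cutoff (default 0.05).
#' @return Tibble with (`contrast`,) `direction`, `n`.
#' @export
transcriptome_summary <- function(mrna, fc_threshold = 1, p_cutoff = 0.05) {
  grp <- if ("contrast" %in% names(mrna)) c("contrast") else character(0)
  mrna %>%
    dplyr::mutate(direction = dplyr::case_when(
      .data$log2fc >= fc_threshold & .data$padj <= p_cutoff ~ "up",
      .data$log2fc <= -fc_threshold & .data$padj <= p_cutoff ~ "down",
      TRUE ~ NA_character_
    )) %>%
    dplyr::filter(!is.na(.data$direction)) %>%
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$direction,
                 name = "n") %>%
    tidyr::complete(direction = c("up", "down"), fill = list(n = 0L))
}
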