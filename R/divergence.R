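# Chromosome-vs-plasmid homologue divergence: alignment hygiene and
# Jukes-Cantor distance comparisons between origin classes.

check_alignment <- function(aln) {
  if (!all(c("id", "origin", "seq") %in% names(aln))) {
    abort("alignment needs columns id, origin, seq")
  }
  if (length(unique(nchar(aln$seq))) > 1) {
    abort("alignment rows must have equal length")
  }
  invisible(TRUE)
}

#' Remove majority-gap columns from an alignment
#'
#' Columns whose gap fraction strictly exceeds `max_gap_fraction` (default
#' 0.60, i.e. majority-gap at >60%) are removed; a column at exactly the
#' threshold is retained. The retained columns' original indices are stored
#' in the `column_map` attribute. Idempotent.
#'
#' @param aln Alignment tibble: `id`, `origin`, `seq` (equal-length strings,
#'   gaps as `-`).
#' @param max_gap_fraction Gap-fraction threshold (strict).
#' @return Filtered alignment tibble with attribute `column_map`.
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.60) {
  check_alignment(aln)
  m <- do.call(rbind, strsplit(toupper(aln$seq), "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) abort("all columns removed by the gap filter")
  out <- aln
  out$seq <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  attr(out, "column_map") <- keep
  out
}

#' Collapse nucleotide-identical sequences
#'
#' Keeps one representative per identical sequence. Identical sequences
#' from different origins (chromosome vs plasmid) are not expected; if they
#' occur, both are kept with a warning.
#'
#' @param aln Alignment tibble.
#' @return List with `alignment` (deduplicated tibble) and `manifest`
#'   (per input row: `id`, `kept`, `representative`).
#' @export
dedupe_identical <- function(aln) {
  check_alignment(aln)
  key <- paste(toupper(aln$seq))
  manifest <- tibble(id = aln$id, kept = FALSE, representative = NA_character_)
  keep <- logical(nrow(aln))
  for (k in unique(key)) {
    idx <- which(key == k)
    origins <- unique(aln$origin[idx])
    if (length(origins) > 1) {
      warn(sprintf(
        "identical sequences across origins (%s); keeping one per origin",
        paste(aln$id[idx], collapse = ", ")
      ))
      for (o in origins) {
        i <- idx[aln$origin[idx] == o][1]
        keep[i] <- TRUE
        manifest$representative[idx[aln$origin[idx] == o]] <- aln$id[i]
      }
    } else {
      keep[idx[1]] <- TRUE
      manifest$representative[idx] <- aln$id[idx[1]]
    }
  }
  manifest$kept <- keep
  list(alignment = aln[keep, , drop = FALSE], manifest = manifest)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' p is the mismatch proportion over pairwise-complete sites (positions
#' where neither sequence has a gap or an ambiguity code), and
#' `d = -(3/4) * log(1 - 4p/3)`. At p >= 3/4 the correction is undefined
#' and the pair is flagged saturated.
#'
#' @param seq_i,seq_j Equal-length aligned strings.
#' @return One-row tibble: `p`, `d`, `n_sites`, `saturated`.
#' @examples
#' jc_distance("ACGT", "ACGA")
#' @export
jc_distance <- function(seq_i, seq_j) {
  a <- strsplit(toupper(seq_i), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_j), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) abort("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T", "U") & b %in% c("A", "C", "G", "T", "U")
  if (sum(ok) == 0) abort("no pairwise-complete sites")
  p <- mean(a[ok] != b[ok])
  saturated <- p >= 0.75
  d <- if (saturated) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  tibble(p = p, d = d, n_sites = sum(ok), saturated = saturated)
}

#' Pairwise Jukes-Cantor distance matrix with origin classes
#'
#' Computes all pairwise distances of a labelled alignment and annotates
#' each pair with its comparison class (`chr_chr`, `chr_plasmid`,
#' `plasmid_plasmid`).
#'
#' @param aln Alignment tibble (`id`, `origin` in
#'   \{`chromosome`, `plasmid`\}, `seq`).
#' @param deletion `"pairwise"` (default; each pair uses its own complete
#'   sites) or `"complete"` (columns with any gap/ambiguity are removed
#'   once, before all comparisons).
#' @return Long tibble: `id1`, `id2`, `pair_class`, `p`, `d`, `n_sites`,
#'   `saturated`.
#' @export
jc_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  check_alignment(aln)
  deletion <- match.arg(deletion)
  seqs <- toupper(aln$seq)
  if (deletion == "complete") {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T", "U")))
    if (!any(ok)) abort("no complete columns")
    seqs <- apply(m[, ok, drop = FALSE], 1, paste, collapse = "")
  }
  n <- nrow(aln)
  pair_class <- function(o1, o2) {
    key <- sort(c(o1, o2))
    if (all(key == "chromosome")) "chr_chr"
    else if (all(key == "plasmid")) "plasmid_plasmid"
    else "chr_plasmid"
  }
  combs <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    dplyr::bind_cols(
      tibble(id1 = aln$id[i], id2 = aln$id[j],
             pair_class = pair_class(aln$origin[i], aln$origin[j])),
      jc_distance(seqs[i], seqs[j])
    )
  })
}

#' Compare distance distributions between origin pair classes
#'
#' Wilcoxon rank-sum tests between the three pair-class distance sets,
#' Bonferroni-adjusted over the three comparisons, with medians and effect
#' direction. Pairwise distances sharing sequences are not independent
#' observations; the tests treat them as if they were (as is conventional
#' for this comparison), which is recorded in the method note.
#'
#' @param dists Tibble from [jc_distance_matrix()].
#' @param exact Use the exact Wilcoxon distribution (small, tie-free
#'   samples only); default `FALSE` uses the normal approximation with tie
#'   correction.
#' @return Tibble with one row per class pair: medians, W statistic,
#'   `p_value`, `p_adjusted`, `untestable`.
#' @export
group_distance_comparison <- function(dists, exact = FALSE) {
  dd <- dists[!dists$saturated & !is.na(dists$d), ]
  classes <- list(
    c("chr_chr", "chr_plasmid"),
    c("chr_chr", "plasmid_plasmid"),
    c("chr_plasmid", "plasmid_plasmid")
  )
  res <- purrr::map_dfr(classes, function(cl) {
    x <- dd$d[dd$pair_class == cl[1]]
    y <- dd$d[dd$pair_class == cl[2]]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(class_a = cl[1], class_b = cl[2],
                    median_a = stats::median(x), median_b = stats::median(y),
                    statistic = NA_real_, p_value = NA_real_,
                    untestable = TRUE))
    }
    if (length(unique(c(x, y))) == 1) {
      # fully tied samples: no evidence either way
      return(tibble(class_a = cl[1], class_b = cl[2],
                    median_a = stats::median(x), median_b = stats::median(y),
                    statistic = length(x) * length(y) / 2, p_value = 1,
                    untestable = FALSE))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    tibble(class_a = cl[1], class_b = cl[2],
           median_a = stats::median(x), median_b = stats::median(y),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           untestable = FALSE)
  })
  m <- sum(!res$untestable)
  res$p_adjusted <- pmin(1, res$p_value * max(m, 1))
  res$method <- paste(
    "Wilcoxon rank-sum, Bonferroni over", m, "tests;",
    "pairwise distances treated as independent observations (they are not)"
  )
  res
}
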