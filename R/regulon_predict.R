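#' Extract the motif search window for each gene
#'
#' The search window for a gene is the sense-strand sequence spanning up to
#' `upstream` bases before the start codon plus the first `orf_bp` bases of
#' the ORF (truncated at contig ends and at the ORF end if the ORF is
#' shorter). This is the region in which Rsm/CsrA recognition motifs are
#' considered relevant to translational control.
#'
#' @param genes Tibble with columns `gene_id`, `start`, `end` (1-based,
#'   closed, `start <= end`) and `strand` (`"+"` or `"-"`).
#' @param genome Single contig sequence (character scalar).
#' @param upstream Maximum upstream span in bases (default 500).
#' @param orf_bp Maximum ORF span in bases (default 100).
#' @return Tibble with `gene_id`, `win_start`, `win_end` (genomic, 1-based
#'   closed, always on the forward strand), `strand`, and `window` (the
#'   sense-strand sequence: reverse-complemented for `-` genes).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", start = 601, end = 1400, strand = "+")
#' extract_search_window(genes, paste(rep("ACGT", 500), collapse = ""))
#' @export
extract_search_window <- function(genes, genome, upstream = 500, orf_bp = 100) {
  stopifnot(is.data.frame(genes), length(genome) == 1)
  glen <- nchar(genome)
  if (any(genes$start < 1 | genes$end > glen | genes$start > genes$end)) {
    abort("gene coordinates fall outside the contig")
  }
  purrr::pmap_dfr(
    genes[c("gene_id", "start", "end", "strand")],
    function(gene_id, start, end, strand) {
      if (strand == "+") {
        ws <- max(1L, start - upstream)
        we <- min(end, start + orf_bp - 1L)
        seq <- substr(genome, ws, we)
      } else if (strand == "-") {
        ws <- max(start, end - orf_bp + 1L)
        we <- min(glen, end + upstream)
        seq <- revcomp(substr(genome, ws, we))
      } else {
        abort(sprintf("gene %s: strand must be '+' or '-'", gene_id))
      }
      tibble(
        gene_id = gene_id, win_start = ws, win_end = we,
        strand = strand, window = seq
      )
    }
  )
}

# Probe-sized subsequence of a window, centred on a motif hit, with
# asymmetric shifting at the window boundaries so the probe keeps its design
# length wherever the window allows.
centre_probe <- function(window, hit_start, hit_end, probe_length) {
  n <- nchar(window)
  motif_len <- hit_end - hit_start + 1L
  left <- (probe_length - motif_len) %/% 2L
  ps <- hit_start - left
  pe <- ps + probe_length - 1L
  if (ps < 1L) { pe <- min(n, pe + (1L - ps)); ps <- 1L }
  if (pe > n) { ps <- max(1L, ps - (pe - n)); pe <- n }
  list(start = ps, end = pe, seq = substr(window, ps, pe))
}

#' Predict the direct-binding regulon of an annotated genome
#'
#' For every gene: extracts the search window, scans it for full (`AnGGA`)
#' and minimal (`GGA`) motifs, folds a probe-sized subsequence centred on
#' each hit (mirroring the 30-bp probe design used for binding assays),
#' classifies the motif's structural exposure, and predicts the binding
#' outcome for the wild-type protein. Genes are then labelled by their best
#' available evidence.
#'
#' @inheritParams extract_search_window
#' @param probe_length Length of the folded probe context around each hit
#'   (default 30).
#' @param min_loop Minimum hairpin loop passed to [fold_oligo()].
#' @return A list with two tibbles: `genes` (per gene: `site_class` of
#'   `"FULL"`, `"SHORT_ONLY"` or `"NONE"`; `n_full`, `n_short`;
#'   `apex_anywhere`; `best_exposure`; `direct_candidate`, true when at least
#'   one hit is predicted STRONG) and `hits` (per motif hit: window position,
#'   probe, exposure and predicted binding).
#' @export
predict_regulon <- function(genes, genome, upstream = 500, orf_bp = 100,
                            probe_length = 30, min_loop = 3) {
  windows <- extract_search_window(genes, genome, upstream, orf_bp)

  hits <- purrr::pmap_dfr(
    windows[c("gene_id", "window")],
    function(gene_id, window) {
      found <- scan_motifs(window)
      if (nrow(found) == 0) return(tibble())
      purrr::pmap_dfr(
        found[c("position", "end", "motif_class", "variant")],
        function(position, end, motif_class, variant) {
          pr <- centre_probe(window, position, end, probe_length)
          fold <- fold_oligo(pr$seq, min_loop = min_loop)
          expo <- classify_exposure(fold, position - pr$start + 1L,
                                    end - pr$start + 1L)
          tibble(
            gene_id = gene_id, position = position, end = end,
            motif_class = motif_class, variant = variant,
            probe = pr$seq, exposure = expo,
            binding = predict_binding(motif_class, expo, "WT")
          )
        }
      )
    }
  )

  exposure_rank <- c(APEX = 1, PARTIAL = 2, LINEAR = 3, OCCLUDED = 4)
  per_gene <- windows["gene_id"]
  if (nrow(hits) > 0) {
    agg <- hits %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(
        n_full = sum(.data$motif_class == "FULL"),
        n_short = sum(.data$motif_class == "SHORT"),
        apex_anywhere = any(.data$exposure == "APEX"),
        best_exposure = names(exposure_rank)[min(exposure_rank[.data$exposure])],
        direct_candidate = any(.data$binding == "STRONG"),
        .groups = "drop"
      )
    per_gene <- dplyr::left_join(per_gene, agg, by = "gene_id")
  } else {
    per_gene$n_full <- integer(nrow(per_gene))
    per_gene$n_short <- integer(nrow(per_gene))
    per_gene$apex_anywhere <- logical(nrow(per_gene))
    per_gene$best_exposure <- NA_character_
    per_gene$direct_candidate <- logical(nrow(per_gene))
  }
  per_gene <- per_gene %>%
    dplyr::mutate(
      n_full = dplyr::coalesce(.data$n_full, 0L),
      n_short = dplyr::coalesce(.data$n_short, 0L),
      apex_anywhere = dplyr::coalesce(.data$apex_anywhere, FALSE),
      direct_candidate = dplyr::coalesce(.data$direct_candidate, FALSE),
      site_class = dplyr::case_when(
        n_full > 0 ~ "FULL",
        n_short > 0 ~ "SHORT_ONLY",
        TRUE ~ "NONE"
      )
    )
  list(genes = per_gene, hits = hits)
}

#' Decompose a non-coding RNA into probe-sized segments
#'
#' Tiles a (nc)RNA sequence into segments of approximately the length used
#' for stem-loop binding probes (default 25), folds and scans each segment,
#' and predicts the wild-type binding outcome for its best motif. This
#' mirrors the analysis of regulator-sequestering small RNAs, whose
#' individual stem loops are copied into short oligos.
#'
#' @param sequence Nucleotide string, at least `segment_length` long.
#' @param segment_length Segment size (default 25; must be >= 10).
#' @param overlap Overlap between consecutive tiles (default 0).
#' @param min_loop Minimum hairpin loop passed to [fold_oligo()].
#' @return Tibble with one row per segment: `segment`, `start`, `end`,
#'   `seq`, `n_full`, `n_short`, `motif_class`, `exposure`, `call`.
#' @export
decompose_ncrna <- function(sequence, segment_length = 25, overlap = 0,
                            min_loop = 3) {
  if (segment_length < 10) abort("`segment_length` must be >= 10")
  n <- nchar(sequence)
  if (n < segment_length) abort("sequence shorter than `segment_length`")
  step <- segment_length - overlap
  if (step < 1) abort("`overlap` must be smaller than `segment_length`")
  starts <- seq.int(1L, n - segment_length + 1L, by = step)
  last <- n - segment_length + 1L
  if (utils::tail(starts, 1) < last && (n - (utils::tail(starts, 1) + segment_length - 1L)) > 0) {
    starts <- c(starts, last)
  }
  starts <- unique(starts)

  purrr::imap_dfr(starts, function(st, k) {
    en <- st + segment_length - 1L
    seg <- substr(sequence, st, en)
    fold <- fold_oligo(seg, min_loop = min_loop)
    found <- scan_motifs(seg)
    if (nrow(found) == 0) {
      return(tibble(
        segment = k, start = st, end = en, seq = seg,
        n_full = 0L, n_short = 0L, motif_class = "NONE",
        exposure = if (fold$score == 0) "LINEAR" else NA_character_,
        call = "NONE"
      ))
    }
    calls <- purrr::pmap_chr(
      found[c("position", "end", "motif_class")],
      function(position, end, motif_class) {
        predict_binding(motif_class,
                        classify_exposure(fold, position, end), "WT")
      }
    )
    expos <- purrr::pmap_chr(
      found[c("position", "end")],
      function(position, end) classify_exposure(fold, position, end)
    )
    strength <- c(STRONG = 1, TRANSIENT = 2, NONE = 3)
    best <- which.min(strength[calls])
    tibble(
      segment = k, start = st, end = en, seq = seg,
      n_full = sum(found$motif_class == "FULL"),
      n_short = sum(found$motif_class == "SHORT"),
      motif_class = found$motif_class[best],
      exposure = expos[best],
      call = calls[best]
    )
  })
}
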