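#' Scan a sequence for Rsm/CsrA recognition motifs
#'
#' Finds all occurrences of the full recognition motif `AnGGA` (A, any base,
#' G, G, A) and of the minimal `GGA` core. A `GGA` lying entirely inside a
#' reported full-motif hit is not reported separately, so the two classes are
#' disjoint; overlapping hits of the same class are all reported. The scan is
#' case-insensitive and treats T as U.
#'
#' @param sequence Single nucleotide string.
#' @return Tibble with one row per hit: `position` (1-based start), `end`,
#'   `motif_class` (`"FULL"` or `"SHORT"`), `match` (the matched string, RNA
#'   alphabet) and `variant` (the 5-mer tag for full hits, `"GGA"` otherwise).
#' @examples
#' scan_motifs("UUACGGAUU") # one FULL hit at position 3
#' scan_motifs("GGAGGA")    # two SHORT hits
#' @export
scan_motifs <- function(sequence) {
  stopifnot(length(sequence) == 1)
  check_nucleotides(sequence, "sequence")
  s <- strsplit(as_rna(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)

  full <- integer(0)
  if (n >= 5) {
    idx <- seq_len(n - 4)
    full <- idx[s[idx] == "A" & s[idx + 2] == "G" & s[idx + 3] == "G" & s[idx + 4] == "A"]
  }
  short <- integer(0)
  if (n >= 3) {
    idx <- seq_len(n - 2)
    short <- idx[s[idx] == "G" & s[idx + 1] == "G" & s[idx + 2] == "A"]
    # drop GGA cores contained in a reported full hit
    if (length(full) > 0 && length(short) > 0) {
      contained <- vapply(short, function(p) {
        any(p >= full & (p + 2) <= full + 4)
      }, logical(1))
      short <- short[!contained]
    }
  }

  out <- dplyr::bind_rows(
    tibble(
      position = full, end = full + 4L, motif_class = "FULL",
      match = vapply(full, function(p) paste(s[p:(p + 4)], collapse = ""), character(1))
    ),
    tibble(
      position = short, end = short + 2L, motif_class = "SHORT",
      match = rep("GGA", length(short))
    )
  )
  out$variant <- out$match
  dplyr::arrange(out, .data$position, .data$motif_class)
}

#' Classify how exposed a motif is within a fold
#'
#' Given a folded probe and the coordinates of a motif hit inside it, reports
#' whether the motif sits open at the apex of a hairpin loop (`"APEX"`: every
#' motif base unpaired and all inside a single terminal loop), is fully base
#' paired into a stem (`"OCCLUDED"`), lies in a molecule with no structure at
#' all (`"LINEAR"`), or anything in between (`"PARTIAL"`, e.g. a motif
#' straddling a stem and its loop).
#'
#' @param fold An `rsm_fold` object.
#' @param motif_start,motif_end 1-based motif coordinates within the folded
#'   sequence.
#' @return One of `"APEX"`, `"PARTIAL"`, `"OCCLUDED"`, `"LINEAR"`.
#' @export
classify_exposure <- function(fold, motif_start, motif_end) {
  stopifnot(inherits(fold, "rsm_fold"))
  if (motif_start < 1 || motif_end > fold$n || motif_start > motif_end) {
    abort("motif coordinates out of range of the folded sequence")
  }
  m <- seq.int(motif_start, motif_end)
  if (nrow(fold$pairs) == 0) return("LINEAR")
  paired <- !is.na(fold$partner[m])
  if (all(paired)) return("OCCLUDED")
  if (!any(paired) && nrow(fold$loops) > 0) {
    in_one_loop <- purrr::map_lgl(fold$loops$positions, function(pos) all(m %in% pos))
    if (any(in_one_loop)) return("APEX")
  }
  "PARTIAL"
}

#' Predict the binding outcome for a classified motif
#'
#' Encodes the qualitative binding rules observed by surface plasmon
#' resonance: the regulator binds strongly to a full or minimal motif
#' presented open at a hairpin apex; binding to a motif in a linear
#' (unstructured) context or partially occluded by a stem is transient; a
#' fully occluded motif, or no motif, gives no binding. Substitutions in the
#' conserved RNA-binding surface (H43A, R44A) attenuate binding by one level
#' (STRONG becomes TRANSIENT, TRANSIENT becomes NONE).
#'
#' @param motif_class `"FULL"`, `"SHORT"`, or `"NONE"`.
#' @param exposure One of `"APEX"`, `"PARTIAL"`, `"OCCLUDED"`, `"LINEAR"`.
#' @param variant Protein variant: `"WT"`, `"H43A"`, or `"R44A"`.
#' @return One of `"STRONG"`, `"TRANSIENT"`, `"NONE"`.
#' @export
predict_binding <- function(motif_class, exposure, variant = "WT") {
  motif_class <- match.arg(motif_class, c("FULL", "SHORT", "NONE"))
  exposure <- match.arg(exposure, c("APEX", "PARTIAL", "OCCLUDED", "LINEAR"))
  if (!variant %in% c("WT", "H43A", "R44A")) {
    abort(sprintf("unknown protein variant '%s'", variant))
  }
  call <- if (motif_class == "NONE" || exposure == "OCCLUDED") {
    "NONE"
  } else if (exposure == "APEX") {
    "STRONG"
  } else {
    "TRANSIENT" # LINEAR or PARTIAL presentation of a motif
  }
  if (variant != "WT") {
    call <- c(STRONG = "TRANSIENT", TRANSIENT = "NONE", NONE = "NONE")[[call]]
  }
  call
}
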