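#' Fold a short oligo by maximum base pairing
#'
#' Computes a nested (pseudoknot-free) secondary structure for a short RNA or
#' ssDNA probe by Nussinov-style dynamic programming: the returned structure
#' maximises the number of base pairs under Watson-Crick (A-U, G-C) and,
#' optionally, G-U wobble pairing, subject to a minimum hairpin loop length.
#' This deliberately replaces thermodynamic free-energy minimisation: the
#' binding model only uses folds qualitatively, to ask whether a recognition
#' motif sits open at the apex of a hairpin loop or is occluded in a stem,
#' and a maximum-pairing structure answers that question reproducibly.
#'
#' Among co-optimal structures the traceback is deterministic: a pair closing
#' the current interval is always preferred over leaving the 5' base unpaired
#' or bifurcating, and outermost pairs are assigned first.
#'
#' @param sequence Single nucleotide string (ACGU; T is read as U).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3, the conventional steric minimum).
#' @param allow_gu Allow G-U wobble pairs (default `TRUE`).
#' @return An object of class `rsm_fold`: a list with `sequence` (RNA
#'   alphabet), `n`, `pairs` (tibble with 1-based columns `i`, `j`, `i < j`),
#'   `partner` (integer vector, `NA` where unpaired), `score` (number of
#'   pairs), and `loops` (tibble of terminal/hairpin loops: the closing pair
#'   and the unpaired positions it encloses, as a list-column).
#' @examples
#' fold_oligo("GGGGAAAACCCC")
#' @export
fold_oligo <- function(sequence, min_loop = 3, allow_gu = TRUE) {
  stopifnot(length(sequence) == 1)
  if (min_loop < 3) abort("`min_loop` must be >= 3")
  check_nucleotides(sequence, "oligo")
  rna <- as_rna(sequence)
  s <- strsplit(rna, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n > 200) abort("fold_oligo is intended for short probes (length <= 200)")

  pairable <- pair_matrix(s, allow_gu)
  # E[i, j]: maximum pairs on s[i..j]; zero below the minimal hairpin span.
  E <- matrix(0L, nrow = max(n, 1), ncol = max(n, 1))
  if (n >= min_loop + 2) {
    for (span in (min_loop + 2):n) {
      for (i in seq_len(n - span + 1)) {
        j <- i + span - 1
        best <- E[i + 1, j]                      # i unpaired
        ks <- (i + min_loop + 1):j
        ks <- ks[pairable[i, ks]]
        for (k in ks) {                          # i paired with k
          inner <- if (k - 1 >= i + 1) E[i + 1, k - 1] else 0L
          outer <- if (k + 1 <= j) E[k + 1, j] else 0L
          cand <- inner + outer + 1L
          if (cand > best) best <- cand
        }
        E[i, j] <- best
      }
    }
  }

  partner <- rep(NA_integer_, n)
  if (n >= min_loop + 2 && E[1, n] > 0) {
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      iv <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- iv[1]; j <- iv[2]
      while (i <= j && j - i >= min_loop + 1 && E[i, j] > 0) {
        # Deterministic traceback: prefer pairing the 5' base, outermost
        # partner first, over leaving it unpaired.
        ks <- j:(i + min_loop + 1)
        ks <- ks[pairable[i, ks]]
        paired <- FALSE
        for (k in ks) {
          inner <- if (k - 1 >= i + 1) E[i + 1, k - 1] else 0L
          outer <- if (k + 1 <= j) E[k + 1, j] else 0L
          if (inner + outer + 1L == E[i, j]) {
            partner[i] <- k; partner[k] <- i
            if (k + 1 <= j && outer > 0) stack[[length(stack) + 1]] <- c(k + 1L, j)
            j <- k - 1L; i <- i + 1L
            paired <- TRUE
            break
          }
        }
        if (!paired) i <- i + 1L
      }
    }
  }

  pairs <- tibble(
    i = which(!is.na(partner) & seq_len(n) < partner),
    j = partner[which(!is.na(partner) & seq_len(n) < partner)]
  )
  structure(
    list(
      sequence = rna,
      n = n,
      pairs = pairs,
      partner = partner,
      score = nrow(pairs),
      loops = hairpin_loops(pairs, partner, n)
    ),
    class = "rsm_fold"
  )
}

# Logical n x n matrix: can s[i] pair with s[j]?
pair_matrix <- function(s, allow_gu) {
  valid <- c("AU", "UA", "GC", "CG")
  if (allow_gu) valid <- c(valid, "GU", "UG")
  outer(s, s, function(a, b) paste0(a, b) %in% valid)
}

# Terminal (hairpin) loops: closing pairs with no paired position inside.
hairpin_loops <- function(pairs, partner, n) {
  if (nrow(pairs) == 0) {
    return(tibble(i = integer(), j = integer(), positions = list()))
  }
  keep <- purrr::map_lgl(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    inside <- seq.int(i + 1, j - 1)
    all(is.na(partner[inside]))
  })
  hp <- pairs[keep, , drop = FALSE]
  hp$positions <- purrr::map2(hp$i, hp$j, ~seq.int(.x + 1, .y - 1))
  hp
}

#' Dot-bracket string of a fold
#'
#' @param fold An `rsm_fold` object from [fold_oligo()].
#' @return A string of `(`, `)` and `.` characters.
#' @export
dot_bracket <- function(fold) {
  stopifnot(inherits(fold, "rsm_fold"))
  db <- rep(".", fold$n)
  db[fold$pairs$i] <- "("
  db[fold$pairs$j] <- ")"
  paste(db, collapse = "")
}

#' @export
print.rsm_fold <- function(x, ...) {
  cat("<rsm_fold> ", x$n, " nt, ", x$score, " pairs\n", sep = "")
  cat(" ", x$sequence, "\n ", dot_bracket(x), "\n", sep = "")
  invisible(x)
}
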