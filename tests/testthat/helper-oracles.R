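# Independent oracles for property tests. These deliberately use the
# slowest, most transparent formulation of each quantity and share no code
# with the package implementations they check.

# Maximum number of nested base pairs, by top-down enumeration of every
# admissible pairing of the 5' base (memoised on the interval).
bf_max_pairs <- function(sequence, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  valid <- c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1, j) # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (paste0(s[i], s[k]) %in% valid) {
        best <- max(best, 1L + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    memo[[key]] <- best
    best
  }
  n <- length(s)
  if (n < min_loop + 2) return(0L)
  rec(1L, n)
}

# Validity checks on a returned structure: each pair complementary, loops
# long enough, no position in two pairs, no crossing pairs.
fold_is_valid <- function(fold, min_loop = 3, allow_gu = TRUE) {
  s <- strsplit(fold$sequence, "")[[1]]
  valid <- c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
  p <- fold$pairs
  if (nrow(p) == 0) return(TRUE)
  ok_pair <- all(paste0(s[p$i], s[p$j]) %in% valid)
  ok_loop <- all(p$j - p$i - 1 >= min_loop)
  ok_once <- !anyDuplicated(c(p$i, p$j))
  ok_nested <- TRUE
  if (nrow(p) > 1) {
    for (a in seq_len(nrow(p) - 1)) {
      for (b in (a + 1):nrow(p)) {
        i1 <- p$i[a]; j1 <- p$j[a]; i2 <- p$i[b]; j2 <- p$j[b]
        crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
          (i2 < i1 && i1 < j2 && j2 < j1)
        if (crossing) ok_nested <- FALSE
      }
    }
  }
  ok_pair && ok_loop && ok_once && ok_nested
}

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration:
# the sum of probabilities of all tables (same margins) whose point
# probability does not exceed the observed table's.
bf_fisher_2x2 <- function(tab, tol = 1e-7) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + tol)])
}

# KS D by brute force: sup of the ECDF gap over every pooled jump point.
bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Position-by-position motif scan with no regular expressions.
bf_scan <- function(sequence) {
  s <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1]]
  n <- length(s)
  full <- integer(0)
  for (p in seq_len(max(n - 4, 0))) {
    if (s[p] == "A" && s[p + 2] == "G" && s[p + 3] == "G" && s[p + 4] == "A") {
      full <- c(full, p)
    }
  }
  short <- integer(0)
  for (p in seq_len(max(n - 2, 0))) {
    if (s[p] == "G" && s[p + 1] == "G" && s[p + 2] == "A") {
      inside <- FALSE
      for (f in full) if (p >= f && p + 2 <= f + 4) inside <- TRUE
      if (!inside) short <- c(short, p)
    }
  }
  list(full = full, short = short)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
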