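# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Normalise a nucleotide string to the internal RNA alphabet (ACGU, upper
# case). T is accepted as U throughout: the binding experiments this package
# models used ssDNA as a structural proxy for RNA, so the two letters are
# interchangeable here.
as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

as_dna <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)

# Error on characters outside ACGT/ACGU, reporting offending positions.
check_nucleotides <- function(x, what = "sequence") {
  chars <- strsplit(as_rna(x), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains non-nucleotide characters at positions: %s",
      what, paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

revcomp <- function(x) {
  x <- as_dna(x)
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

# Single sequence of random bases, uniform A/C/G/T (keeps the chance-GGA rate
# analytically computable: 1/64 per position).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(TRUE)
}

# One-row tidy test result, the common currency of the statistics modules.
test_result <- function(statistic_name, statistic, p_value,
                        p_adjusted = NA_real_, method = NA_character_) {
  tibble(
    statistic_name = statistic_name,
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    p_adjusted = as.numeric(p_adjusted),
    method = method
  )
}
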