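# Readers and writers for the plain-text formats the modules exchange.

#' Read an aligned FASTA plus an origin label map
#'
#' @param fasta Path to an aligned FASTA (equal-length rows, gaps `-`).
#' @param labels Optional path to a TSV with columns `id`, `origin`
#'   (chromosome/plasmid); when omitted all rows get origin `"unknown"`.
#' @return Alignment tibble (`id`, `origin`, `seq`) for the divergence
#'   functions.
#' @export
read_alignment_fasta <- function(fasta, labels = NULL) {
  ss <- Biostrings::readBStringSet(fasta)
  aln <- tibble(id = names(ss), origin = "unknown",
                seq = as.character(ss))
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, stringsAsFactors = FALSE)
    aln$origin <- lab$origin[match(aln$id, lab$id)]
    if (anyNA(aln$origin)) abort("label map is missing some alignment ids")
  }
  aln
}

#' Write a genome (or any named set of sequences) to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a gene table as GFF3
#'
#' Minimal GFF3 serialisation of a 1-based closed gene table (the format's
#' native convention).
#'
#' @param genes Tibble with `gene_id`, `start`, `end`, `strand`.
#' @param path Output path.
#' @param seqid Contig name.
#' @export
write_genes_gff3 <- function(genes, path, seqid = "contig1") {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\trsmregulon\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            seqid, genes$start, genes$end, genes$strand, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a fold-change table from TSV
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `padj` (extra columns
#'   such as `replicon` or `contrast` are kept).
#' @return Tibble.
#' @export
read_fold_change_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df))) {
    abort(sprintf("fold-change table needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read a plasmid manifest TSV
#'
#' @param path TSV with columns `plasmid_id`, `family`, `length_bp`,
#'   `mobility` (optional extra columns kept).
#' @return Tibble.
#' @export
read_plasmid_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plasmid_id", "family", "length_bp", "mobility")
  if (!all(need %in% names(df))) {
    abort(sprintf("plasmid manifest needs columns: %s",
                  paste(need, collapse = ", ")))
  }
  as_tibble(df)
}
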