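# Readers/writers for the plain-text formats the pipeline exchanges.
# FASTA goes through Biostrings; BED and TSV are simple tabular files
# (0-based half-open coordinates, per BED convention).

#' Read sequences from FASTA
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  s <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  s <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a BED file
#' @param path BED file (3-6 columns).
#' @return `data.frame` with chrom, start, end and, when present, name,
#'   score, strand. Coordinates 0-based half-open.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cn[seq_len(min(ncol(x), 6L))]
  x
}

#' Write a BED file
#' @param df `data.frame` with at least chrom, start, end.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}
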