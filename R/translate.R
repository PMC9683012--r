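#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six reading frames. Frames +1..+3
#' read the forward strand at offsets 0..2; frames -1..-3 read the reverse
#' complement at offsets 0..2. Codons containing N translate to `X`; stop
#' codons to `*`.
#'
#' @param nt Nucleotide string (ACGTN, case-insensitive).
#' @return A list with one element per frame (named `"+1"`..`"-3"`): each a
#'   list with `frame`, `aa` (translated string) and `offset`.
#' @export
six_frame_translate <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  up <- toupper(nt)
  bad <- unique(strsplit(gsub("[ACGTN]", "", up), "")[[1]])
  if (length(bad)) {
    stop("illegal characters in nucleotide sequence: ",
         paste(bad, collapse = ", "))
  }
  fwd <- Biostrings::DNAString(up)
  rev <- Biostrings::reverseComplement(fwd)
  L <- nchar(up)
  out <- list()
  for (k in 1:3) {
    for (strand in c(1L, -1L)) {
      src <- if (strand > 0) fwd else rev
      n_codon <- (L - (k - 1L)) %/% 3L
      aa <- if (n_codon > 0) {
        as.character(Biostrings::translate(
          Biostrings::subseq(src, start = k, width = 3L * n_codon),
          if.fuzzy.codon = "X", no.init.codon = TRUE))
      } else ""
      fr <- strand * k
      out[[frame_name(fr)]] <- list(frame = fr, aa = aa, offset = k - 1L)
    }
  }
  out[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

frame_name <- function(frame) {
  paste0(ifelse(frame > 0, "+", "-"), abs(frame))
}

#' Map a frame-local amino-acid interval to forward-strand nucleotides
#'
#' @param frame Frame in -3..-1, +1..+3.
#' @param aa_start,aa_end 0-based half-open aa interval within the frame's
#'   translation.
#' @param seq_len Length of the nucleotide sequence.
#' @return `c(start, end)`, 0-based half-open on the forward strand.
#' @export
frame_to_forward <- function(frame, aa_start, aa_end, seq_len) {
  off <- abs(frame) - 1L
  nt_lo <- off + 3L * aa_start
  nt_hi <- off + 3L * aa_end
  if (frame > 0) c(nt_lo, nt_hi) else c(seq_len - nt_hi, seq_len - nt_lo)
}

#' Forward-strand coordinate of one frame-local codon
#'
#' Returns the forward-strand start of the codon at 0-based aa position
#' `aa_pos` in the given frame.
#' @inheritParams frame_to_forward
#' @param aa_pos 0-based position in the frame translation.
#' @return Integer forward-strand 0-based coordinate of the codon start.
#' @export
codon_forward_start <- function(frame, aa_pos, seq_len) {
  frame_to_forward(frame, aa_pos, aa_pos + 1L, seq_len)[1]
}
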