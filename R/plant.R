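# Constructors of annotation test cases with planted, locally unambiguous
# lesions. A case embeds an exact back-translated copy of a random protein
# in random flanking sequence and plants either premature stop codons or a
# single-nucleotide deletion. Lesions are placed so that the disrupted codon
# mismatches the probe (negative matrix score); this makes the planted
# coordinate identifiable from local alignments at codon resolution, which
# is the precision the annotation reports.

#' Construct a case with planted premature stops
#'
#' @param n_aa Probe length (aa).
#' @param n_stops Number of in-frame TAA stops to plant.
#' @param flank Length of random flanking sequence on each side (nt).
#' @param seed Integer seed.
#' @return List: `probe` (aa string), `subject` (nt string), `orf_start`
#'   (0-based nt offset of the reading frame), `stop_positions` (0-based
#'   forward nt coordinates of planted stop codons), `stop_codons`
#'   (1-based codon indices).
#' @export
plant_stop_case <- function(n_aa = 240L, n_stops = 2L, flank = 150L,
                            seed = 1L) {
  with_seed(derive_seed(seed, "stop_case"), {
    orf <- random_orf(n_aa)
    probe <- translate_code(orf)
    codons <- sort(sample(10:(n_aa - 10L), n_stops))
    for (cd in codons) {
      orf[(3L * (cd - 1L) + 1L):(3L * cd)] <- c(4L, 1L, 1L)  # TAA
    }
    fl1 <- sample.int(4L, flank, replace = TRUE)
    fl2 <- sample.int(4L, flank, replace = TRUE)
    subject <- nt_decode(c(fl1, orf, fl2))
    list(probe = probe, subject = subject, orf_start = flank,
         stop_positions = flank + 3L * (codons - 1L), stop_codons = codons)
  })
}

#' Construct a case with a planted single-nucleotide frameshift
#'
#' Deletes one nucleotide inside a codon chosen so that the disrupted codon
#' mismatches the probe residue under the scoring matrix (resampling the
#' position otherwise), keeping the breakpoint locally unambiguous.
#'
#' @param n_aa Probe length (aa).
#' @param flank Flanking length (nt).
#' @param smat A [scoring_matrix()] used for the cleanliness check.
#' @param seed Integer seed.
#' @return List: `probe`, `subject`, `orf_start`, `fs_position` (0-based
#'   forward nt coordinate of the first disrupted codon, the expected
#'   reported breakpoint), `del_codon`.
#' @export
plant_frameshift_case <- function(n_aa = 240L, flank = 150L,
                                  smat = scoring_matrix(), seed = 1L) {
  with_seed(derive_seed(seed, "fs_case"), {
    for (try in 1:50) {
      orf <- random_orf(n_aa)
      probe_chars <- strsplit(translate_code(orf), "")[[1]]
      cd <- sample(30:(n_aa - 30L), 1L)
      cut <- 3L * (cd - 1L) + 1L  # delete the codon's first nucleotide
      mut <- orf[-cut]
      # identifiability at codon resolution requires two mismatches: the
      # disrupted codon read in the original frame, and the junction codon
      # read in the shifted frame (one codon left of the breakpoint), must
      # both score negative against the probe residue they would pair with
      shifted <- mut[(3L * (cd - 1L) + 1L):(3L * cd)]
      s1 <- smat$matrix[probe_chars[cd], translate_code(shifted)]
      junction <- mut[(3L * (cd - 1L)):(3L * (cd - 1L) + 2L)]
      s2 <- smat$matrix[probe_chars[cd], translate_code(junction)]
      if (s1 < 0 && s2 < 0) {
        fl1 <- sample.int(4L, flank, replace = TRUE)
        fl2 <- sample.int(4L, flank, replace = TRUE)
        subject <- nt_decode(c(fl1, mut, fl2))
        return(list(probe = paste(probe_chars, collapse = ""),
                    subject = subject, orf_start = flank,
                    fs_position = flank + 3L * (cd - 1L), del_codon = cd))
      }
    }
    stop("could not place a clean frameshift (try another seed)")
  })
}
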