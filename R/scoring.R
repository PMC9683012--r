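#' Protein scoring scheme for translated searches
#'
#' Wraps a substitution matrix (by default BLOSUM45, the matrix of choice for
#' distant translated homology) with affine gap penalties. The matrix keeps
#' its `*` column so stop codons in translated frames are scored (strongly
#' negatively, -5 against any residue) but never forbidden: in degraded
#' elements in-frame stops are signal, not noise.
#'
#' @param name `"BLOSUM45"`, `"BLOSUM62"`, or `"BLOSUM80"`.
#' @param gap_open,gap_ext Affine gap penalties (first gap residue costs
#'   `gap_open + gap_ext`).
#' @return An object of class `scoring_matrix`: list with `matrix`,
#'   `alphabet`, `gap_open`, `gap_ext`, `name`.
#' @export
scoring_matrix <- function(name = "BLOSUM45", gap_open = 14L, gap_ext = 2L) {
  name <- match.arg(name, c("BLOSUM45", "BLOSUM62", "BLOSUM80"))
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  stopifnot(gap_open >= 0, gap_ext > 0)
  out <- list(matrix = m, alphabet = paste(rownames(m), collapse = ""),
              gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
              name = name)
  class(out) <- "scoring_matrix"
  out
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("scoring_matrix:", x$name, "gap open/ext", x$gap_open, "/",
      x$gap_ext, "\n")
  invisible(x)
}

# encode an aa string as 0-based indices into the matrix alphabet;
# unknown residues map to X
aa_encode <- function(aa, smat) {
  chars <- strsplit(toupper(aa), "")[[1]]
  idx <- match(chars, rownames(smat$matrix))
  idx[is.na(idx)] <- match("X", rownames(smat$matrix))
  idx - 1L
}
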