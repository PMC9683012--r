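#' Merge two multiple alignments by profile-profile alignment
#'
#' Aligns the column profiles of two alignments with global
#' Needleman-Wunsch: the score of pairing column i of A with column j of B
#' is the expected nucleotide substitution score between the two column
#' residue distributions (match `match_score`, mismatch `mismatch_score`,
#' gaps excluded from the profiles). Columns within each input are preserved
#' as units; gap columns are inserted where one profile lacks a counterpart.
#'
#' @param a,b Character matrices (rows = sequences, `-` gaps) with disjoint
#'   row-name sets.
#' @param match_score,mismatch_score Profile scoring.
#' @param gap Linear gap penalty per skipped column.
#' @return Merged character matrix with `nrow(a) + nrow(b)` rows.
#' @export
merge_alignments <- function(a, b, match_score = 2, mismatch_score = -1,
                             gap = 2.5) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) > 0, nrow(b) > 0)
  if (length(intersect(rownames(a), rownames(b)))) {
    stop("sequence id collision between alignments: ",
         paste(intersect(rownames(a), rownames(b)), collapse = ", "))
  }
  pa <- column_profile(a)
  pb <- column_profile(b)
  S <- matrix(mismatch_score, 4, 4)
  diag(S) <- match_score
  score <- t(pa) %*% S %*% pb  # ncol(a) x ncol(b) expected scores
  path <- cpp_nw_profile(score, gap)
  cols_a <- ifelse(path$a == 0, NA_integer_, path$a)
  cols_b <- ifelse(path$b == 0, NA_integer_, path$b)
  out_a <- matrix("-", nrow(a), length(cols_a),
                  dimnames = list(rownames(a), NULL))
  out_b <- matrix("-", nrow(b), length(cols_b),
                  dimnames = list(rownames(b), NULL))
  out_a[, !is.na(cols_a)] <- a[, cols_a[!is.na(cols_a)]]
  out_b[, !is.na(cols_b)] <- b[, cols_b[!is.na(cols_b)]]
  rbind(out_a, out_b)
}

# 4 x ncol matrix of A,C,G,T frequencies per column (gaps/ambiguity excluded;
# all-gap columns get a uniform profile)
column_profile <- function(m) {
  p <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    cnt <- c(sum(x == "A"), sum(x == "C"), sum(x == "G"), sum(x == "T"))
    tot <- sum(cnt)
    if (tot == 0) rep(0.25, 4) else cnt / tot
  }, numeric(4))
  matrix(p, nrow = 4)
}

#' Remove gap-rich alignment columns
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction`. The indices
#' of surviving columns (into the input) are kept in the `"column_map"`
#' attribute for coordinate back-translation.
#'
#' @param aln Character matrix.
#' @param max_gap_fraction Highest tolerated gap fraction in \[0, 1\].
#' @return Trimmed matrix (warns when empty).
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.8) {
  stopifnot(is.matrix(aln), max_gap_fraction >= 0, max_gap_fraction <= 1)
  gf <- colMeans(aln == "-")
  keep <- which(gf <= max_gap_fraction)
  if (!length(keep)) warning("all columns removed by trimming")
  out <- aln[, keep, drop = FALSE]
  attr(out, "column_map") <- keep
  out
}

#' Pairwise p-distances with pairwise deletion
#'
#' Observed proportion of differing nucleotides per pair, comparing only
#' columns where both rows hold an unambiguous A/C/G/T (gaps and IUPAC
#' ambiguity codes are excluded pairwise). Pairs with no comparable site are
#' `NA`; the number of compared sites per pair is returned in the
#' `"comparable_sites"` attribute.
#'
#' @param aln Character matrix (rows = sequences) or named character vector.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_p_distance <- function(aln) {
  m <- as_char_matrix(aln)
  stopifnot(nrow(m) >= 2L)
  codes <- match(toupper(m), c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  cm <- matrix(codes, nrow = nrow(m))
  res <- cpp_pdist(cm)
  d <- res$d
  dimnames(d) <- list(rownames(m), rownames(m))
  dimnames(res$n) <- dimnames(d)
  attr(d, "comparable_sites") <- res$n
  d
}

#' Lower-triangle values of a distance matrix
#' @param d Symmetric matrix from [pairwise_p_distance()].
#' @param drop_na Drop undefined pairs.
#' @return Numeric vector of pairwise values.
#' @export
distance_values <- function(d, drop_na = TRUE) {
  v <- d[lower.tri(d)]
  if (drop_na) v <- v[!is.na(v)]
  v
}
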