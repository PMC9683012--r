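#' Annotate inactivating mutations in a hit group
#'
#' Premature stop codons are read off the aligned subject translations
#' (every `*` inside an HSP), and frameshifts are inferred between adjacent
#' chained HSPs whose reading frames differ. All coordinates are 0-based
#' forward-strand positions of the first nucleotide of the affected codon.
#'
#' When the subject sequence is supplied, the frameshift breakpoint is
#' refined by a codon-resolution scan: candidate breakpoints around the HSP
#' junction are scored as (matrix score of upstream-frame codons before the
#' breakpoint) + (score of downstream-frame codons after it), and the
#' highest-scoring breakpoint wins (leftmost in reading direction on ties).
#' Without the subject, the junction convention is used: the breakpoint is
#' placed at the first codon past the upstream HSP.
#'
#' @param group A `hit_group` from [merge_hits()].
#' @param subject Subject nucleotide string (optional, enables refinement).
#' @param probe Probe protein string (required for refinement).
#' @param smat The [scoring_matrix()] used for the search.
#' @return List with `stops` (`data.frame`: pos, frame, aa_pos) and
#'   `frameshifts` (`data.frame`: pos, from_frame, to_frame).
#' @export
annotate_inactivation <- function(group, subject = NULL, probe = NULL,
                                  smat = scoring_matrix()) {
  stopifnot(inherits(group, "hit_group"))
  hsps <- group$hsps
  n <- if (!is.null(subject)) nchar(subject) else
    max(hsps$send)  # only used for minus-strand codon mapping
  stops <- list()
  for (i in seq_len(nrow(hsps))) {
    saln <- strsplit(hsps$saln[i], "")[[1]]
    star_cols <- which(saln == "*")
    if (!length(star_cols)) next
    nongap <- cumsum(saln != "-")
    for (col in star_cols) {
      aa_pos <- hsps$f_sstart[i] + nongap[col] - 1L
      slen <- if (!is.null(subject)) nchar(subject) else
        subject_len_from_hsp(hsps[i, ])
      stops[[length(stops) + 1L]] <- data.frame(
        pos = codon_forward_start(hsps$frame[i], aa_pos, slen),
        frame = hsps$frame[i], aa_pos = aa_pos)
    }
  }
  shifts <- list()
  if (nrow(hsps) >= 2) {
    frames <- if (!is.null(subject)) six_frame_translate(subject) else NULL
    for (i in seq_len(nrow(hsps) - 1L)) {
      f1 <- hsps$frame[i]; f2 <- hsps$frame[i + 1L]
      if (f1 == f2 || sign(f1) != sign(f2)) next
      pos <- refine_frameshift(hsps[i, ], hsps[i + 1L, ], frames, subject,
                               probe, smat)
      shifts[[length(shifts) + 1L]] <- data.frame(
        pos = pos, from_frame = f1, to_frame = f2)
    }
  }
  list(
    stops = if (length(stops)) do.call(rbind, stops) else
      data.frame(pos = integer(0), frame = integer(0), aa_pos = integer(0)),
    frameshifts = if (length(shifts)) do.call(rbind, shifts) else
      data.frame(pos = integer(0), from_frame = integer(0),
                 to_frame = integer(0))
  )
}

# subject length cannot be recovered from a plus-strand HSP alone; for the
# minus strand the HSPs' forward coordinates already embed it, so any
# consistent value works for relative positions. Refinement paths always
# receive the true subject.
subject_len_from_hsp <- function(h) {
  h$send + 3L * 2L
}

# aligned (probe, subject-codon) pairs of one HSP in reading-strand
# coordinates: rpos = reading-strand nt start of the codon, qi = 1-based
# probe index
hsp_pairs <- function(h) {
  qa <- strsplit(h$qaln, "")[[1]]
  sa <- strsplit(h$saln, "")[[1]]
  qpos <- h$qstart + cumsum(qa != "-")        # 1-based probe index
  spos <- h$f_sstart + cumsum(sa != "-") - 1L  # 0-based frame aa position
  keep <- qa != "-" & sa != "-"
  data.frame(rpos = (abs(h$frame) - 1L) + 3L * spos[keep], qi = qpos[keep])
}

# codon-scan refinement of a frameshift breakpoint between two chained HSPs
# (same strand, different frames); returns the forward-strand start of the
# first codon read in the downstream frame.
#
# Local alignments overshoot frameshift junctions, pairing a few codons with
# the wrong frame, so the probe<->codon correspondence is anchored on pairs
# well outside the junction zone and extrapolated gaplessly toward it; each
# candidate breakpoint is scored as (matrix score of upstream-frame codons
# before it) + (score of downstream-frame codons after it), leftmost maximum
# in reading direction on ties.
refine_frameshift <- function(h1, h2, frames, subject, probe, smat) {
  str <- sign(h1$frame)
  if (is.null(frames) || is.null(probe)) {
    # junction convention: first codon past the upstream HSP
    return(if (str > 0) h1$send else h1$sstart - 3L)
  }
  L <- nchar(subject)
  # reading-strand coordinates r = forward (plus) or L - forward (minus)
  r1_end <- if (str > 0) h1$send else L - h1$sstart
  r1_start <- if (str > 0) h1$sstart else L - h1$send
  r2_start <- if (str > 0) h2$sstart else L - h2$send
  r2_end <- if (str > 0) h2$send else L - h2$sstart
  o1 <- abs(h1$frame) - 1L
  o2 <- abs(h2$frame) - 1L
  aa1 <- frames[[frame_name(h1$frame)]]$aa
  aa2 <- frames[[frame_name(h2$frame)]]$aa
  S <- smat$matrix
  pch <- strsplit(toupper(probe), "")[[1]]
  pch[!pch %in% rownames(S)] <- "X"
  jlo <- min(r1_end, r2_start) - 12L
  jhi <- max(r1_end, r2_start) + 12L
  p1 <- hsp_pairs(h1)
  p2 <- hsp_pairs(h2)
  if (!nrow(p1) || !nrow(p2)) {
    return(if (str > 0) h1$send else h1$sstart - 3L)
  }
  a1 <- p1[p1$rpos <= jlo - 3L, , drop = FALSE]
  a1 <- if (nrow(a1)) a1[nrow(a1), ] else p1[1, ]
  a2 <- p2[p2$rpos >= jhi + 3L, , drop = FALSE]
  a2 <- if (nrow(a2)) a2[1, ] else p2[nrow(p2), ]
  lo <- max(r1_start + 3L, jlo)
  hi <- min(r2_end - 3L, jhi)
  cands <- seq.int(lo + (o1 - lo) %% 3L, hi, by = 3L)
  if (!length(cands)) return(if (str > 0) h1$send else h1$sstart - 3L)
  aa_at <- function(aa, o, x) {
    ai <- (x - o) %/% 3L + 1L
    substr(aa, ai, ai)
  }
  pair_score <- function(x, anchor, aa, o) {
    qi <- anchor$qi + (x - anchor$rpos) %/% 3L
    a <- aa_at(aa, o, x)
    if (qi >= 1L && qi <= length(pch) && nzchar(a) && a %in% rownames(S))
      S[pch[qi], a] else 0
  }
  # cumulative changepoint score over a fixed window spanning every
  # candidate: upstream-frame codons before b plus downstream-frame codons
  # from b on; each codon away from the true breakpoint changes the total
  # by (match - mismatch), so the maximum is sharp
  wlo <- max(r1_start, lo - 15L)
  whi <- min(r2_end - 3L, hi + 15L)
  score_at <- function(b) {
    sc <- 0
    xs <- seq.int(b - 3L, by = -3L, length.out = 64L)
    xs <- xs[xs >= wlo]
    for (x in xs) sc <- sc + pair_score(x, a1, aa1, o1)
    b2 <- b + (o2 - b) %% 3L
    xs <- seq.int(b2, by = 3L, length.out = 64L)
    xs <- xs[xs <= whi]
    for (x in xs) sc <- sc + pair_score(x, a2, aa2, o2)
    sc
  }
  scores <- vapply(cands, score_at, 0)
  b <- cands[which.max(scores)]  # leftmost maximum in reading direction
  if (str > 0) b else L - b - 3L
}
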