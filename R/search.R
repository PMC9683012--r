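#' Translated local-alignment search (protein probe vs nucleotide subject)
#'
#' Searches all six reading frames of `subject` with a protein probe, in the
#' manner of tBLASTn: seed word matches (word size 2) above a neighborhood
#' score threshold are extended ungapped with an X-drop, and promising
#' anchors receive a windowed gapped Smith-Waterman. `mode = "exhaustive"`
#' instead runs a full Smith-Waterman per frame (practical for small
#' inputs; reports the single best local alignment per frame).
#'
#' @param probe Protein string.
#' @param subject Nucleotide string (ACGTN).
#' @param smat A [scoring_matrix()].
#' @param mode `"seeded"` or `"exhaustive"`.
#' @param max_evalue Report HSPs with E-value below this.
#' @param seed_threshold Minimum word score to seed an extension.
#' @param xdrop X-drop for ungapped extension.
#' @param window_pad Initial half-width (aa) of the gapped extension window
#'   around an anchor (grown automatically while the alignment touches the
#'   window edge).
#' @param exhaustive_area In seeded mode, frames whose DP area (probe length
#'   x frame length, aa cells) is at most this bound are searched by full
#'   Smith-Waterman instead: word seeding is a sensitivity heuristic that
#'   only pays off on large subjects, and on small inputs the exact search
#'   is both affordable and guaranteed optimal. Set to 0 to force seeding
#'   everywhere.
#' @param params Karlin-Altschul parameters; default [ka_params()] for
#'   `smat` (cached).
#' @param prep Precomputed [prepare_subject()] object for `subject` (lets a
#'   caller searching many probes against one subject translate and encode
#'   it once).
#' @return `data.frame` of HSPs sorted by decreasing score: frame, raw
#'   score, bit score, E-value, percent identity, query interval (aa,
#'   0-based half-open), subject interval (nt, forward strand, 0-based
#'   half-open), frame-local aa interval, and the aligned strings (`saln`
#'   keeps `*` for stops).
#' @export
local_align_translated <- function(probe, subject, smat = scoring_matrix(),
                                   mode = c("seeded", "exhaustive"),
                                   max_evalue = 10, seed_threshold = 11L,
                                   xdrop = 20L, window_pad = 40L,
                                   exhaustive_area = 250000,
                                   params = ka_params_cached(smat),
                                   prep = NULL) {
  mode <- match.arg(mode)
  if (!nzchar(probe) || !nzchar(subject)) return(empty_hsps())
  if (is.null(prep)) prep <- prepare_subject(subject, smat)
  m <- nchar(probe)
  n <- prep$n
  # raw-score cutoff implied by the E-value threshold
  min_score <- if (is.finite(max_evalue)) {
    max(1L, as.integer(ceiling(
      log(params$K * as.double(m) * as.double(n) / max_evalue) /
        params$lambda)))
  } else 1L
  # anchors must reach half the reporting cutoff before gapped extension:
  # on genomic subjects this prunes the mass of random ungapped segments
  # (whose gapped extensions cannot approach the cutoff anyway) while any
  # reportable alignment almost surely contains such a segment
  gapped_trigger <- max(16L, min(64L, as.integer(ceiling(min_score / 2))))
  gapped_trigger <- min(gapped_trigger, max(1L, min_score))
  pcode <- aa_encode(probe, smat)
  rows <- list()
  for (fi in seq_along(prep$frames)) {
    fr <- prep$frames[[fi]]
    if (!nzchar(fr$aa)) next
    scode <- prep$codes[[fi]]
    use_seeding <- mode == "seeded" &&
      as.double(length(pcode)) * length(scode) > exhaustive_area
    hits <- if (use_seeding) {
      cpp_sw_seeded(pcode, scode, smat$matrix, smat$gap_open, smat$gap_ext,
                    seed_threshold, xdrop, gapped_trigger, window_pad,
                    min_score, smat$alphabet)
    } else {
      h <- cpp_sw_exhaustive(pcode, scode, smat$matrix, smat$gap_open,
                             smat$gap_ext, smat$alphabet)
      if (h$score >= max(1L, min_score)) list(h) else list()
    }
    for (h in hits) {
      iv <- frame_to_forward(fr$frame, h$sstart, h$send, n)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr$frame, score = h$score,
        qstart = h$qstart, qend = h$qend,
        sstart = iv[1], send = iv[2],
        f_sstart = h$sstart, f_send = h$send,
        pident = 100 * h$matches / h$align_len,
        align_len = h$align_len,
        qaln = h$qaln, saln = h$saln,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hsps())
  out <- do.call(rbind, rows)
  ev <- estimate_evalue(out$score, m, n, params)
  out$evalue <- ev$evalue
  out$bit_score <- ev$bit_score
  out <- out[out$evalue <= max_evalue, , drop = FALSE]
  out <- out[order(-out$score, out$sstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hsps <- function() {
  data.frame(frame = integer(0), score = integer(0), qstart = integer(0),
             qend = integer(0), sstart = integer(0), send = integer(0),
             f_sstart = integer(0), f_send = integer(0),
             pident = numeric(0), align_len = integer(0),
             qaln = character(0), saln = character(0),
             evalue = numeric(0), bit_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Translate and encode a subject once for repeated searches
#'
#' @param subject Nucleotide string.
#' @param smat A [scoring_matrix()].
#' @return List with `frames` ([six_frame_translate()] output), `codes`
#'   (encoded translations) and `n` (subject length).
#' @export
prepare_subject <- function(subject, smat = scoring_matrix()) {
  frames <- six_frame_translate(subject)
  list(frames = frames,
       codes = lapply(frames, function(fr) aa_encode(fr$aa, smat)),
       n = nchar(subject))
}

# per-process cache of Karlin-Altschul parameters keyed by matrix + gaps
.ka_cache <- new.env(parent = emptyenv())

#' @rdname local_align_translated
#' @export
ka_params_cached <- function(smat) {
  key <- paste(smat$name, smat$gap_open, smat$gap_ext, sep = "/")
  if (is.null(.ka_cache[[key]])) .ka_cache[[key]] <- ka_params(smat)
  .ka_cache[[key]]
}

#' Chain HSPs of one probe into hit groups
#'
#' HSPs on the same strand are chained when collinear in both query and
#' subject within `max_gap` nt of subject (small overlaps allowed, as arise
#' at frameshift junctions). Opposite strands never chain. Aggregate query
#' cover is computed on the union of the chained query intervals.
#'
#' @param hsps HSP `data.frame` from [local_align_translated()], all for the
#'   same probe and subject.
#' @param probe_len Probe length (aa).
#' @param probe Probe name tag carried into the result.
#' @param max_gap Maximum subject gap (nt) between chained HSPs.
#' @param max_overlap Maximum subject overlap (nt) tolerated when chaining
#'   (local alignments overshoot frameshift junctions by up to tens of
#'   codons).
#' @return List of `hit_group` objects: `probe`, `hsps` (ordered along the
#'   reading direction), `query_cover` (%), `best_evalue`, `strand`.
#' @export
merge_hits <- function(hsps, probe_len, probe = "probe", max_gap = 1000L,
                       max_overlap = 240L) {
  if (!nrow(hsps)) return(list())
  groups <- list()
  for (str in c(1L, -1L)) {
    sub <- hsps[sign(hsps$frame) == str, , drop = FALSE]
    if (!nrow(sub)) next
    # order along the reading direction
    ord <- if (str > 0) order(sub$sstart, sub$qstart)
           else order(-sub$send, sub$qstart)
    sub <- sub[ord, , drop = FALSE]
    open_groups <- list()
    assign_grp <- integer(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      placed <- FALSE
      for (gi in rev(seq_along(open_groups))) {
        j <- open_groups[[gi]]  # index of last member
        gap <- if (str > 0) sub$sstart[i] - sub$send[j]
               else sub$sstart[j] - sub$send[i]
        q_ok <- sub$qstart[i] >= sub$qstart[j] &&
          sub$qend[i] >= sub$qend[j]
        if (gap <= max_gap && gap >= -max_overlap && q_ok) {
          assign_grp[i] <- assign_grp[j]
          open_groups[[gi]] <- i
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        assign_grp[i] <- length(groups) + length(open_groups) + 1L
        open_groups[[length(open_groups) + 1L]] <- i
      }
    }
    for (g in unique(assign_grp)) {
      rows <- sub[assign_grp == g, , drop = FALSE]
      cover <- interval_union_length(rows$qstart, rows$qend) / probe_len * 100
      groups[[length(groups) + 1L]] <- structure(
        list(probe = probe, hsps = rows, query_cover = cover,
             best_evalue = min(rows$evalue), strand = str),
        class = "hit_group")
    }
  }
  # best group first
  groups[order(vapply(groups, function(g) g$best_evalue, 1))]
}

interval_union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] > cur_e) {
      tot <- tot + (cur_e - cur_s); cur_s <- starts[k]; cur_e <- ends[k]
    } else cur_e <- max(cur_e, ends[k])
  }
  tot + (cur_e - cur_s)
}

#' @export
print.hit_group <- function(x, ...) {
  cat("hit_group:", x$probe, "-", nrow(x$hsps), "HSP(s), cover",
      round(x$query_cover, 1), "%, best E", format(x$best_evalue, digits = 3),
      ", strand", ifelse(x$strand > 0, "+", "-"), "\n")
  invisible(x)
}
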