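#' Landmark gene set flanking an integration locus
#'
#' Curated protein sequences of the protein-coding genes immediately
#' upstream and downstream of an integration, in chromosomal order (the
#' last upstream and first downstream gene are innermost, i.e. closest to
#' the integration).
#'
#' @param upstream,downstream Named character vectors of protein sequences,
#'   ordered along the chromosome.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(upstream, downstream) {
  stopifnot(length(upstream) >= 1L, length(downstream) >= 1L,
            !is.null(names(upstream)), !is.null(names(downstream)))
  nm <- c(names(upstream), names(downstream))
  if (anyDuplicated(nm)) stop("landmark names must be unique")
  out <- list(upstream = upstream, downstream = downstream)
  class(out) <- "landmark_set"
  out
}

#' Locate landmark genes on a subject sequence
#'
#' Runs the translated search for every landmark protein and keeps the best
#' hit group per landmark. Absence of a landmark is data, not an error.
#'
#' @param subject Nucleotide string (one taxon's locus or contig).
#' @param landmarks A [landmark_set()].
#' @param smat A [scoring_matrix()].
#' @param max_evalue Landmark detection threshold.
#' @param ... Passed to [local_align_translated()].
#' @return `data.frame`: name, side, found, sstart, send, strand, evalue,
#'   plus attribute `rearranged` (TRUE when located landmarks are out of
#'   the expected chromosomal order).
#' @export
locate_landmarks <- function(subject, landmarks, smat = scoring_matrix(),
                             max_evalue = 1e-3, ...) {
  stopifnot(inherits(landmarks, "landmark_set"))
  all_lm <- c(landmarks$upstream, landmarks$downstream)
  side <- rep(c("upstream", "downstream"),
              c(length(landmarks$upstream), length(landmarks$downstream)))
  rows <- list()
  prep <- if (nzchar(subject)) prepare_subject(subject, smat)
  for (i in seq_along(all_lm)) {
    nm <- names(all_lm)[i]
    found <- FALSE; sstart <- NA_integer_; send <- NA_integer_
    strand <- NA_character_; ev <- NA_real_
    if (nzchar(subject)) {
      hsps <- local_align_translated(all_lm[[i]], subject, smat,
                                     max_evalue = max_evalue, prep = prep,
                                     ...)
      grps <- merge_hits(hsps, nchar(all_lm[[i]]), probe = nm)
      if (length(grps)) {
        g <- grps[[1]]
        found <- TRUE
        sstart <- min(g$hsps$sstart); send <- max(g$hsps$send)
        strand <- if (g$strand > 0) "+" else "-"
        ev <- g$best_evalue
      }
    }
    rows[[i]] <- data.frame(name = nm, side = side[i], found = found,
                            sstart = sstart, send = send, strand = strand,
                            evalue = ev, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  loc <- out[out$found, , drop = FALSE]
  attr(out, "rearranged") <- is.unsorted(loc$sstart, strictly = FALSE) &&
    is.unsorted(rev(loc$sstart), strictly = FALSE)
  out
}

#' Define the orthologous region between innermost landmarks
#'
#' The region spans from the end of the innermost located upstream landmark
#' to the start of the innermost located downstream landmark. With only one
#' side anchored, the region extends from that anchor by
#' `3 * expected_aa + pad` nt towards the missing side. With neither side
#' located the region is ambiguous.
#'
#' @param located Output of [locate_landmarks()].
#' @param seq_len Subject length (nt).
#' @param expected_aa Expected length of the ancestral element's protein
#'   (used for one-sided extension).
#' @param pad Extra padding (nt) added at the region edges.
#' @return An object of class `ortho_region`: `interval` (0-based half-open
#'   or `NULL`), `status` in `"defined"`, `"one_sided"`, `"ambiguous"`,
#'   `rearranged`, `support`.
#' @export
define_ortho_region <- function(located, seq_len, expected_aa = 1053L,
                                pad = 0L) {
  up <- located[located$side == "upstream" & located$found, , drop = FALSE]
  dn <- located[located$side == "downstream" & located$found, , drop = FALSE]
  status <- "defined"; interval <- NULL
  if (nrow(up) && nrow(dn)) {
    lo <- max(up$send); hi <- min(dn$sstart)
    interval <- c(max(0L, lo - pad), min(seq_len, hi + pad))
    if (interval[1] >= interval[2]) interval <- c(lo, lo)  # empty region
  } else if (nrow(up) || nrow(dn)) {
    status <- "one_sided"
    ext <- 3L * expected_aa + pad
    if (nrow(up)) {
      lo <- max(up$send)
      interval <- c(max(0L, lo - pad), min(seq_len, lo + ext))
    } else {
      hi <- min(dn$sstart)
      interval <- c(max(0L, hi - ext), min(seq_len, hi + pad))
    }
  } else {
    status <- "ambiguous"
  }
  structure(list(interval = interval, status = status,
                 rearranged = isTRUE(attr(located, "rearranged")),
                 support = located),
            class = "ortho_region")
}

#' @export
print.ortho_region <- function(x, ...) {
  cat("ortho_region:", x$status)
  if (!is.null(x$interval)) cat(" [", x$interval[1], ",", x$interval[2], ")")
  cat("\n")
  invisible(x)
}

#' Call element presence inside an orthologous region
#'
#' Present requires at least `min_probes` core-protein hit groups with best
#' E-value below `threshold` inside the region. Absent is only called when
#' the region is anchored by landmarks on both sides and was actually
#' searched; an unanchored region yields ambiguous, never absent, so
#' assembly gaps cannot masquerade as loss.
#'
#' @param region An [define_ortho_region()] `ortho_region`.
#' @param subject The taxon's nucleotide sequence.
#' @param probes Named character vector of core protein probes.
#' @param smat A [scoring_matrix()].
#' @param threshold Presence E-value threshold.
#' @param min_probes Probes required for a present call (1 = the minimal
#'   single-marker evidence; 2 = stricter mode).
#' @param ... Passed to [local_align_translated()].
#' @return An object of class `presence_call`: `state` in
#'   `"present"`, `"absent"`, `"ambiguous"`; `hit_groups`; `annotations`;
#'   `arrangement_ok`.
#' @export
call_presence <- function(region, subject, probes, smat = scoring_matrix(),
                          threshold = 1e-5, min_probes = 1L, ...) {
  stopifnot(inherits(region, "ortho_region"))
  if (region$status == "ambiguous" || is.null(region$interval)) {
    return(structure(list(state = "ambiguous", hit_groups = list(),
                          annotations = list(), arrangement_ok = NA,
                          region = region),
                     class = "presence_call"))
  }
  iv <- region$interval
  subseq <- substr(subject, iv[1] + 1L, iv[2])
  groups <- list()
  if (nchar(subseq) >= 3L) {
    prep <- prepare_subject(subseq, smat)
    for (nm in names(probes)) {
      hsps <- local_align_translated(probes[[nm]], subseq, smat,
                                     max_evalue = threshold * 10,
                                     prep = prep, ...)
      g <- merge_hits(hsps, nchar(probes[[nm]]), probe = nm)
      g <- Filter(function(x) x$best_evalue < threshold, g)
      if (length(g)) {
        best <- g[[1]]
        # shift coordinates back to the full subject
        best$hsps$sstart <- best$hsps$sstart + iv[1]
        best$hsps$send <- best$hsps$send + iv[1]
        groups[[nm]] <- best
      }
    }
  }
  state <- if (length(groups) >= min_probes) "present" else {
    if (region$status == "defined") "absent" else "ambiguous"
  }
  ann <- lapply(groups, function(g) {
    g2 <- g
    g2$hsps$sstart <- g2$hsps$sstart - iv[1]
    g2$hsps$send <- g2$hsps$send - iv[1]
    a <- annotate_inactivation(g2, subject = subseq,
                               probe = probes[[g$probe]], smat = smat)
    a$stops$pos <- a$stops$pos + iv[1]
    a$frameshifts$pos <- a$frameshifts$pos + iv[1]
    a
  })
  structure(list(state = state, hit_groups = groups, annotations = ann,
                 arrangement_ok = NA, region = region),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat("presence_call:", x$state, "(", length(x$hit_groups),
      "core-protein hit groups )\n")
  invisible(x)
}

#' Check hit arrangement against the canonical element organization
#'
#' The order of detected core-protein hits along the subject must match the
#' template gene order (allowing missing genes, and allowing the whole
#' element to lie on either strand), and integrase and major capsid hits
#' must be on the same strand. Fewer than two hits are vacuously consistent.
#'
#' @param groups Named list of `hit_group` objects (names = probe names).
#' @param template An [eve_template()].
#' @param int_gene,mcp_gene Names of the integrase and major capsid genes.
#' @return Logical consistency flag.
#' @export
check_arrangement <- function(groups, template = eve_template(),
                              int_gene = "INT", mcp_gene = "MCP") {
  if (length(groups) < 2L) return(TRUE)
  if (all(c(int_gene, mcp_gene) %in% names(groups))) {
    if (groups[[int_gene]]$strand != groups[[mcp_gene]]$strand) return(FALSE)
  }
  mid <- vapply(groups, function(g) {
    (min(g$hsps$sstart) + max(g$hsps$send)) / 2
  }, 1)
  observed <- names(groups)[order(mid)]
  expected <- intersect(template$genes$name, observed)
  identical(observed[observed %in% expected], expected) ||
    identical(rev(observed)[rev(observed) %in% expected], expected)
}

#' Assemble presence calls into a taxa-by-loci matrix
#'
#' @param calls `data.frame` with columns taxon, locus, method, state.
#' @return An object of class `presence_matrix` wrapping the call table.
#' @export
build_presence_matrix <- function(calls) {
  stopifnot(all(c("taxon", "locus", "method", "state") %in% names(calls)),
            nrow(calls) >= 1L,
            all(calls$state %in% c("present", "absent", "ambiguous")))
  key <- paste(calls$taxon, calls$locus, calls$method)
  if (anyDuplicated(key)) {
    stop("duplicate taxon-locus-method call: ", key[anyDuplicated(key)])
  }
  structure(list(calls = calls), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  tab <- table(x$calls$state)
  cat("presence_matrix:", length(unique(x$calls$taxon)), "taxa x",
      length(unique(x$calls$locus)), "loci;",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Matrix view of a presence matrix for one method
#' @param pm A `presence_matrix`.
#' @param method Method name (default: the first).
#' @return Character matrix taxa x loci.
#' @export
presence_states <- function(pm, method = pm$calls$method[1]) {
  sub <- pm$calls[pm$calls$method == method, , drop = FALSE]
  taxa <- sort(unique(sub$taxon)); loci <- sort(unique(sub$locus))
  m <- matrix(NA_character_, length(taxa), length(loci),
              dimnames = list(taxa, loci))
  m[cbind(match(sub$taxon, taxa), match(sub$locus, loci))] <- sub$state
  m
}

#' Compare presence calls between two methods
#'
#' Lists every taxon-locus pair on which the two methods disagree; nothing
#' is reconciled silently.
#'
#' @param pm_a,pm_b `presence_matrix` objects (or the same object holding
#'   two methods).
#' @param method_a,method_b Method names.
#' @return `data.frame` of discordant calls (possibly empty).
#' @export
compare_methods <- function(pm_a, pm_b = pm_a,
                            method_a = unique(pm_a$calls$method)[1],
                            method_b = unique(pm_b$calls$method)[2]) {
  a <- pm_a$calls[pm_a$calls$method == method_a, , drop = FALSE]
  b <- pm_b$calls[pm_b$calls$method == method_b, , drop = FALSE]
  m <- merge(a[, c("taxon", "locus", "state")],
             b[, c("taxon", "locus", "state")],
             by = c("taxon", "locus"), suffixes = c("_a", "_b"))
  m[m$state_a != m$state_b, , drop = FALSE]
}
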