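# Alignment utilities: MAF slicing, stitching, profile merging, trimming,
# p-distances.

# build a small synthetic MAF from an alignment matrix: one block per
# supplied column range, reference = first row
synthetic_maf <- function(aln, breaks) {
  ref <- rownames(aln)[1]
  blocks <- list()
  start <- c(0L, breaks)
  end <- c(breaks, ncol(aln))
  ref_pos <- 0L
  for (k in seq_along(start)) {
    cols <- (start[k] + 1L):end[k]
    rows <- list()
    for (sp in rownames(aln)) {
      txt <- paste(aln[sp, cols], collapse = "")
      size <- nchar(gsub("-", "", txt))
      if (size == 0L && sp != ref) next
      prev <- if (sp == ref) ref_pos else {
        sum(aln[sp, seq_len(start[k])] != "-")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        src = sp, start = prev, size = size, strand = "+",
        src_size = sum(aln[sp, ] != "-"), text = txt,
        stringsAsFactors = FALSE)
    }
    ref_pos <- ref_pos + sum(aln[ref, cols] != "-")
    blocks[[k]] <- do.call(rbind, rows)
  }
  blocks
}

random_gapped_alignment <- function(n = 4, L = 60, gap_frac = 0.15) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  gaps <- matrix(runif(n * L) < gap_frac, n, L)
  gaps[1, ] <- FALSE  # reference row ungapped for clean MAF coordinates
  m[gaps] <- "-"
  rownames(m) <- paste0("sp", seq_len(n))
  m
}

test_that("MAF round-trips through write and read", {
  set.seed(71)
  aln <- random_gapped_alignment()
  blocks <- synthetic_maf(aln, breaks = c(20L, 45L))
  path <- tempfile(fileext = ".maf")
  write_maf(blocks, path)
  back <- read_maf(path)
  expect_equal(length(back), 3L)
  for (k in seq_along(blocks)) {
    expect_equal(back[[k]]$text, blocks[[k]]$text)
    expect_equal(back[[k]]$start, blocks[[k]]$start)
  }
})

test_that("region extraction clips blocks exactly (column-scan oracle)", {
  set.seed(72)
  aln <- random_gapped_alignment(n = 5, L = 80)
  blocks <- synthetic_maf(aln, breaks = c(30L))
  region <- list(chrom = "sp1", start = 15L, end = 50L)
  clipped <- extract_maf_region(blocks, region)
  stitched <- maf_to_fasta(clipped, species = rownames(aln))
  # oracle: brute-force column scan of the underlying alignment
  ref_pos <- cumsum(aln["sp1", ] != "-") - 1L
  keep <- which(ref_pos >= 15L & ref_pos < 50L & aln["sp1", ] != "-")
  oracle <- aln[, min(keep):max(keep), drop = FALSE]
  expect_equal(unname(stitched[rownames(aln), ]), unname(oracle))
  # per-row coordinates recomputed exactly
  for (b in clipped) {
    expect_equal(nchar(gsub("-", "", b$text)), b$size)
  }
})

test_that("regions off the reference or in gaps come back empty", {
  set.seed(73)
  aln <- random_gapped_alignment()
  blocks <- synthetic_maf(aln, breaks = c(30L))
  expect_length(extract_maf_region(blocks,
                                   list(chrom = "nope", start = 0, end = 10)),
                0L)
  expect_length(extract_maf_region(blocks,
                                   list(chrom = "sp1", start = 900,
                                        end = 950)),
                0L)
  # region covering exactly one whole block returns it unchanged
  one <- extract_maf_region(blocks, list(chrom = "sp1", start = 0L,
                                         end = sum(aln[1, 1:30] != "-")))
  expect_equal(one[[1]]$text, blocks[[1]]$text)
})

test_that("stitching pads absent species and rejects overlapping blocks", {
  aln <- rbind(sp1 = strsplit("ACGTACGTAC", "")[[1]],
               sp2 = strsplit("ACG-ACGTAC", "")[[1]])
  blocks <- synthetic_maf(aln, breaks = 5L)
  # drop sp2 from the second block
  blocks[[2]] <- blocks[[2]][blocks[[2]]$src == "sp1", , drop = FALSE]
  m <- maf_to_fasta(blocks, species = c("sp1", "sp2"))
  expect_equal(paste(m["sp2", 6:10], collapse = ""), "-----")
  expect_equal(paste(m["sp1", ], collapse = ""), "ACGTACGTAC")
  # overlapping blocks on the reference are rejected
  bad <- blocks
  bad[[2]]$start[1] <- 2L
  expect_error(maf_to_fasta(bad), "overlap")
})

test_that("merging a renamed copy adds no gap columns", {
  set.seed(74)
  a <- random_gapped_alignment(n = 3, L = 40)
  b <- a
  rownames(b) <- paste0("copy_", rownames(a))
  merged <- merge_alignments(a, b)
  expect_equal(ncol(merged), ncol(a))
  expect_equal(nrow(merged), 6L)
  expect_error(merge_alignments(a, a), "collision")
})

test_that("merged width is bounded by the inputs", {
  set.seed(75)
  a <- random_gapped_alignment(n = 3, L = 10)
  b <- random_gapped_alignment(n = 2, L = 12)
  rownames(b) <- c("x1", "x2")
  merged <- merge_alignments(a, b)
  expect_gte(ncol(merged), 12L)
  expect_lte(ncol(merged), 22L)
  # within-input columns preserved as units: removing gap columns recovers
  # the original rows
  for (sp in rownames(a)) {
    expect_equal(gsub("-", "", paste(merged[sp, ], collapse = "")),
                 gsub("-", "", paste(a[sp, ], collapse = "")))
  }
})

test_that("profile merging matches a naive Needleman-Wunsch oracle", {
  set.seed(76)
  a <- random_gapped_alignment(n = 3, L = 8, gap_frac = 0)
  b <- random_gapped_alignment(n = 3, L = 10, gap_frac = 0)
  rownames(b) <- paste0("y", 1:3)
  merged <- merge_alignments(a, b, match_score = 2, mismatch_score = -1,
                             gap = 2.5)
  # oracle: naive global NW over the same profile score matrix
  prof <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      cnt <- c(sum(m[, j] == "A"), sum(m[, j] == "C"),
               sum(m[, j] == "G"), sum(m[, j] == "T"))
      cnt / max(1, sum(cnt))
    }, numeric(4))
  }
  S <- matrix(-1, 4, 4); diag(S) <- 2
  sc <- t(prof(a)) %*% S %*% prof(b)
  na <- ncol(a); nb <- ncol(b)
  H <- matrix(0, na + 1, nb + 1)
  H[, 1] <- -2.5 * (0:na); H[1, ] <- -2.5 * (0:nb)
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      H[i, j] <- max(H[i - 1, j - 1] + sc[i - 1, j - 1],
                     H[i - 1, j] - 2.5, H[i, j - 1] - 2.5)
    }
  }
  # oracle checks the optimal score; the merged width implies the path cost
  path <- paleoeve:::cpp_nw_profile(sc, 2.5)
  expect_equal(path$score, H[na + 1, nb + 1])
  expect_equal(ncol(merged), length(path$a))
})

test_that("gap-rich columns are trimmed with a column map", {
  aln <- rbind(a = c("A", "A", "A", "A", "-"),
               b = c("C", "C", "C", "-", "-"),
               c = c("G", "G", "-", "-", "-"),
               d = c("T", "-", "-", "-", "-"),
               e = c("A", "A", "A", "A", "-"))
  # gap fractions: 0, .2, .4, .6, 1
  out <- trim_columns(aln, 0.5)
  expect_equal(ncol(out), 3L)
  expect_equal(attr(out, "column_map"), 1:3)
  expect_equal(ncol(trim_columns(aln, 1)), 5L)
  expect_warning(out0 <- trim_columns(aln[, 5, drop = FALSE], 0),
                 "all columns removed")
  expect_equal(ncol(out0), 0L)
})

test_that("p-distances use pairwise deletion and match oracles", {
  expect_equal(pairwise_p_distance(c(x = "ACGT", y = "ACGA"))["x", "y"],
               0.25)
  expect_equal(pairwise_p_distance(c(x = "AC-T", y = "ACGT"))["x", "y"], 0)
  expect_equal(pairwise_p_distance(c(x = "ACNT", y = "ACGT"))["x", "y"], 0)
  # no comparable sites: undefined and flagged
  d0 <- pairwise_p_distance(c(x = "A---", y = "-CGT"))
  expect_true(is.na(d0["x", "y"]))
  expect_equal(attr(d0, "comparable_sites")["x", "y"], 0L)
  # random alignment vs naive double loop and vs ape::dist.dna
  set.seed(77)
  aln <- random_gapped_alignment(n = 10, L = 100)
  d <- pairwise_p_distance(aln)
  expect_equal(unname(d), unname(t(d)), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  naive <- matrix(0, 10, 10)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      ok <- aln[i, ] %in% c("A", "C", "G", "T") &
        aln[j, ] %in% c("A", "C", "G", "T")
      naive[i, j] <- naive[j, i] <- mean(aln[i, ok] != aln[j, ok])
    }
  }
  expect_equal(unname(d), naive, ignore_attr = TRUE)
  ape_d <- as.matrix(ape::dist.dna(ape::as.DNAbin(aln), model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(ape_d[rownames(aln), rownames(aln)]),
               ignore_attr = TRUE)
})
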