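# Minimal MAF (multiple alignment format) support: reading, writing,
# reference-anchored region extraction, and stitching blocks to a FASTA-style
# multiple alignment. No installed package parses MAF, so the format is
# handled here directly (it is line-oriented and simple).

#' Read a MAF file
#'
#' @param path MAF file (uncompressed).
#' @return List of blocks; each block is a `data.frame` with columns
#'   `src`, `start`, `size`, `strand`, `src_size`, `text` (one row per
#'   species, coordinates as in the file: 0-based, start on the given
#'   strand).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) {
      blocks[[length(blocks) + 1L]] <<- do.call(rbind, cur)
      cur <<- list()
    }
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      flush()
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur[[length(cur) + 1L]] <- data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
  }
  flush()
  lapply(blocks, validate_maf_block)
}

validate_maf_block <- function(b) {
  w <- unique(nchar(b$text))
  if (length(w) != 1L) stop("MAF block rows differ in aligned length")
  ungapped <- nchar(gsub("-", "", b$text))
  if (any(ungapped != b$size)) {
    stop("MAF block size field disagrees with ungapped text length")
  }
  rownames(b) <- NULL
  b
}

#' Write MAF blocks
#' @param blocks List of block `data.frame`s (as from [read_maf()]).
#' @param path Output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src, b$start, b$size,
                       b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Extract MAF blocks overlapping a reference region
#'
#' Blocks are clipped to the region in reference coordinates: alignment
#' columns outside the region (per the reference row) are dropped and every
#' row's start/size recomputed exactly (for either strand, removing leading
#' alignment columns advances that row's own-strand start by the number of
#' its non-gap characters removed).
#'
#' @param blocks List of MAF blocks.
#' @param region List/vector with `chrom` (reference src), `start`, `end`
#'   (0-based half-open, forward strand of the reference).
#' @return List of clipped blocks (empty if the region hits nothing).
#' @export
extract_maf_region <- function(blocks, region) {
  out <- list()
  for (b in blocks) {
    ri <- which(b$src == region$chrom)
    if (!length(ri)) next
    ri <- ri[1]
    if (b$strand[ri] != "+") {
      stop("reference row must be on the + strand")
    }
    b_start <- b$start[ri]
    b_end <- b_start + b$size[ri]
    lo <- max(b_start, region$start)
    hi <- min(b_end, region$end)
    if (lo >= hi) next
    ref_chars <- strsplit(b$text[ri], "")[[1]]
    ref_pos <- cumsum(ref_chars != "-") - 1L + b_start  # ref coord per col
    ref_pos[ref_chars == "-"] <- NA_integer_
    keep_cols <- which(!is.na(ref_pos) & ref_pos >= lo & ref_pos < hi)
    cols <- seq.int(min(keep_cols), max(keep_cols))
    out[[length(out) + 1L]] <- clip_block(b, cols)
  }
  out
}

# slice a block to the given alignment columns, recomputing coordinates
clip_block <- function(b, cols) {
  texts <- strsplit(b$text, "")
  nb <- b
  for (r in seq_len(nrow(b))) {
    ch <- texts[[r]]
    lead <- sum(ch[seq_len(min(cols) - 1L)] != "-")
    kept <- ch[cols]
    nb$start[r] <- b$start[r] + lead
    nb$size[r] <- sum(kept != "-")
    nb$text[r] <- paste(kept, collapse = "")
  }
  nb[nb$size > 0 | seq_len(nrow(nb)) == 1L, , drop = FALSE]
}

#' Stitch MAF blocks into one multiple alignment
#'
#' Blocks are ordered along the reference; per-species rows are concatenated
#' block-wise, padding species missing from a block with gaps over that
#' block's width.
#'
#' @param blocks List of MAF blocks sharing the reference species (the
#'   first row of each block).
#' @param species Species (src values) to include; default: all seen.
#' @return Character matrix (species x columns) with `-` gaps.
#' @export
maf_to_fasta <- function(blocks, species = NULL) {
  stopifnot(length(blocks) >= 1L)
  ref <- blocks[[1]]$src[1]
  starts <- vapply(blocks, function(b) b$start[b$src == ref][1], 1)
  ends <- starts + vapply(blocks, function(b) b$size[b$src == ref][1], 1)
  o <- order(starts)
  blocks <- blocks[o]; starts <- starts[o]; ends <- ends[o]
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("blocks overlap on the reference: cannot stitch consistently")
  }
  if (is.null(species)) {
    species <- unique(unlist(lapply(blocks, `[[`, "src")))
  }
  rows <- setNames(rep("", length(species)), species)
  for (b in blocks) {
    w <- nchar(b$text[1])
    pad <- strrep("-", w)
    for (sp in species) {
      i <- which(b$src == sp)
      rows[sp] <- paste0(rows[sp], if (length(i)) b$text[i[1]] else pad)
    }
  }
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- species
  m
}
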