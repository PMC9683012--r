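# Shared fixtures, built in code at load time.

# internal helpers exercised directly by unit tests
edge_table <- paleoeve:::edge_table
descendant_tips <- paleoeve:::descendant_tips
aa_encode <- paleoeve:::aa_encode
nt_decode <- paleoeve:::nt_decode
nt_encode <- paleoeve:::nt_encode
ks_dplus <- paleoeve:::ks_dplus
translate_code <- paleoeve:::translate_code
node_ages_from_phylo <- paleoeve:::node_ages_from_phylo
pruning_loglik_compressed <- paleoeve:::pruning_loglik_compressed

# small calibrated host tree used across module tests
toy_host <- function() {
  build_host_tree("(((A:20,B:20):30,(C:40,D:40):10):40,((E:35,F:35):25,G:60):30);")
}

# the package's default mammal-like tree and carriers
mammal_host <- function() build_host_tree(default_host_newick())

# single-gene element template (a polymerase remnant), the dated marker
polb_template <- function(aa_len = 1053L) {
  eve_template(genes = data.frame(name = "POLB", aa_len = aa_len,
                                  strand = "+", stringsAsFactors = FALSE))
}

# random protein / nucleotide strings
random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reverse complement of a nucleotide string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# exact back-translation of a protein: for each residue pick one codon
# (deterministic: the first codon in the genetic code table)
backtranslate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(unique(gc), function(a) names(gc)[gc == a][1], "")
  paste(tab[strsplit(protein, "")[[1]]], collapse = "")
}

# hand-built HSP table with the columns merge_hits expects
empty_like_hsps <- function(frame, qstart, qend, sstart, send,
                            score = NULL, evalue = NULL) {
  n <- length(frame)
  if (is.null(score)) score <- rep(100L, n)
  if (is.null(evalue)) evalue <- rep(1e-10, n)
  data.frame(frame = frame, score = score, qstart = qstart, qend = qend,
             sstart = sstart, send = send,
             f_sstart = rep(0L, n), f_send = rep(0L, n),
             pident = rep(90, n), align_len = qend - qstart,
             qaln = strrep("A", qend - qstart),
             saln = strrep("A", qend - qstart),
             evalue = evalue, bit_score = rep(50, n),
             stringsAsFactors = FALSE)
}

# naive full Smith-Waterman in R with affine gaps (independent oracle for
# the C++ engines); returns the best score only
sw_score_oracle <- function(probe, subject_aa, smat) {
  S <- smat$matrix
  p <- strsplit(probe, "")[[1]]
  s <- strsplit(subject_aa, "")[[1]]
  p[!p %in% rownames(S)] <- "X"
  s[!s %in% rownames(S)] <- "X"
  m <- length(p); n <- length(s)
  go <- smat$gap_open; ge <- smat$gap_ext
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      FF[i, j] <- max(FF[i - 1, j] - ge, H[i - 1, j] - go - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[p[i - 1], s[j - 1]],
                     E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force likelihood: enumerate all internal-state assignments
enumeration_loglik <- function(tr, aln, model) {
  chars <- do.call(rbind, strsplit(aln, ""))[tr$tip.label, , drop = FALSE]
  codes <- matrix(match(chars, model$states), nrow = nrow(chars))
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  internals <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_along(model$freq)),
                                    length(internals))))
  total <- 0
  for (s in seq_len(ncol(codes))) {
    site <- 0
    for (cat in seq_along(model$cat_rates)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e) {
        prob_matrix(model, tr$edge.length[e], model$cat_rates[cat])
      })
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        stv <- c(codes[, s], grid[g, ])
        p <- model$freq[stv[ntip + 1L]]
        for (e in seq_len(nrow(tr$edge))) {
          p <- p * P[[e]][stv[tr$edge[e, 1]], stv[tr$edge[e, 2]]]
        }
        tot <- tot + p
      }
      site <- site + tot / length(model$cat_rates)
    }
    total <- total + log(site)
  }
  total
}

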