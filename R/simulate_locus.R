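#' Simulate the ancestral locus carrying the element
#'
#' Builds the ancestral (pre-divergence) genomic locus: `landmark_n`
#' protein-coding landmark genes upstream, intergenic spacers, the intact
#' element (per its template, with terminal inverted repeats), more spacers,
#' and `landmark_n` landmark genes downstream. Landmark and element gene ORFs
#' are stop-free at creation. Every feature is annotated with 0-based
#' half-open coordinates.
#'
#' @param config A [sim_config()].
#' @param template An [eve_template()].
#' @param seed Integer seed; the locus is byte-identical on re-run.
#' @param eve_seed Seed for the element's own sequence content (default:
#'   `seed`). Two loci built with different `seed` but the same `eve_seed`
#'   and template share an identical ancestral element in different flanks,
#'   emulating paralogous insertions of one virus.
#' @return An object of class `ancestral_locus`: list with `seq` (integer
#'   nucleotide codes), `anno` (feature `data.frame`: name, type, start, end,
#'   strand), `proteins` (named list of aa strings for landmarks and element
#'   genes), `eve_interval`, `template` and `config`.
#' @export
simulate_ancestral_locus <- function(config, template = eve_template(),
                                     seed, eve_seed = seed) {
  stopifnot(inherits(config, "sim_config"), inherits(template, "eve_template"))
  with_seed(derive_seed(seed, "ancestral_locus"), {
    freq <- config$model$freq
    rand_nt <- function(n) sample.int(4L, n, replace = TRUE, prob = freq)
    pieces <- list(); anno <- list(); proteins <- list()
    pos <- 0L
    add <- function(code, name, type, strand = "+") {
      pieces[[length(pieces) + 1L]] <<- code
      anno[[length(anno) + 1L]] <<- data.frame(
        name = name, type = type, start = pos, end = pos + length(code),
        strand = strand, stringsAsFactors = FALSE)
      pos <<- pos + length(code)
    }
    up <- paste0("LMU", seq_len(config$landmark_n))
    dn <- paste0("LMD", seq_len(config$landmark_n))
    for (g in up) {
      orf <- random_orf(config$landmark_aa)
      proteins[[g]] <- translate_code(orf)
      add(orf, g, "landmark")
      add(rand_nt(config$spacer_len), paste0(g, "_spacer"), "spacer")
    }
    eve_start <- pos
    with_seed(derive_seed(eve_seed, "eve_content"), {
      if (template$tir_len > 0L) {
        tir <- rand_nt(template$tir_len)
        add(tir, "TIR5", "tir")
      }
      add(rand_nt(template$spacer_len), "eve_spacer0", "spacer")
      for (i in seq_len(nrow(template$genes))) {
        g <- template$genes[i, ]
        orf <- random_orf(g$aa_len)
        proteins[[g$name]] <- translate_code(orf)
        if (g$strand == "-") orf <- revcomp_code(orf)
        add(orf, g$name, "eve_gene", g$strand)
        add(rand_nt(template$spacer_len), paste0("eve_spacer", i), "spacer")
      }
      if (template$tir_len > 0L) {
        add(revcomp_code(tir), "TIR3", "tir")
      }
    })
    eve_end <- pos
    for (g in dn) {
      add(rand_nt(config$spacer_len), paste0(g, "_spacer"), "spacer")
      orf <- random_orf(config$landmark_aa)
      proteins[[g]] <- translate_code(orf)
      add(orf, g, "landmark")
    }
    anno <- do.call(rbind, anno)
    anno <- rbind(anno, data.frame(name = "EVE", type = "eve",
                                   start = eve_start, end = eve_end,
                                   strand = "+", stringsAsFactors = FALSE))
    out <- list(seq = unlist(pieces), anno = anno, proteins = proteins,
                eve_interval = c(eve_start, eve_end),
                template = template, config = config)
    class(out) <- "ancestral_locus"
    out
  })
}

# random stop-free ORF of n_aa codons (integer nucleotide codes)
random_orf <- function(n_aa) {
  sense <- sense_codons()
  idx <- sample.int(nrow(sense), n_aa, replace = TRUE)
  as.integer(t(sense[idx, , drop = FALSE]))
}

sense_codons <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      all3 <- as.matrix(expand.grid(1:4, 1:4, 1:4))[, 3:1]
      txt <- apply(all3, 1, function(r) paste(NT_CHARS[r], collapse = ""))
      aa <- as.character(Biostrings::GENETIC_CODE[txt])
      memo <<- all3[aa != "*", , drop = FALSE]
    }
    memo
  }
})

# translate integer-coded nt (frame +1) to an aa string; plain table lookup
# (cheaper than a DNAString round-trip for the simulator's tight loops)
translate_code <- function(code) {
  n <- length(code) %/% 3L
  if (n == 0L) return("")
  m <- matrix(NT_CHARS[code[seq_len(3L * n)]], nrow = 3L)
  codons <- paste0(m[1, ], m[2, ], m[3, ])
  paste(as.character(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Evolve the ancestral locus along a host tree
#'
#' The host locus (flanks) evolves from the root of the host tree; the
#' element evolves only from its insertion age down the subtree of the
#' insertion branch, and is spliced into carrier genomes at the insertion
#' point. Non-carriers receive the flanks with no element (joined flanks).
#' Substitutions follow the configured GTR+Gamma model scaled by
#' `clock_rate` and per-branch lognormal multipliers; indels follow a
#' geometric length distribution.
#'
#' @param tree A [build_host_tree()] `host_tree`.
#' @param ancestral An [simulate_ancestral_locus()] `ancestral_locus`.
#' @param insertion_branch Branch carrying the insertion, as returned by
#'   [branch_above()] (the branch's child node id).
#' @param seed Integer seed.
#' @param element_root_age Optional age (My) of the element's own ancestor:
#'   when given (> insertion age), the element accrues that much extra
#'   pre-insertion evolution on its stem, so two loci sharing an ancestral
#'   element behave as paralogues that split at this age.
#' @return An object of class `eve_simulation`: per-taxon sequences and
#'   coordinate maps, the truth record, and the inputs.
#' @export
evolve_locus <- function(tree, ancestral, insertion_branch, seed,
                         element_root_age = NULL) {
  stopifnot(inherits(tree, "host_tree"),
            inherits(ancestral, "ancestral_locus"))
  config <- ancestral$config
  model <- config$model
  ph <- tree$phylo
  edges <- edge_table(tree)
  if (!insertion_branch %in% edges$child) {
    stop("insertion branch (child node ", insertion_branch,
         ") not found in host tree")
  }
  ei <- ancestral$eve_interval
  eve_len <- ei[2] - ei[1]

  # --- flank overlay: locus minus the element, over the full tree ---------
  keep <- setdiff(seq_along(ancestral$seq), (ei[1] + 1L):ei[2])
  site_scale <- rep(1, length(ancestral$seq))
  for (i in seq_len(nrow(ancestral$anno))) {
    a <- ancestral$anno[i, ]
    if (a$type == "landmark" && a$end > a$start) {
      site_scale[(a$start + 1L):a$end] <- config$landmark_rate_scale
    }
  }
  with_seed(derive_seed(seed, "evolve_flanks"), {
    flank_root <- new_state(ancestral$seq[keep], scale = site_scale[keep],
                            model = model)
    # flank anc coordinates are positions in the ANCESTRAL LOCUS system
    flank_root$anc <- keep - 1L
    mults_f <- draw_branch_mults(nrow(edges), config$branch_sd)
    flank_states <- evolve_tree(edges, ape::Ntip(ph) + 1L, flank_root,
                                model, config$clock_rate, mults_f,
                                config$indel_rate, config$indel_mean_len)
  })

  # --- element overlay: insertion subtree only ----------------------------
  ins_child_age <- unname(tree$ages[insertion_branch])
  ins_parent_age <- edges$parent_age[match(insertion_branch, edges$child)]
  insertion_age <- if (is.null(config$insertion_age)) {
    (ins_child_age + ins_parent_age) / 2
  } else config$insertion_age
  if (insertion_age <= ins_child_age || insertion_age >= ins_parent_age) {
    stop("insertion_age must lie strictly within the insertion branch (",
         ins_child_age, ", ", ins_parent_age, ") My")
  }
  carriers <- descendant_tips(tree, insertion_branch)
  sub_edges <- subtree_edges(edges, insertion_branch)
  stem_top <- if (is.null(element_root_age)) insertion_age else {
    stopifnot(element_root_age > insertion_age)
    element_root_age
  }
  with_seed(derive_seed(seed, "evolve_eve"), {
    # pre-insertion (stem) the element is a functional viral genome: its
    # genes evolve under purifying constraint (landmark-level rate, no
    # indels); neutral decay starts at insertion
    gene_scale <- rep(1, eve_len)
    gene_rows <- ancestral$anno[ancestral$anno$type == "eve_gene", ,
                                drop = FALSE]
    for (i in seq_len(nrow(gene_rows))) {
      gene_scale[(gene_rows$start[i] - ei[1] + 1L):
                   (gene_rows$end[i] - ei[1])] <- config$landmark_rate_scale
    }
    eve_root <- new_state(ancestral$seq[(ei[1] + 1L):ei[2]],
                          scale = gene_scale, model = model)
    eve_root$anc <- ei[1]:(ei[2] - 1L)  # ancestral-locus coordinates
    stem_mult <- draw_branch_mults(1L, config$branch_sd)
    eve_at_insertion <- substitute_state(
      eve_root, model,
      (stem_top - insertion_age) * config$clock_rate * stem_mult)
    eve_at_insertion$scale <- rep(config$eve_rate_scale, eve_len)
    # post-insertion: neutral decay down the carrier subtree, plus the
    # remainder of the insertion branch itself
    post_edges <- rbind(
      data.frame(parent = -1L, child = insertion_branch,
                 parent_age = insertion_age, child_age = ins_child_age,
                 duration = insertion_age - ins_child_age),
      sub_edges)
    mults_e <- draw_branch_mults(nrow(post_edges), config$branch_sd)
    eve_states <- evolve_tree(post_edges, -1L, eve_at_insertion, model,
                              config$clock_rate, mults_e,
                              config$indel_rate, config$indel_mean_len)
  })

  # --- assemble per-taxon genomes -----------------------------------------
  taxa <- tree$taxa
  genomes <- list()
  for (i in seq_along(taxa)) {
    fl <- flank_states[[as.character(i)]]
    if (taxa[i] %in% carriers) {
      ev <- eve_states[[as.character(i)]]
      cut <- splice_index(fl, ei[1])
      genomes[[taxa[i]]] <- list(
        seq = c(fl$seq[seq_len(cut)], ev$seq,
                if (cut < length(fl$seq)) fl$seq[(cut + 1L):length(fl$seq)]),
        anc = c(fl$anc[seq_len(cut)], ev$anc,
                if (cut < length(fl$anc)) fl$anc[(cut + 1L):length(fl$anc)]),
        eve_state = ev, flank_state = fl, eve_cut = cut
      )
    } else {
      genomes[[taxa[i]]] <- list(seq = fl$seq, anc = fl$anc,
                                 eve_state = NULL, flank_state = fl,
                                 eve_cut = NA_integer_)
    }
  }

  truth <- list(
    insertion_branch = insertion_branch,
    insertion_age = insertion_age,
    element_root_age = if (is.null(element_root_age)) insertion_age
                       else element_root_age,
    insertion_age_range = c(ins_child_age, ins_parent_age),
    carrier_mrca_age = if (length(carriers) >= 2)
      mrca_age(tree, carriers) else ins_child_age,
    present = setNames(taxa %in% carriers, taxa),
    lost = setNames(rep(FALSE, length(taxa)), taxa),
    planted_stops = list(), planted_frameshifts = list()
  )
  out <- list(tree = tree, ancestral = ancestral, genomes = genomes,
              truth = truth, seed = seed)
  class(out) <- "eve_simulation"
  out
}

# rows of `edges` inside the clade below `node` (preorder preserved)
subtree_edges <- function(edges, node) {
  keep <- logical(nrow(edges))
  inside <- node
  for (i in seq_len(nrow(edges))) {
    if (edges$parent[i] %in% inside) {
      keep[i] <- TRUE
      inside <- c(inside, edges$child[i])
    }
  }
  edges[keep, , drop = FALSE]
}

# index (1-based, 0 allowed) in a flank state after which ancestral-locus
# coordinate `at` would fall
splice_index <- function(state, at) {
  filled <- state$anc
  na <- is.na(filled)
  if (any(na)) {
    # carry the last seen ancestral coordinate forward over insertions;
    # leading insertions sort before every ancestral coordinate
    last <- cummax(ifelse(na, 0L, seq_along(filled)))
    filled <- ifelse(last == 0L, -1L, state$anc[pmax(last, 1L)])
  }
  sum(filled < at)
}

#' Apply lineage-specific element losses
#'
#' Each carrier taxon independently loses the element with probability
#' `loss_probability`: the element interval is excised from its genome
#' (flanks joined) and the truth record updated.
#'
#' @param sim An [evolve_locus()] `eve_simulation`.
#' @param loss_probability Per-taxon loss probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The modified `eve_simulation`.
#' @export
apply_losses <- function(sim, loss_probability, seed) {
  stopifnot(inherits(sim, "eve_simulation"),
            loss_probability >= 0, loss_probability <= 1)
  if (loss_probability == 0) return(sim)
  carriers <- names(which(sim$truth$present))
  with_seed(derive_seed(seed, "losses"), {
    lost <- carriers[runif(length(carriers)) < loss_probability]
  })
  for (tx in lost) {
    g <- sim$genomes[[tx]]
    fl <- g$flank_state
    sim$genomes[[tx]] <- list(seq = fl$seq, anc = fl$anc, eve_state = NULL,
                              flank_state = fl, eve_cut = NA_integer_)
    sim$truth$present[tx] <- FALSE
    sim$truth$lost[tx] <- TRUE
  }
  sim
}

#' Per-taxon sequence of a simulation as a character string
#' @param sim An `eve_simulation`.
#' @param taxon Tip label.
#' @return Nucleotide string.
#' @export
taxon_sequence <- function(sim, taxon) {
  nt_decode(sim$genomes[[taxon]]$seq)
}

#' Per-taxon feature annotation in tip coordinates
#'
#' Maps every ancestral feature through the taxon's coordinate map.
#' Features wholly deleted in the taxon come back with zero width.
#'
#' @param sim An `eve_simulation`.
#' @param taxon Tip label.
#' @return BED-like `data.frame` (name, type, start, end, strand), 0-based
#'   half-open.
#' @export
taxon_features <- function(sim, taxon) {
  g <- sim$genomes[[taxon]]
  anno <- sim$ancestral$anno
  st <- list(anc = g$anc)
  res <- anno
  for (i in seq_len(nrow(anno))) {
    iv <- map_interval(st, anno$start[i], anno$end[i])
    res$start[i] <- iv[1]; res$end[i] <- iv[2]
  }
  eve_rows <- res$type %in% c("eve", "eve_gene", "tir") |
    grepl("^eve_spacer", res$name)
  if (is.null(g$eve_state)) res <- res[!eve_rows, , drop = FALSE]
  res
}

#' True multiple alignment of a region across taxa
#'
#' Columns are ancestral-locus coordinates in `[start, end)`; deletions show
#' as gaps and post-root insertions are omitted. Taxa lacking the region
#' entirely (non-carriers, for element coordinates) get all-gap rows unless
#' `drop_missing`.
#'
#' @param sim An `eve_simulation`.
#' @param start,end 0-based half-open interval in ancestral coordinates.
#' @param taxa Taxa to include (default all).
#' @param drop_missing Drop all-gap rows.
#' @return Character matrix (taxa x columns) of A/C/G/T/-.
#' @export
true_alignment <- function(sim, start, end, taxa = sim$tree$taxa,
                           drop_missing = FALSE) {
  states <- lapply(taxa, function(tx) {
    g <- sim$genomes[[tx]]
    list(seq = g$seq, anc = g$anc)
  })
  m <- true_alignment_rows(states, start, end)
  rownames(m) <- taxa
  if (drop_missing) m <- m[rowSums(m != "-") > 0, , drop = FALSE]
  m
}

#' Write a simulation to disk in standard formats
#'
#' One FASTA per taxon, per-taxon features in BED (1 file per taxon), the
#' truth table as TSV, and the configuration echo as YAML.
#'
#' @param sim An `eve_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest of written files.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tx in sim$tree$taxa) {
    fa <- file.path(dir, paste0(tx, ".fa"))
    s <- Biostrings::DNAStringSet(setNames(taxon_sequence(sim, tx), tx))
    Biostrings::writeXStringSet(s, fa)
    bed <- file.path(dir, paste0(tx, ".bed"))
    ft <- taxon_features(sim, tx)
    write_bed(data.frame(chrom = tx, start = ft$start, end = ft$end,
                         name = ft$name, score = 0, strand = ft$strand),
              bed)
    files <- c(files, fa, bed)
  }
  tt <- data.frame(taxon = sim$tree$taxa,
                   present = unname(sim$truth$present[sim$tree$taxa]),
                   lost = unname(sim$truth$lost[sim$tree$taxa]))
  truth_file <- file.path(dir, "truth.tsv")
  write.table(tt, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_file <- file.path(dir, "config.yaml")
  yaml::write_yaml(c(config_echo(sim$ancestral$config),
                     list(seed = sim$seed,
                          insertion_age = sim$truth$insertion_age)),
                   cfg_file)
  invisible(c(files, truth_file, cfg_file))
}
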