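#' Build the fixed dating-tree topology for orthologous insertions
#'
#' Orthologous insertions track the host phylogeny, so each locus (insertion)
#' contributes a clade mirroring the host tree restricted to its carrier
#' taxa; with two loci the clades are joined at the root, which represents
#' the common ancestor of the two elements (the paralogue split). Tip labels
#' are `taxon|locus`. Node ages are initialized from host ages within clades.
#'
#' @param host A [build_host_tree()] `host_tree`.
#' @param carriers Named list: one character vector of carrier taxa per
#'   locus (1 or 2 loci).
#' @param root_age_init Initial root age (My) for a two-locus tree.
#' @return List of class `dating_tree`: `phylo` (topology with branch
#'   lengths in My from the initial ages), `ages` (per node), `crown_nodes`
#'   (named: crown node id per locus), `tips_by_locus`.
#' @export
build_dating_tree <- function(host, carriers, root_age_init = NULL) {
  stopifnot(inherits(host, "host_tree"), length(carriers) %in% 1:2,
            !is.null(names(carriers)))
  clades <- list()
  for (locus in names(carriers)) {
    tx <- carriers[[locus]]
    stopifnot(length(tx) >= 2L)
    ph <- ape::keep.tip(host$phylo, tx)
    ph$tip.label <- paste(ph$tip.label, locus, sep = "|")
    clades[[locus]] <- ph
  }
  if (length(clades) == 1L) {
    phylo <- clades[[1]]
  } else {
    crown1 <- max(node_ages_from_phylo(clades[[1]]))
    crown2 <- max(node_ages_from_phylo(clades[[2]]))
    if (is.null(root_age_init)) {
      root_age_init <- 1.5 * max(crown1, crown2)
    }
    stopifnot(root_age_init > max(crown1, crown2))
    t1 <- clades[[1]]; t2 <- clades[[2]]
    t1$root.edge <- root_age_init - crown1
    t2$root.edge <- root_age_init - crown2
    phylo <- ape::bind.tree(t1, t2, position = t1$root.edge)
  }
  ages <- node_ages_from_phylo(phylo)
  ages[seq_len(ape::Ntip(phylo))] <- 0
  crown_nodes <- vapply(names(carriers), function(locus) {
    tips <- paste(carriers[[locus]], locus, sep = "|")
    if (length(tips) == 2L && length(carriers) == 1L) {
      ape::Ntip(phylo) + 1L
    } else {
      as.integer(ape::getMRCA(phylo, tips))
    }
  }, 1L)
  structure(list(phylo = phylo, ages = ages, crown_nodes = crown_nodes,
                 tips_by_locus = lapply(names(carriers), function(l)
                   paste(carriers[[l]], l, sep = "|"))),
            class = "dating_tree")
}

#' @export
print.dating_tree <- function(x, ...) {
  cat("dating_tree:", ape::Ntip(x$phylo), "tips,",
      length(x$crown_nodes), "locus clade(s), root age init",
      format(max(x$ages)), "My\n")
  invisible(x)
}

#' Calibration prior on a clade age
#'
#' A normal prior (TimeTree-style point estimate with uncertainty) on the
#' age of the MRCA of a taxon set.
#'
#' @param taxa Tip labels (in the dating tree) whose MRCA is calibrated.
#' @param mean,sd Normal prior mean and standard deviation (My), `sd > 0`.
#' @return An object of class `calibration`.
#' @export
calibration <- function(taxa, mean, sd) {
  stopifnot(length(taxa) >= 2L, sd > 0, mean > 0)
  structure(list(taxa = taxa, mean = mean, sd = sd), class = "calibration")
}

#' Host-derived calibrations for a dating tree
#'
#' Builds one [calibration()] per requested host clade and locus, with means
#' at the host-tree node ages (the simulation truth, mimicking calibrations
#' taken from a reference timescale).
#'
#' @param host A `host_tree`.
#' @param carriers Named list of carrier taxa per locus (as in
#'   [build_dating_tree()]).
#' @param clades List of host taxon sets to calibrate (each of length >= 2);
#'   defaults to every internal node of the host tree restricted to
#'   carriers.
#' @param sd Calibration standard deviation (My), recycled.
#' @return List of `calibration` objects (clades unresolvable within a
#'   locus's carriers are skipped for that locus).
#' @export
host_calibrations <- function(host, carriers, clades = NULL, sd = 3) {
  if (is.null(clades)) {
    ph <- host$phylo
    clades <- lapply((ape::Ntip(ph) + 1L):(ape::Ntip(ph) + ph$Nnode),
                     function(nd) descendant_tips(host, nd))
  }
  sd <- rep_len(sd, length(clades))
  out <- list()
  for (locus in names(carriers)) {
    for (k in seq_along(clades)) {
      tx <- clades[[k]]
      # only clades wholly within the carriers map onto dating-tree nodes;
      # partial overlaps would mis-assign an older host age to a shallower
      # node
      if (length(tx) < 2L || !all(tx %in% carriers[[locus]])) next
      age <- mrca_age(host, tx)
      out[[length(out) + 1L]] <- calibration(
        paste(tx, locus, sep = "|"), mean = age, sd = sd[k])
    }
  }
  # drop duplicates resolving to the same node set
  keys <- vapply(out, function(cl) paste(sort(cl$taxa), collapse = ","),
                 "")
  out[!duplicated(keys)]
}

#' Minimum insertion age from a presence matrix
#'
#' The age of the MRCA of all taxa called present for a locus is a lower
#' bound on the insertion age under orthology. Ambiguous taxa are excluded;
#' fewer than two carriers leave the age undefined.
#'
#' @param host A `host_tree`.
#' @param pm A [build_presence_matrix()] `presence_matrix`.
#' @param locus Locus name.
#' @param method Method whose calls to use.
#' @return List with `age` (My), `node` (host node id), `carriers`.
#' @export
min_age_from_presence <- function(host, pm, locus,
                                  method = pm$calls$method[1]) {
  calls <- pm$calls[pm$calls$locus == locus & pm$calls$method == method, ,
                    drop = FALSE]
  carriers <- calls$taxon[calls$state == "present"]
  if (length(carriers) < 2L) {
    stop("minimum age undefined: fewer than two taxa carry locus ", locus)
  }
  node <- mrca_node(host, carriers)
  list(age = unname(host$ages[node]), node = node, carriers = carriers)
}

#' Simulate a two-locus dating alignment with known truth
#'
#' Simulates sequence evolution directly on the fixed dating tree implied by
#' a host tree, carriers, and a true root (paralogue-split) age: each locus
#' clade follows host divergence times, the element having entered the host
#' genome on the carriers' stem. Returns the alignment and the generating
#' values.
#'
#' @param host A `host_tree`.
#' @param carriers Named list of carrier taxa per locus.
#' @param root_age True age of the element ancestor (root), My.
#' @param rate True mean substitution rate (subs/site/My).
#' @param n_sites Alignment columns.
#' @param model `subst_model` used to simulate.
#' @param branch_sd Lognormal per-branch rate variation (default 0: the
#'   strict-clock generative model matching the default analysis, so
#'   coverage checks are model-matched).
#' @param seed Integer seed.
#' @return List: `alignment` (named character vector), `dating_tree`,
#'   `truth` (root_age, crown ages, rate).
#' @export
simulate_dating_alignment <- function(host, carriers, root_age = 250,
                                      rate = 0.0027, n_sites = 600L,
                                      model = gtr_model(), branch_sd = 0,
                                      seed = 1L) {
  dt <- build_dating_tree(host, carriers, root_age_init = root_age)
  ph <- dt$phylo
  ages <- dt$ages
  edges <- data.frame(parent = ph$edge[, 1], child = ph$edge[, 2])
  ord <- rev(ape::postorder(ph))
  edges <- edges[ord, ]
  edges$duration <- ages[edges$parent] - ages[edges$child]
  with_seed(derive_seed(seed, "dating_alignment"), {
    root_state <- new_state(sample.int(4L, n_sites, replace = TRUE,
                                       prob = model$freq), model = model)
    mults <- draw_branch_mults(nrow(edges), branch_sd)
    states <- evolve_tree(edges, ape::Ntip(ph) + 1L, root_state, model,
                          rate, mults)
  })
  aln <- vapply(seq_len(ape::Ntip(ph)), function(i) {
    nt_decode(states[[as.character(i)]]$seq)
  }, "")
  names(aln) <- ph$tip.label
  crown_ages <- ages[dt$crown_nodes]
  names(crown_ages) <- names(dt$crown_nodes)
  list(alignment = aln, dating_tree = dt,
       truth = list(root_age = root_age, crown_ages = crown_ages,
                    rate = rate, branch_sd = branch_sd))
}
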