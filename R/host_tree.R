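#' Build a calibrated host species tree
#'
#' Parses a Newick string into a rooted, ultrametric host tree whose internal
#' nodes carry absolute ages in million years (My) before present. Branch
#' lengths in the input are interpreted as durations in My; node ages are
#' recovered as root-to-tip depth differences and validated for
#' ultrametricity (all tips at age 0).
#'
#' @param newick_text A Newick string with branch lengths in My.
#' @param tol Tolerance (My) for the ultrametricity check.
#' @return An object of class `host_tree`: a list with elements `phylo`
#'   (an [ape::read.tree] phylogeny, or `NULL` for a single-taxon tree),
#'   `ages` (numeric vector of node ages indexed by ape node number; tips
#'   are 0), and `taxa` (tip labels).
#' @examples
#' tr <- build_host_tree("((A:102,B:102):70,C:172);")
#' root_age(tr)  # 172
#' @export
build_host_tree <- function(newick_text, tol = 1e-6) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  txt <- trimws(newick_text)
  if (!nzchar(txt)) stop("empty Newick string")
  # single-taxon tree: no parentheses, just a label (ape cannot represent it)
  if (!grepl("[(]", txt)) {
    lab <- sub(";\\s*$", "", txt)
    lab <- sub(":.*$", "", lab)
    if (!nzchar(lab) || grepl("[(),;]", lab)) {
      stop("malformed Newick near: '", txt, "'")
    }
    out <- list(phylo = NULL, ages = numeric(0), taxa = lab)
    class(out) <- "host_tree"
    return(out)
  }
  ph <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(ph)) {
    # locate the first token ape chokes on: report the tail of the string
    # after the last successfully balanced parenthesis
    bal <- cumsum((strsplit(txt, "")[[1]] == "(") - (strsplit(txt, "")[[1]] == ")"))
    bad <- if (any(bal < 0)) which(bal < 0)[1] else nchar(txt)
    stop("malformed Newick near: '",
         substr(txt, max(1, bad - 10), min(nchar(txt), bad + 10)), "'")
  }
  if (is.null(ph$edge.length)) {
    stop("Newick has no branch lengths; node ages cannot be derived")
  }
  ages <- node_ages_from_phylo(ph)
  tip_ages <- ages[seq_len(ape::Ntip(ph))]
  if (max(abs(tip_ages)) > tol) {
    stop("tree is not ultrametric within tolerance ", tol,
         " My (max tip-depth discrepancy ",
         format(max(abs(tip_ages))), " My)")
  }
  ages[seq_len(ape::Ntip(ph))] <- 0
  if (ages[ape::Ntip(ph) + 1L] <= tol) {
    stop("degenerate tree: root age is zero")
  }
  parent_age <- ages[ph$edge[, 1]]
  child_age <- ages[ph$edge[, 2]]
  if (any(child_age >= parent_age + tol) || any(child_age > parent_age)) {
    stop("node ages violate parent > child ordering")
  }
  out <- list(phylo = ph, ages = ages, taxa = ph$tip.label)
  class(out) <- "host_tree"
  out
}

# node ages (depth below root subtracted from root height), indexed by ape
# node number; computed from edge lengths by preorder accumulation
node_ages_from_phylo <- function(ph) {
  n_node <- ape::Ntip(ph) + ph$Nnode
  depth <- rep(NA_real_, n_node)
  root <- ape::Ntip(ph) + 1L
  depth[root] <- 0
  ord <- rev(ape::postorder(ph))  # preorder over edges
  for (e in ord) {
    depth[ph$edge[e, 2]] <- depth[ph$edge[e, 1]] + ph$edge.length[e]
  }
  max(depth, na.rm = TRUE) - depth
}

#' @export
print.host_tree <- function(x, ...) {
  cat("host_tree:", length(x$taxa), "taxa")
  if (!is.null(x$phylo)) cat(", root age", format(root_age(x)), "My")
  cat("\n")
  invisible(x)
}

#' Root age of a host tree
#' @param tree A `host_tree`.
#' @return Age of the root in My (0 for a single-taxon tree).
#' @export
root_age <- function(tree) {
  stopifnot(inherits(tree, "host_tree"))
  if (is.null(tree$phylo)) return(0)
  unname(tree$ages[ape::Ntip(tree$phylo) + 1L])
}

#' Age of the most recent common ancestor of a taxon set
#' @param tree A `host_tree`.
#' @param taxa Character vector of at least two tip labels.
#' @return MRCA age in My.
#' @export
mrca_age <- function(tree, taxa) {
  unname(tree$ages[mrca_node(tree, taxa)])
}

# ape node number of the MRCA of a taxon set
mrca_node <- function(tree, taxa) {
  stopifnot(inherits(tree, "host_tree"), length(taxa) >= 2L)
  miss <- setdiff(taxa, tree$taxa)
  if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "))
  ape::getMRCA(tree$phylo, taxa)
}

#' Identify the branch subtending a clade
#'
#' Branches are identified by their child node. The "stem" branch of a clade
#' is the branch whose child is the clade's MRCA.
#'
#' @param tree A `host_tree`.
#' @param taxa Tip labels delimiting the clade (a single label selects the
#'   terminal branch of that tip).
#' @return Integer node id (the branch's child node).
#' @export
branch_above <- function(tree, taxa) {
  stopifnot(inherits(tree, "host_tree"))
  if (length(taxa) == 1L) {
    id <- match(taxa, tree$taxa)
    if (is.na(id)) stop("taxon not in tree: ", taxa)
    return(id)
  }
  mrca_node(tree, taxa)
}

# tips descending from a node (including the node itself if it is a tip)
descendant_tips <- function(tree, node) {
  ph <- tree$phylo
  ntip <- ape::Ntip(ph)
  if (node <= ntip) return(tree$taxa[node])
  kids <- node
  tips <- integer(0)
  while (length(kids)) {
    ch <- ph$edge[ph$edge[, 1] %in% kids, 2]
    tips <- c(tips, ch[ch <= ntip])
    kids <- ch[ch > ntip]
  }
  tree$taxa[sort(tips)]
}

# edge table in preorder: parent, child, parent age, child age, duration
edge_table <- function(tree) {
  ph <- tree$phylo
  ord <- rev(ape::postorder(ph))
  e <- ph$edge[ord, , drop = FALSE]
  data.frame(
    parent = e[, 1], child = e[, 2],
    parent_age = tree$ages[e[, 1]], child_age = tree$ages[e[, 2]],
    duration = tree$ages[e[, 1]] - tree$ages[e[, 2]]
  )
}
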