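#' Felsenstein pruning log-likelihood
#'
#' Computes the phylogenetic log-likelihood of an alignment on a fixed tree
#' under a reversible substitution model with discrete-gamma rate variation,
#' by postorder pruning with pattern compression and per-node rescaling.
#' Branch lengths are in expected substitutions per site.
#'
#' @param tree An `ape::phylo` with `edge.length` in substitutions/site.
#' @param alignment Character matrix (rows = tips, named) or named character
#'   vector of equal-length sequences. Gaps (`-`) and characters outside the
#'   model alphabet are treated as missing data.
#' @param model A [gtr_model()]-style `subst_model`.
#' @return Log-likelihood (scalar). Non-finite results raise an error.
#' @examples
#' tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
#' pruning_loglik(tr, c(A = "ACGT", B = "ACGT"), jc_model())
#' @export
pruning_loglik <- function(tree, alignment, model) {
  pat <- compress_alignment(alignment, model, tree$tip.label)
  ll <- pruning_loglik_compressed(tree, tree$edge.length, pat, model)
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood (check branch lengths and alignment)")
  }
  ll
}

# fast path used by the MCMC: pattern compression done once up front
pruning_loglik_compressed <- function(tree, elen, pat, model) {
  po <- attr(pat, "postorder")
  if (is.null(po)) po <- ape::postorder(tree)
  cpp_pruning_loglik(pat$tips, pat$weights,
                     tree$edge[po, , drop = FALSE], elen[po],
                     ape::Ntip(tree) + tree$Nnode, ape::Ntip(tree) + 1L,
                     model$V, model$Vinv, model$lambda, model$freq,
                     model$cat_rates)
}

#' Pattern-compress an alignment against a model alphabet
#'
#' @param alignment Character matrix or named character vector.
#' @param model A `subst_model` (supplies the state alphabet).
#' @param tip_order Row order to enforce (tip labels).
#' @return List with `tips` (tips x patterns integer matrix, 0-based state
#'   codes, -1 = missing) and `weights` (pattern counts).
#' @export
compress_alignment <- function(alignment, model, tip_order = NULL) {
  m <- as_char_matrix(alignment)
  if (!is.null(tip_order)) {
    miss <- setdiff(tip_order, rownames(m))
    if (length(miss)) stop("alignment missing tips: ",
                           paste(miss, collapse = ", "))
    m <- m[tip_order, , drop = FALSE]
  }
  codes <- match(toupper(m), model$states)
  codes[is.na(codes)] <- 0L
  cm <- matrix(codes - 1L, nrow = nrow(m))
  key <- apply(cm, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(uk, key)
  tips <- cm[, idx, drop = FALSE]
  weights <- as.numeric(table(key)[uk])
  out <- list(tips = tips, weights = weights)
  out
}

as_char_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    stopifnot(!is.null(rownames(alignment)))
    return(alignment)
  }
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  m
}
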