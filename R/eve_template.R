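#' Template of the ancestral endogenous viral element
#'
#' Describes the gene content and layout of the intact ancestral element used
#' by the simulator: an ordered set of core protein-coding genes flanked by
#' terminal inverted repeats (TIRs), separated by short intergenic spacers.
#' The default gene set is the nine core proteins conserved across vertebrate
#' *Maverick*/Polinton elements, all on the forward strand: the
#' protein-primed family-B DNA polymerase (POLB), the retroviral-like
#' integrase (INT), four proteins of unknown function (PM, PW, PZ), the DNA
#' packaging ATPase, the adenoviral-like protease (PRO), and the minor and
#' major capsid proteins (mCP, MCP). POLB defaults to 1,053 aa, the length of
#' the intact reference element's polymerase.
#'
#' @param genes `data.frame` with columns `name`, `aa_len`, `strand`.
#' @param tir_len TIR length in nt (0 omits TIRs).
#' @param spacer_len Intergenic spacer length within the element, nt.
#' @return An object of class `eve_template`.
#' @export
eve_template <- function(genes = default_eve_genes(),
                         tir_len = 400L, spacer_len = 100L) {
  stopifnot(is.data.frame(genes),
            all(c("name", "aa_len", "strand") %in% names(genes)),
            !anyDuplicated(genes$name), all(genes$aa_len >= 10),
            all(genes$strand %in% c("+", "-")),
            tir_len >= 0, spacer_len >= 0)
  out <- list(genes = genes, tir_len = as.integer(tir_len),
              spacer_len = as.integer(spacer_len))
  class(out) <- "eve_template"
  out
}

#' @rdname eve_template
#' @export
default_eve_genes <- function() {
  data.frame(
    name = c("POLB", "INT", "PM", "PW", "PZ", "ATPase", "PRO", "mCP", "MCP"),
    aa_len = c(1053L, 380L, 250L, 220L, 260L, 300L, 180L, 300L, 550L),
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' @export
print.eve_template <- function(x, ...) {
  cat("eve_template:", nrow(x$genes), "genes (",
      paste(x$genes$name, collapse = " > "), "), TIR", x$tir_len, "nt\n")
  invisible(x)
}

# total element length in nt
template_length <- function(template) {
  ng <- nrow(template$genes)
  2L * template$tir_len + sum(3L * template$genes$aa_len) +
    (ng + 1L) * template$spacer_len
}
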