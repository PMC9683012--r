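#' Karlin-Altschul parameters for a scoring scheme
#'
#' Solves the Karlin-Altschul equation
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for the ungapped decay
#' parameter lambda over the 20 standard residues under the Robinson-Robinson
#' background, by bisection/Brent root finding. Gapped statistics are outside
#' the ungapped theory, so the gapped regime uses configurable constants:
#' by default lambda is the ungapped solution scaled by 0.9 and K is a fixed
#' constant of typical magnitude. Every E-value produced downstream is
#' labelled with the regime used.
#'
#' @param smat A [scoring_matrix()].
#' @param freq_query,freq_subject Residue background frequencies (named,
#'   20 standard residues); defaults to Robinson-Robinson.
#' @param gapped Use the gapped regime constants.
#' @param K Karlin-Altschul K (configurable constant; exact computation of
#'   the ungapped lattice series is not attempted).
#' @return List with `lambda`, `K`, `regime`.
#' @export
ka_params <- function(smat, freq_query = robinson_frequencies(),
                      freq_subject = robinson_frequencies(),
                      gapped = TRUE, K = if (gapped) 0.05 else 0.3) {
  lam <- karlin_lambda(smat, freq_query, freq_subject)
  list(lambda = if (gapped) 0.9 * lam else lam, K = K,
       regime = if (gapped) "gapped" else "ungapped")
}

#' @rdname ka_params
#' @export
karlin_lambda <- function(smat, freq_query = robinson_frequencies(),
                          freq_subject = robinson_frequencies()) {
  res <- names(freq_query)
  S <- smat$matrix[res, res]
  p <- as.numeric(freq_query) / sum(freq_query)
  q <- as.numeric(freq_subject) / sum(freq_subject)
  pq <- outer(p, q)
  expected <- sum(pq * S)
  if (expected >= 0) {
    stop("matrix unusable for local-alignment statistics: expected score ",
         "per aligned pair is non-negative (", format(expected), ")")
  }
  if (max(S) <= 0) {
    stop("matrix unusable: no positive scores")
  }
  f <- function(lam) sum(pq * exp(lam * S)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1e-8, hi), tol = 1e-12)$root
}

#' E-value and bit score of a raw alignment score
#'
#' Karlin-Altschul statistics: `E = K * m * n * exp(-lambda * S)` and
#' `bit = (lambda * S - ln K) / ln 2`.
#'
#' @param score Raw alignment score(s).
#' @param m Query length (aa).
#' @param n Subject search-space length (nt for translated searches).
#' @param params A [ka_params()] list.
#' @return `data.frame` with `evalue` and `bit_score`.
#' @export
estimate_evalue <- function(score, m, n, params) {
  stopifnot(m > 0, n > 0)
  ev <- params$K * as.double(m) * as.double(n) *
    exp(-params$lambda * score)
  bits <- (params$lambda * score - log(params$K)) / log(2)
  data.frame(evalue = ev, bit_score = bits)
}

#' Robinson-Robinson amino-acid background frequencies
#' @return Named numeric vector over the 20 standard residues.
#' @export
robinson_frequencies <- function() {
  c(A = 0.078047, R = 0.051290, N = 0.044873, D = 0.053641, C = 0.019246,
    Q = 0.042644, E = 0.062949, G = 0.073772, H = 0.021992, I = 0.051420,
    L = 0.090191, K = 0.057438, M = 0.022425, F = 0.038556, P = 0.052028,
    S = 0.071198, T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
}
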