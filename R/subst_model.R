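#' General time-reversible substitution model with discrete-gamma rates
#'
#' Constructs a GTR+Gamma nucleotide model (or, via [empirical_model()], any
#' reversible k-state model) normalized to one expected substitution per site
#' per unit branch length. Among-site rate variation uses Yang's discrete
#' gamma with `ncat` equal-probability categories whose rates are the
#' category means (mean 1 overall).
#'
#' @param exch Exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (all > 0; the scale is arbitrary).
#' @param freq Stationary base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape; `Inf` disables rate variation.
#' @param ncat Number of discrete gamma categories.
#' @return An object of class `subst_model` holding the rate matrix, its
#'   eigendecomposition, stationary frequencies and category rates.
#' @examples
#' m <- gtr_model()            # mammal-like defaults
#' j <- jc_model()             # Jukes-Cantor special case
#' @export
gtr_model <- function(exch = c(AC = 0.75, AG = 2.8, AT = 0.6,
                               CG = 0.9, CT = 2.8, GT = 1.0),
                      freq = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295),
                      alpha = 1, ncat = 4L) {
  stopifnot(length(exch) == 6L, all(exch > 0), length(freq) == 4L)
  R <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  R[upper.tri(R)] <- exch[c(1, 2, 4, 3, 5, 6)]  # column-major upper triangle
  R <- R + t(R)
  out <- empirical_model(R, freq, alpha = alpha, ncat = ncat, label = "GTR")
  out$exch <- setNames(as.numeric(exch),
                       c("AC", "AG", "AT", "CG", "CT", "GT"))
  out
}

#' Jukes-Cantor model (equal rates and frequencies)
#' @param alpha,ncat Gamma shape and category count (default: no variation).
#' @return A `subst_model`.
#' @export
jc_model <- function(alpha = Inf, ncat = 1L) {
  m <- gtr_model(exch = rep(1, 6), freq = rep(0.25, 4),
                 alpha = alpha, ncat = ncat)
  m$label <- "JC"
  m
}

#' Reversible substitution model from an exchangeability matrix
#'
#' Builds a k-state reversible model Q\[i,j\] = r\[i,j\] * freq\[j\],
#' normalized to one expected substitution per site per unit time. Use this
#' for amino-acid models by supplying a published 20x20 exchangeability
#' matrix and its frequencies.
#'
#' @param exch_matrix Symmetric nonnegative k x k matrix with zero diagonal
#'   (dimnames give the state alphabet).
#' @param freq Stationary frequencies, length k.
#' @param alpha,ncat Discrete-gamma shape and category count.
#' @param label Model name tag.
#' @return A `subst_model`.
#' @export
empirical_model <- function(exch_matrix, freq, alpha = Inf, ncat = 1L,
                            label = "empirical") {
  k <- length(freq)
  stopifnot(is.matrix(exch_matrix), nrow(exch_matrix) == k,
            ncol(exch_matrix) == k,
            max(abs(exch_matrix - t(exch_matrix))) < 1e-10,
            all(freq > 0), abs(sum(freq) - 1) < 1e-8,
            is.finite(alpha) || ncat == 1L || alpha > 0)
  if (is.finite(alpha) && alpha <= 0) stop("gamma shape must be positive")
  freq <- freq / sum(freq)
  Q <- exch_matrix %*% diag(freq)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q <- Q / scale
  # reversible Q: symmetrize with pi^(1/2) for a stable eigendecomposition
  sq <- sqrt(freq)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / sq) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sq)
  states <- rownames(exch_matrix)
  if (is.null(states)) states <- as.character(seq_len(k))
  out <- list(Q = Q, V = V, Vinv = Vinv, lambda = eig$values,
              freq = freq, alpha = alpha, ncat = as.integer(ncat),
              cat_rates = gamma_category_rates(alpha, ncat),
              states = states, label = label)
  class(out) <- "subst_model"
  out
}

#' @export
print.subst_model <- function(x, ...) {
  cat("subst_model:", x$label, "(", length(x$freq), "states ),",
      x$ncat, "rate categories, alpha =", x$alpha, "\n")
  invisible(x)
}

# mean rates of ncat equal-probability discrete gamma bins (overall mean 1)
gamma_category_rates <- function(alpha, ncat) {
  ncat <- as.integer(ncat)
  if (ncat == 1L || !is.finite(alpha)) return(rep(1, ncat))
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha,
                     rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- ncat * diff(p)
  r / mean(r) * 1  # guard rounding; mean is 1 by construction
}

#' Transition probability matrix
#'
#' @param model A `subst_model`.
#' @param t Branch length in expected substitutions per site (already scaled
#'   by any clock rate).
#' @param rate Site-rate multiplier (e.g. a gamma category rate).
#' @return k x k row-stochastic matrix P(t).
#' @export
prob_matrix <- function(model, t, rate = 1) {
  P <- model$V %*% (exp(model$lambda * t * rate) * model$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
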