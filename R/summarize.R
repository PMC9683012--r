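#' Shortest 95% highest-posterior-density interval
#'
#' The shortest contiguous interval containing at least `prob` of the
#' samples (sorted-window method). By construction the reported interval
#' contains >= `prob` of the samples.
#'
#' @param x Numeric samples.
#' @param prob Target mass.
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(x[1], x[1]))
  k <- ceiling(prob * n)
  k <- min(max(k, 1L), n)
  if (k == n) return(c(x[1], x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))`, summing sample autocorrelations from lag 1
#' until the first non-positive value (initial positive sequence
#' truncation).
#'
#' @param x Numeric samples.
#' @return Effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 3L || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 10L * ceiling(log10(n)) * 10L),
             plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  out <- n / (1 + 2 * sum(rho))
  min(max(out, 1), n)
}

#' Summarize a posterior trace
#'
#' Per-column posterior mean, median, shortest 95% HPD, ESS and Monte-Carlo
#' standard error (sd/sqrt(ESS)), after discarding burn-in.
#'
#' @param trace A [mcmc_run()] `posterior_trace`, or a numeric matrix.
#' @param burnin Fraction of samples to discard.
#' @param prob HPD mass.
#' @return `data.frame`, one row per parameter.
#' @export
summarize_trace <- function(trace, burnin = 0.25, prob = 0.95) {
  m <- if (inherits(trace, "posterior_trace")) trace$samples else trace
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  keep <- seq.int(floor(nrow(m) * burnin) + 1L, nrow(m))
  if (length(keep) < 2L) stop("fewer than 2 post-burn-in samples")
  m <- m[keep, , drop = FALSE]
  rows <- lapply(colnames(m), function(cn) {
    x <- m[, cn]
    h <- hpd_interval(x, prob)
    e <- ess(x)
    data.frame(parameter = cn, mean = mean(x), median = median(x),
               hpd_lower = h[1], hpd_upper = h[2], ess = e,
               mcse = sd(x) / sqrt(e), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Node-age summary for the loci of a dating run
#'
#' Convenience extraction of the root and per-locus crown ("minimum
#' insertion age") rows from a posterior trace, in the layout of a dating
#' results table: node, mean, median, 95% HPD.
#'
#' @param trace A `posterior_trace` from [mcmc_run()].
#' @param burnin Burn-in fraction.
#' @return `data.frame` with one row per node of interest.
#' @export
node_age_summary <- function(trace, burnin = 0.25) {
  s <- summarize_trace(trace, burnin)
  nodes <- c(root = trace$root, trace$crown_nodes)
  labs <- c("root", paste0(names(trace$crown_nodes), " MRCA"))
  rows <- lapply(seq_along(nodes), function(i) {
    cn <- paste0("age_", nodes[i])
    r <- s[s$parameter == cn, ]
    data.frame(node = labs[i], mean = r$mean, median = r$median,
               hpd_lower = r$hpd_lower, hpd_upper = r$hpd_upper,
               ess = r$ess, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
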