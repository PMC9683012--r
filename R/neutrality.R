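#' Sample noncoding null regions around an element
#'
#' Draws `n` windows of exactly the element's length, uniformly among all
#' placements inside `window` that do not intersect any annotated feature
#' (genes, the element itself, anything listed in `exclude`). Sampled
#' windows may overlap each other.
#'
#' @param exclude `data.frame` with `start`/`end` columns (0-based
#'   half-open): intervals the windows must avoid.
#' @param window `c(start, end)`: the span to sample from.
#' @param width Window width (the element's length), nt.
#' @param n Number of windows.
#' @param seed Integer seed (placements are reproducible).
#' @return `data.frame` with `start`, `end`, `name` (null_1..null_n).
#' @export
sample_noncoding_regions <- function(exclude, window, width, n, seed = 1L) {
  stopifnot(width >= 1, n >= 0, window[2] > window[1])
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      name = character(0)))
  }
  span <- window[2] - window[1]
  if (span < width) stop("sampling window shorter than region width")
  ok <- rep(TRUE, span - width + 1L)  # candidate starts window[1] + 0:...
  if (nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      lo <- max(exclude$start[i] - width + 1L, window[1])
      hi <- min(exclude$end[i] - 1L, window[2] - width)
      if (hi >= lo) ok[(lo - window[1] + 1L):(hi - window[1] + 1L)] <- FALSE
    }
  }
  starts <- window[1] + which(ok) - 1L
  if (length(starts) < n) {
    stop("insufficient placeable space for ", n, " null regions (",
         length(starts), " achievable)")
  }
  with_seed(derive_seed(seed, "null_regions"), {
    s <- sample(starts, n)
  })
  data.frame(start = s, end = s + width,
             name = paste0("null_", seq_len(n)), stringsAsFactors = FALSE)
}

#' Pairwise-distance samples for the element and null regions
#'
#' Computes pairwise p-distances (pairwise deletion, via
#' [pairwise_p_distance()]) within the element region and within every null
#' region, pooling the null values into one empirical distribution.
#'
#' @param aln Character matrix: the locus alignment (columns = locus
#'   coordinates).
#' @param eve_region `c(start, end)` of the element in alignment columns.
#' @param null_regions `data.frame` from [sample_noncoding_regions()].
#' @return List of class `distance_samples`: `eve` (values), `null` (pooled
#'   values), `per_region` (list of per-null-region values), `n_undefined`
#'   (pairs skipped for lack of comparable sites).
#' @export
build_distance_samples <- function(aln, eve_region, null_regions) {
  stopifnot(is.matrix(aln))
  codes <- match(toupper(aln), c("A", "C", "G", "T"))  # encode once
  codes[is.na(codes)] <- 0L
  cm <- matrix(codes, nrow = nrow(aln))
  vals <- function(lo, hi) {
    d <- cpp_pdist(cm[, (lo + 1L):hi, drop = FALSE])$d
    v <- d[lower.tri(d)]
    list(v = v[!is.na(v)], na = sum(is.na(v)))
  }
  ev <- vals(eve_region[1], eve_region[2])
  per <- lapply(seq_len(nrow(null_regions)), function(i) {
    vals(null_regions$start[i], null_regions$end[i])
  })
  structure(list(
    eve = ev$v,
    null = unlist(lapply(per, `[[`, "v")),
    per_region = lapply(per, `[[`, "v"),
    n_undefined = ev$na + sum(vapply(per, `[[`, 1, "na"))
  ), class = "distance_samples")
}

#' One-tailed two-sample Kolmogorov-Smirnov test
#'
#' For `alternative = "less"` (x stochastically smaller than y, the
#' constrained-element signature) the statistic is
#' `D+ = sup_t (F_x(t) - F_y(t))`. The asymptotic one-sided p-value is
#' `exp(-2 m n D^2 / (m + n))`; `"permutation"` resamples the pooled labels
#' (seeded) and `"exact"` enumerates every split (small samples only).
#'
#' @param x,y Numeric samples (element and null distances).
#' @param alternative `"less"` (x below y) or `"greater"`.
#' @param method P-value computation.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param seed Seed for the permutation method.
#' @return List of class `ks_result`: `statistic`, `p_value`, `alternative`,
#'   `method`, `m`, `n`.
#' @export
ks_test_one_tailed <- function(x, y, alternative = c("less", "greater"),
                               method = c("asymptotic", "permutation",
                                          "exact"),
                               n_perm = 999L, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty sample")
  m <- length(x); n <- length(y)
  D <- ks_dplus(x, y, alternative)
  p <- switch(method,
    asymptotic = min(1, exp(-2 * m * n * D^2 / (m + n))),
    permutation = with_seed(derive_seed(seed, "ks_perm"), {
      pool <- c(x, y)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(m + n, m)
        if (ks_dplus(pool[idx], pool[-idx], alternative) >= D - 1e-12) {
          hits <- hits + 1L
        }
      }
      (1 + hits) / (n_perm + 1)
    }),
    exact = {
      pool <- c(x, y)
      splits <- utils::combn(m + n, m)
      if (ncol(splits) > 2e5) stop("too many splits for exact enumeration")
      ge <- vapply(seq_len(ncol(splits)), function(b) {
        idx <- splits[, b]
        ks_dplus(pool[idx], pool[-idx], alternative) >= D - 1e-12
      }, TRUE)
      mean(ge)
    })
  structure(list(statistic = D, p_value = p, alternative = alternative,
                 method = method, m = m, n = n),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("one-tailed KS (%s, %s): D = %.4f, p = %.4g (m=%d, n=%d)\n",
              x$alternative, x$method, x$statistic, x$p_value, x$m, x$n))
  invisible(x)
}

# D+ = sup_t (F_x(t) - F_y(t)) for "less", mirrored for "greater";
# streaming ECDF evaluation over the pooled sorted values
ks_dplus <- function(x, y, alternative = "less") {
  if (alternative == "greater") {
    tmp <- x; x <- y; y <- tmp
  }
  sx <- sort(x); sy <- sort(y)
  t <- c(sx, sy)
  fx <- findInterval(t, sx) / length(sx)
  fy <- findInterval(t, sy) / length(sy)
  max(fx - fy)
}

#' Region-calibrated neutrality test for an element
#'
#' Tests whether the element's pairwise distances are stochastically smaller
#' than those of surrounding noncoding regions (the signature of selective
#' constraint). The one-sided KS statistic of the element against the pooled
#' null regions is referred to the empirical distribution of the same
#' statistic computed for each null region against the pool of the others
#' (region-label permutation): pairwise distances within a region are
#' strongly dependent (they share the species tree), so this exchangeable
#' region-level reference is what keeps the test calibrated. The classical
#' pooled-sample KS p-value is also reported for reference.
#'
#' @param aln Locus alignment (character matrix, columns = coordinates).
#' @param eve_region `c(start, end)` element interval in alignment columns.
#' @param exclude Feature intervals null regions must avoid (`data.frame`
#'   with start/end; typically genes + the element).
#' @param window Sampling span (default: the whole alignment).
#' @param n_null Number of null regions.
#' @param alternative Direction (default `"less"`: element more constrained).
#' @param seed Integer seed.
#' @return List of class `neutrality_result`: `ks` (region-calibrated
#'   `ks_result`), `ks_pooled` (asymptotic reference), `samples`
#'   (`distance_samples`), `null_regions`.
#' @export
neutrality_test <- function(aln, eve_region, exclude, window = NULL,
                            n_null = 100L, alternative = "less", seed = 1L) {
  if (is.null(window)) window <- c(0L, ncol(aln))
  width <- eve_region[2] - eve_region[1]
  nulls <- sample_noncoding_regions(exclude, window, width, n_null, seed)
  smp <- build_distance_samples(aln, eve_region, nulls)
  # each focal region (element or null) is referred to the pool of null
  # regions that do not overlap it: null windows may overlap each other but
  # never the element, and pooling overlappers would make the null regions'
  # reference statistics systematically smaller than the element's
  overlaps <- function(lo, hi) {
    pmin(nulls$end, hi) > pmax(nulls$start, lo)
  }
  D_eve <- ks_dplus(smp$eve,
                    unlist(smp$per_region[!overlaps(eve_region[1],
                                                    eve_region[2])]),
                    alternative)
  D_null <- vapply(seq_along(smp$per_region), function(j) {
    keep <- !overlaps(nulls$start[j], nulls$end[j])
    keep[j] <- FALSE
    ks_dplus(smp$per_region[[j]], unlist(smp$per_region[keep]), alternative)
  }, 1)
  p <- (1 + sum(D_null >= D_eve - 1e-12)) / (n_null + 1)
  ks <- structure(list(statistic = D_eve, p_value = p,
                       alternative = alternative,
                       method = "region-permutation",
                       m = length(smp$eve), n = length(smp$null)),
                  class = "ks_result")
  pooled <- ks_test_one_tailed(smp$eve, smp$null, alternative,
                               method = "asymptotic")
  structure(list(ks = ks, ks_pooled = pooled, samples = smp,
                 null_regions = nulls),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  print(x$ks)
  cat(sprintf("  element mean distance %.4f vs null %.4f (pooled KS p %.3g)\n",
              mean(x$samples$eve), mean(x$samples$null),
              x$ks_pooled$p_value))
  invisible(x)
}

#' Overlap of an element with piRNA clusters (or any interval set)
#'
#' Half-open interval intersection: touching boundaries do not overlap.
#'
#' @param eve_region `c(start, end)`, 0-based half-open.
#' @param clusters `data.frame` with `start`, `end` and optionally `name`.
#' @return `data.frame` of intersecting clusters with `overlap` lengths
#'   (zero rows = no matches).
#' @export
pirna_overlap <- function(eve_region, clusters) {
  ov <- pmin(clusters$end, eve_region[2]) - pmax(clusters$start,
                                                 eve_region[1])
  hit <- which(ov > 0)
  out <- clusters[hit, , drop = FALSE]
  out$overlap <- ov[hit]
  rownames(out) <- NULL
  out
}
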