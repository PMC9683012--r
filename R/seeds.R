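# Deterministic seed derivation: every stochastic stage receives its own
# seed derived from the global seed and a stage tag, so stages can be rerun
# independently and no hidden global RNG state leaks between them.

#' Derive a stage seed from a global seed
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag.
#' @return An integer in \[1, 2^31 - 2\], a stable hash of (seed, tag).
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(tag)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

with_seed <- function(seed, expr) {
  force(seed)  # a lazily supplied seed may itself consume global RNG draws
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

NT_CHARS <- c("A", "C", "G", "T")

# integer-coded (1..4) nucleotide helpers used throughout the simulator
nt_encode <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) x <- strsplit(x, "")[[1]]
  m <- match(toupper(x), NT_CHARS)
  if (anyNA(m)) stop("non-ACGT character in sequence")
  m
}

nt_decode <- function(code) paste(NT_CHARS[code], collapse = "")

revcomp_code <- function(code) rev(5L - code)
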