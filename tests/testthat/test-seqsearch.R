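test_that("six-frame translation follows the codon table and N policy", {
  fr <- six_frame_translate("ATGAAATAA")
  expect_equal(fr[["+1"]]$aa, "MK*")
  expect_equal(six_frame_translate("ATGNAA")[["+1"]]$aa, "MX")
  # reverse frames read the reverse complement
  s <- revcomp_chr("ATGAAA")
  expect_equal(six_frame_translate(s)[["-1"]]$aa, "MK")
  expect_error(six_frame_translate("ATGU"), "illegal characters")
})

test_that("frame coordinates invert exactly on both strands", {
  s <- random_dna(101)
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    iv <- frame_to_forward(frame, 4L, 9L, nchar(s))
    expect_equal(iv[2] - iv[1], 15L)
    sub <- substr(s, iv[1] + 1L, iv[2])
    if (frame < 0) sub <- revcomp_chr(sub)
    aa <- six_frame_translate(s)[[paleoeve:::frame_name(frame)]]$aa
    expect_equal(six_frame_translate(sub)[["+1"]]$aa, substr(aa, 5L, 9L))
  }
})

test_that("an exact embedded ORF yields a perfect HSP with self-score", {
  set.seed(31)
  prot <- random_protein(40)
  nt <- paste0(random_dna(60), backtranslate(prot), random_dna(60))
  sm <- scoring_matrix()
  h <- local_align_translated(prot, nt, sm, max_evalue = 1e-3)
  expect_gte(nrow(h), 1L)
  top <- h[1, ]
  expect_equal(top$pident, 100)
  self_score <- sum(diag(sm$matrix)[match(strsplit(prot, "")[[1]],
                                          rownames(sm$matrix))])
  expect_equal(top$score, self_score)
  expect_equal(top$qstart, 0L)
  expect_equal(top$qend, 40L)
  expect_equal(top$send - top$sstart, 120L)
  expect_equal(substr(nt, top$sstart + 1, top$send), backtranslate(prot))
})

test_that("unrelated sequences yield nothing at a stringent threshold", {
  set.seed(5)
  h <- local_align_translated(random_protein(30), random_dna(300),
                              max_evalue = 1e-8)
  expect_equal(nrow(h), 0L)
  expect_equal(nrow(local_align_translated("", "ACGT")), 0L)
  expect_equal(nrow(local_align_translated("MKV", "")), 0L)
})

test_that("search equals an independent exhaustive SW per frame", {
  set.seed(91)
  sm <- scoring_matrix()
  for (rep in 1:12) {
    p <- random_protein(sample(15:45, 1))
    s <- random_dna(sample(100:250, 1))
    h <- local_align_translated(p, s, sm, max_evalue = Inf)
    frames <- six_frame_translate(s)
    for (fr in frames) {
      oracle <- sw_score_oracle(p, fr$aa, sm)
      mine <- h$score[h$frame == fr$frame]
      top <- if (length(mine)) max(mine) else 0
      expect_equal(top, oracle, label = paste("frame", fr$frame))
    }
  }
})

test_that("forced seeding matches exhaustive search on real homology", {
  # seeding is a sensitivity heuristic: on probe/subject pairs carrying a
  # diverged copy of the probe (the regime it is designed for), the seeded
  # engine must find the same top score as the exact search
  set.seed(17)
  sm <- scoring_matrix()
  for (rep in 1:15) {
    prot <- random_protein(60)
    nt <- paste0(random_dna(150), backtranslate(prot), random_dna(150))
    nt_mut <- strsplit(nt, "")[[1]]
    mut <- sample(seq_along(nt_mut), round(0.1 * length(nt_mut)))
    nt_mut[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    nt <- paste(nt_mut, collapse = "")
    seeded <- local_align_translated(prot, nt, sm, max_evalue = 1e-3,
                                     exhaustive_area = 0)
    exact <- local_align_translated(prot, nt, sm, mode = "exhaustive",
                                    max_evalue = 1e-3)
    expect_equal(seeded$score[1], exact$score[1])
  }
})

test_that("strand symmetry: reverse-complementing the subject mirrors hits", {
  set.seed(23)
  prot <- random_protein(35)
  nt <- paste0(random_dna(40), backtranslate(prot), random_dna(50))
  h_fwd <- local_align_translated(prot, nt, max_evalue = 1e-3)
  h_rev <- local_align_translated(prot, revcomp_chr(nt), max_evalue = 1e-3)
  expect_equal(nrow(h_fwd), nrow(h_rev))
  expect_equal(h_fwd$score[1], h_rev$score[1])
  expect_equal(h_fwd$frame[1], -h_rev$frame[1])
  n <- nchar(nt)
  expect_equal(c(h_fwd$sstart[1], h_fwd$send[1]),
               c(n - h_rev$send[1], n - h_rev$sstart[1]))
})

test_that("Karlin-Altschul lambda matches an independent bisection root", {
  # +1/-1 match/mismatch over a uniform 4-letter alphabet: solve
  # (1/4) e^l + (3/4) e^-l = 1 by plain bisection
  S <- matrix(-1L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  diag(S) <- 1L
  sm <- list(matrix = S, alphabet = "ACGT", gap_open = 5L, gap_ext = 2L,
             name = "pm1")
  class(sm) <- "scoring_matrix"
  freq <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  lam <- karlin_lambda(sm, freq, freq)
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-l) - 1
  lo <- 1e-6; hi <- 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(lam, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("E-values are linear in n and monotone in score", {
  p <- ka_params(scoring_matrix())
  e1 <- estimate_evalue(50, 100, 1000, p)$evalue
  e2 <- estimate_evalue(50, 100, 2000, p)$evalue
  expect_equal(e2, 2 * e1)
  scores <- seq(10, 200, by = 10)
  ev <- estimate_evalue(scores, 100, 1000, p)$evalue
  expect_true(all(diff(ev) < 0))
  expect_lt(estimate_evalue(1e6, 100, 1000, p)$evalue, 1e-300)
})

test_that("a matrix with non-negative expected score is rejected", {
  S <- matrix(1L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  sm <- structure(list(matrix = S, alphabet = "ACGT", gap_open = 5L,
                       gap_ext = 2L, name = "bad"),
                  class = "scoring_matrix")
  freq <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  expect_error(karlin_lambda(sm, freq, freq), "unusable")
})

test_that("hit chaining computes union query cover and splits strands", {
  h <- empty_like_hsps(
    frame = c(1L, 2L),
    qstart = c(0L, 40L), qend = c(50L, 100L),
    sstart = c(100L, 260L), send = c(250L, 440L))
  g <- merge_hits(h, probe_len = 200L, probe = "P")
  expect_length(g, 1L)
  expect_equal(g[[1]]$query_cover, 50)  # union [0,100) of 200
  h1 <- empty_like_hsps(frame = 1L, qstart = 0L, qend = 200L,
                        sstart = 0L, send = 600L)
  expect_equal(merge_hits(h1, 200L)[[1]]$query_cover, 100)
  # opposite strands never chain
  h2 <- empty_like_hsps(frame = c(1L, -2L), qstart = c(0L, 40L),
                        qend = c(50L, 100L), sstart = c(100L, 260L),
                        send = c(250L, 440L))
  g2 <- merge_hits(h2, 200L)
  expect_length(g2, 2L)
  expect_setequal(vapply(g2, `[[`, 1L, "strand"), c(1L, -1L))
})

test_that("distant HSPs are not chained", {
  h <- empty_like_hsps(frame = c(1L, 1L), qstart = c(0L, 60L),
                       qend = c(50L, 100L), sstart = c(0L, 5000L),
                       send = c(150L, 5120L))
  expect_length(merge_hits(h, 200L, max_gap = 1000L), 2L)
})
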