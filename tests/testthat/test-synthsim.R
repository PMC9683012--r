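test_that("ancestral locus layout follows the template", {
  cfg <- sim_config(spacer_len = 500L)
  tmpl <- eve_template(tir_len = 50L, spacer_len = 30L)
  anc <- simulate_ancestral_locus(cfg, tmpl, seed = 3)
  genes <- anc$anno[anc$anno$type == "eve_gene", ]
  expect_identical(genes$name, tmpl$genes$name)  # template order
  expect_true(all(diff(genes$start) > 0))
  expect_true(all(genes$end - genes$start == 3L * tmpl$genes$aa_len))
  # landmark ORFs are stop-free
  for (g in grep("^LM", names(anc$proteins), value = TRUE)) {
    expect_false(grepl("\\*", anc$proteins[[g]]))
  }
  # TIRs are exact reverse complements at creation
  tirs <- anc$anno[anc$anno$type == "tir", ]
  expect_equal(nrow(tirs), 2L)
  t5 <- anc$seq[(tirs$start[1] + 1):tirs$end[1]]
  t3 <- anc$seq[(tirs$start[2] + 1):tirs$end[2]]
  expect_identical(t3, paleoeve:::revcomp_code(t5))
  # features tile the locus without overlap
  a <- anc$anno[anc$anno$name != "EVE", ]
  expect_true(all(a$start[-1] == a$end[-nrow(a)]))
})

test_that("TIR length 0 emits no TIR features", {
  anc <- simulate_ancestral_locus(sim_config(), eve_template(tir_len = 0L),
                                  seed = 3)
  expect_equal(sum(anc$anno$type == "tir"), 0L)
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config()
  tmpl <- polb_template(120L)
  a1 <- simulate_ancestral_locus(cfg, tmpl, seed = 11)
  a2 <- simulate_ancestral_locus(cfg, tmpl, seed = 11)
  expect_identical(a1$seq, a2$seq)
  expect_identical(a1$anno, a2$anno)
  host <- toy_host()
  s1 <- evolve_locus(host, a1, branch_above(host, c("A", "B", "C", "D")),
                     seed = 5)
  s2 <- evolve_locus(host, a2, branch_above(host, c("A", "B", "C", "D")),
                     seed = 5)
  expect_identical(lapply(s1$genomes, `[[`, "seq"),
                   lapply(s2$genomes, `[[`, "seq"))
  expect_false(identical(
    s1$genomes$A$seq,
    evolve_locus(host, a1, branch_above(host, c("A", "B", "C", "D")),
                 seed = 6)$genomes$A$seq))
})

test_that("two loci can share one ancestral element in different flanks", {
  cfg <- sim_config(spacer_len = 400L)
  tmpl <- polb_template(100L)
  a1 <- simulate_ancestral_locus(cfg, tmpl, seed = 1, eve_seed = 99)
  a2 <- simulate_ancestral_locus(cfg, tmpl, seed = 2, eve_seed = 99)
  expect_identical(a1$proteins$POLB, a2$proteins$POLB)
  expect_false(identical(a1$proteins$LMU1, a2$proteins$LMU1))
  e1 <- a1$seq[(a1$eve_interval[1] + 1):a1$eve_interval[2]]
  e2 <- a2$seq[(a2$eve_interval[1] + 1):a2$eve_interval[2]]
  expect_identical(e1, e2)
})

test_that("zero clock rate transmits the ancestor unchanged", {
  cfg <- sim_config(clock_rate = 0, branch_sd = 0)
  anc <- simulate_ancestral_locus(cfg, polb_template(80L), seed = 2)
  host <- toy_host()
  sim <- evolve_locus(host, anc, branch_above(host, c("A", "B", "C", "D")),
                      seed = 4)
  expect_identical(sim$genomes$A$seq, anc$seq)
  # non-carrier: ancestor minus the element interval
  ei <- anc$eve_interval
  expect_identical(sim$genomes$G$seq,
                   anc$seq[-((ei[1] + 1L):ei[2])])
})

test_that("exact re-scan of emitted sequences agrees with presence flags", {
  cfg <- sim_config(clock_rate = 0, branch_sd = 0)
  anc <- simulate_ancestral_locus(cfg, polb_template(60L), seed = 8)
  host <- toy_host()
  sim <- evolve_locus(host, anc, branch_above(host, c("E", "F", "G")),
                      seed = 4)
  sim <- apply_losses(sim, 0.5, seed = 31)
  ei <- anc$eve_interval
  eve_seq <- nt_decode(anc$seq[(ei[1] + 1L):ei[2]])
  for (tx in sim$tree$taxa) {
    found <- grepl(eve_seq, taxon_sequence(sim, tx), fixed = TRUE)
    expect_identical(unname(found), unname(sim$truth$present[tx]),
                     label = tx)
  }
})

test_that("pairwise divergence matches the Jukes-Cantor expectation", {
  # two tips separated by 2T: E[p] = 3/4 (1 - exp(-8 r T / 3));
  # empirical mean over 50 replicate loci within 3 standard errors
  host <- build_host_tree("((X:50,Y:50):25,Z:75);")
  r <- 0.002
  cfg <- sim_config(model = jc_model(), clock_rate = r, branch_sd = 0,
                    indel_rate = 0, landmark_n = 1L, landmark_aa = 40L,
                    landmark_rate_scale = 1, spacer_len = 300L)
  tmpl <- polb_template(60L)
  set.seed(421)
  p_hat <- replicate(50, {
    anc <- simulate_ancestral_locus(cfg, tmpl, seed = sample.int(1e6, 1))
    sim <- evolve_locus(host, anc, branch_above(host, c("X", "Y")),
                        seed = sample.int(1e6, 1))
    m <- true_alignment(sim, 0, length(anc$seq))
    mean(m[1, ] != m[2, ])
  })
  expected <- 0.75 * (1 - exp(-8 * r * 50 / 3))
  se <- sd(p_hat) / sqrt(length(p_hat))
  expect_lt(abs(mean(p_hat) - expected), 3 * se + 1e-9)
})

test_that("a stem insertion is present in the clade and absent outside", {
  host <- mammal_host()
  carriers <- default_carrier_taxa()
  anc <- simulate_ancestral_locus(sim_config(), polb_template(150L),
                                  seed = 5)
  sim <- evolve_locus(host, anc, branch_above(host, carriers), seed = 6)
  expect_true(all(sim$truth$present[carriers]))
  expect_false(any(sim$truth$present[c("opossum", "platypus")]))
  expect_equal(sim$truth$carrier_mrca_age, 102)
  rng <- sim$truth$insertion_age_range
  expect_true(sim$truth$insertion_age > rng[1] &&
                sim$truth$insertion_age < rng[2])
  expect_equal(rng, c(102, 172))
})

test_that("losses follow the per-taxon probability", {
  host <- toy_host()
  carriers <- c("A", "B", "C", "D")
  anc <- simulate_ancestral_locus(sim_config(clock_rate = 0),
                                  polb_template(50L), seed = 1)
  sim <- evolve_locus(host, anc, branch_above(host, carriers), seed = 2)
  expect_identical(apply_losses(sim, 0, seed = 1)$truth$present,
                   sim$truth$present)
  all_lost <- apply_losses(sim, 1, seed = 1)
  expect_false(any(all_lost$truth$present))
  # element excised: flanks joined
  ei <- anc$eve_interval
  expect_identical(all_lost$genomes$A$seq, anc$seq[-((ei[1] + 1L):ei[2])])
  # mean loss count over 200 seeds ~ Binomial(4, 0.2)
  losses <- vapply(1:200, function(s) {
    sum(apply_losses(sim, 0.2, seed = s)$truth$lost)
  }, 1)
  n <- length(carriers)
  expect_lt(abs(mean(losses) - 0.2 * n),
            3 * sqrt(0.2 * 0.8 * n / 200))
})

test_that("per-taxon features map through indels", {
  host <- toy_host()
  cfg <- sim_config()
  anc <- simulate_ancestral_locus(cfg, polb_template(100L), seed = 3)
  sim <- evolve_locus(host, anc, branch_above(host, c("A", "B")), seed = 9)
  ft <- taxon_features(sim, "A")
  expect_true(all(ft$end >= ft$start))
  g <- ft[ft$name == "POLB", ]
  seq_a <- sim$genomes$A$seq
  # the mapped interval stays inside the genome and near the original size
  expect_true(g$start >= 0 && g$end <= length(seq_a))
  expect_gt(g$end - g$start, 0.8 * 300)
  # non-carrier features lack element rows
  ft_g <- taxon_features(sim, "G")
  expect_false(any(ft_g$type %in% c("eve", "eve_gene", "tir")))
})

test_that("written outputs round-trip through standard formats", {
  host <- toy_host()
  anc <- simulate_ancestral_locus(sim_config(spacer_len = 200L),
                                  polb_template(40L), seed = 2)
  sim <- evolve_locus(host, anc, branch_above(host, c("A", "B")), seed = 3)
  dir <- tempfile("simout")
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  fa <- read_fasta(file.path(dir, "A.fa"))
  expect_identical(unname(fa), taxon_sequence(sim, "A"))
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE)
  expect_identical(truth$present[truth$taxon == "G"], FALSE)
})
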