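# Synteny-anchored orthology and presence calling, validated against the
# simulator's truth records.

sim_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      host <- mammal_host()
      anc <- simulate_ancestral_locus(sim_config(spacer_len = 3000L),
                                      polb_template(400L), seed = 61)
      sim <- evolve_locus(host, anc, branch_above(host,
                                                  default_carrier_taxa()),
                          seed = 62)
      memo <<- list(host = host, anc = anc, sim = sim)
    }
    memo
  }
})

test_that("landmarks are located in truth order on a simulated genome", {
  fx <- sim_fixture()
  subject <- taxon_sequence(fx$sim, "human")
  loc <- locate_landmarks(subject, sim_landmark_set(fx$anc))
  expect_true(all(loc$found))
  expect_false(attr(loc, "rearranged"))
  truth <- taxon_features(fx$sim, "human")
  for (i in seq_len(nrow(loc))) {
    tr <- truth[truth$name == loc$name[i], ]
    # located interval overlaps most of the true gene (local alignments
    # trim diverged termini, so exact ends are not expected)
    ov <- min(loc$send[i], tr$end) - max(loc$sstart[i], tr$start)
    expect_gt(ov, 0.5 * (tr$end - tr$start))
    expect_lt(abs(loc$sstart[i] - tr$start), 700)
    expect_lt(abs(loc$send[i] - tr$end), 700)
  }
  # chromosomal order of located landmarks matches the truth order
  expect_identical(loc$name[order(loc$sstart)],
                   truth$name[truth$type == "landmark"][order(
                     truth$start[truth$type == "landmark"])])
})

test_that("shuffled landmarks raise the rearranged flag", {
  fx <- sim_fixture()
  lms <- sim_landmark_set(fx$anc)
  spacer <- random_dna(500)
  shuffled <- paste0(spacer, backtranslate(lms$downstream[[2]]), spacer,
                     backtranslate(lms$upstream[[1]]), spacer,
                     backtranslate(lms$upstream[[3]]), spacer)
  loc <- locate_landmarks(shuffled, lms)
  expect_true(attr(loc, "rearranged"))
})

test_that("an empty sequence locates nothing and yields ambiguity", {
  fx <- sim_fixture()
  loc <- locate_landmarks("", sim_landmark_set(fx$anc))
  expect_false(any(loc$found))
  region <- define_ortho_region(loc, 0L)
  expect_equal(region$status, "ambiguous")
  call <- call_presence(region, "", sim_core_probes(fx$anc))
  expect_equal(call$state, "ambiguous")
})

test_that("ortho regions span innermost landmarks or extend one-sided", {
  located <- data.frame(
    name = c("u1", "u2", "d1", "d2"),
    side = c("upstream", "upstream", "downstream", "downstream"),
    found = c(TRUE, TRUE, TRUE, TRUE),
    sstart = c(200L, 1000L, 9000L, 9500L),
    send = c(800L, 2000L, 9400L, 9900L),
    strand = "+", evalue = 1e-20, stringsAsFactors = FALSE)
  r <- define_ortho_region(located, 12000L)
  expect_equal(r$interval, c(2000L, 9000L))
  expect_equal(r$status, "defined")
  # one-sided anchor: extension by 3 * 1053 nt
  one <- located[located$side == "upstream", ]
  r1 <- define_ortho_region(one, 12000L, expected_aa = 1053L)
  expect_equal(r1$status, "one_sided")
  expect_equal(r1$interval, c(2000L, 2000L + 3159L))
  # adjacent landmarks leave an empty region
  adj <- located
  adj$sstart[3:4] <- c(2000L, 9500L)
  r2 <- define_ortho_region(adj, 12000L)
  expect_equal(r2$interval[1], r2$interval[2])
})

test_that("presence calls match simulator truth including losses", {
  fx <- sim_fixture()
  sim <- apply_losses(fx$sim, 0.3, seed = 99)
  expect_true(any(sim$truth$lost))
  sc <- screen_presence(sim, "L")
  truth <- ifelse(sim$truth$present, "present", "absent")
  expect_identical(unname(sc$calls$state), unname(truth[sc$calls$taxon]))
  # carriers carry a polymerase hit group
  carrier <- names(which(sim$truth$present))[1]
  expect_true("POLB" %in% names(sc$details[[carrier]]$hit_groups))
})

test_that("an empty inter-landmark region is called absent, not ambiguous", {
  fx <- sim_fixture()
  lms <- sim_landmark_set(fx$anc)
  joined <- paste0(random_dna(300),
                   paste(vapply(lms$upstream, backtranslate, ""),
                         collapse = ""),
                   paste(vapply(lms$downstream, backtranslate, ""),
                         collapse = ""),
                   random_dna(300))
  loc <- locate_landmarks(joined, lms)
  region <- define_ortho_region(loc, nchar(joined))
  call <- call_presence(region, joined, sim_core_probes(fx$anc))
  expect_equal(call$state, "absent")
})

test_that("arrangement consistency follows template order and strands", {
  tmpl <- eve_template()
  mk_group <- function(probe, sstart, send, strand = 1L) {
    structure(list(probe = probe,
                   hsps = empty_like_hsps(frame = strand * 1L,
                                          qstart = 0L, qend = 10L,
                                          sstart = sstart, send = send),
                   query_cover = 50, best_evalue = 1e-10, strand = strand),
              class = "hit_group")
  }
  # template order with missing genes: consistent
  g <- list(POLB = mk_group("POLB", 100, 400),
            PZ = mk_group("PZ", 1000, 1300),
            MCP = mk_group("MCP", 2000, 2400))
  expect_true(check_arrangement(g, tmpl))
  # scrambled order: inconsistent
  g2 <- g[c(1, 2, 3)]
  g2$PZ$hsps$sstart <- 5000; g2$PZ$hsps$send <- 5300
  expect_false(check_arrangement(g2, tmpl))
  # integrase and major capsid on opposite strands: inconsistent
  g3 <- list(INT = mk_group("INT", 100, 400, strand = 1L),
             MCP = mk_group("MCP", 2000, 2400, strand = -1L))
  expect_false(check_arrangement(g3, tmpl))
  # single hit: vacuously consistent
  expect_true(check_arrangement(g[1], tmpl))
})

test_that("presence matrices reject duplicates and compare methods", {
  calls <- data.frame(
    taxon = rep(c("t1", "t2", "t3"), 2),
    locus = "L",
    method = rep(c("hits", "alignment"), each = 3),
    state = c("present", "absent", "present",
              "present", "present", "present"),
    stringsAsFactors = FALSE)
  pm <- build_presence_matrix(calls)
  m <- presence_states(pm, "hits")
  expect_equal(m["t2", "L"], "absent")
  cmp <- compare_methods(pm, pm, "hits", "alignment")
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$taxon, "t2")
  # identical methods agree everywhere
  expect_equal(nrow(compare_methods(pm, pm, "hits", "hits")), 0L)
  expect_error(build_presence_matrix(rbind(calls, calls[1, ])),
               "duplicate")
})

test_that("removing landmarks moves calls toward ambiguous, never flips", {
  fx <- sim_fixture()
  probes <- sim_core_probes(fx$anc)
  lms <- sim_landmark_set(fx$anc)
  for (tx in c("human", "opossum")) {
    subject <- taxon_sequence(fx$sim, tx)
    full <- call_presence(
      define_ortho_region(locate_landmarks(subject, lms), nchar(subject)),
      subject, probes)
    none <- call_presence(
      define_ortho_region(locate_landmarks("", lms), 0L), subject, probes)
    expect_equal(none$state, "ambiguous")
    expect_true(full$state %in% c("present", "absent"))
  }
})
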