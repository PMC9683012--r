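# Calibrated Bayesian dating: likelihood oracles, priors, MCMC mechanics,
# trace summaries and presence-based minimum ages.

test_that("pruning equals enumeration on 4- and 5-taxon trees", {
  set.seed(81)
  m <- gtr_model(alpha = 0.6, ncat = 4)
  tr4 <- ape::read.tree(text = "((A:0.12,B:0.3):0.08,(C:0.25,D:0.05):0.1);")
  aln4 <- setNames(replicate(4, paste(sample(c("A", "C", "G", "T"), 10,
                                             TRUE), collapse = "")),
                   c("A", "B", "C", "D"))
  expect_lt(abs(pruning_loglik(tr4, aln4, m) -
                  enumeration_loglik(tr4, aln4, m)), 1e-8)
  tr5 <- ape::read.tree(
    text = "(((A:0.1,B:0.2):0.05,C:0.3):0.04,(D:0.15,E:0.22):0.09);")
  aln5 <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 10,
                                             TRUE), collapse = "")),
                   c("A", "B", "C", "D", "E"))
  expect_lt(abs(pruning_loglik(tr5, aln5, m) -
                  enumeration_loglik(tr5, aln5, m)), 1e-8)
})

test_that("two-taxon Jukes-Cantor matches the closed form", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.15);")
  d <- 0.25
  same <- log((1 / 4) * ((1 / 4) + (3 / 4) * exp(-4 * d / 3)))
  diff <- log((1 / 4) * ((1 / 4) - (1 / 4) * exp(-4 * d / 3)))
  expect_equal(pruning_loglik(tr, c(A = "A", B = "A"), jc_model()), same)
  expect_equal(pruning_loglik(tr, c(A = "A", B = "C"), jc_model()), diff)
})

test_that("duplicating every column doubles the log-likelihood", {
  set.seed(82)
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.07);")
  aln <- setNames(replicate(4, paste(sample(c("A", "C", "G", "T"), 20,
                                            TRUE), collapse = "")),
                  c("A", "B", "C", "D"))
  doubled <- setNames(paste0(aln, aln), names(aln))
  m <- gtr_model(alpha = 1, ncat = 4)
  expect_equal(pruning_loglik(tr, doubled, m),
               2 * pruning_loglik(tr, aln, m), tolerance = 1e-10)
})

test_that("gaps and ambiguity act as missing data", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.15);")
  m <- jc_model()
  # a site missing in B contributes the marginal of A only: log(1/4)
  expect_equal(pruning_loglik(tr, c(A = "A", B = "-"), m), log(0.25))
  expect_equal(pruning_loglik(tr, c(A = "A", B = "N"), m), log(0.25))
})

test_that("prior density honours calibrations and age ordering", {
  host <- toy_host()
  dt <- build_dating_tree(host, list(L = host$taxa))
  cal <- calibration(c("A|L", "B|L"), mean = 20, sd = 1.5)
  ph <- dt$phylo
  ctx <- list(edge = ph$edge, root = ape::Ntip(ph) + 1L,
              root_min = 20, root_max = 500,
              calib_nodes = as.integer(ape::getMRCA(ph, cal$taxa)),
              calib_means = 20, calib_sds = 1.5,
              rate_meanlog = log(0.003), rate_sdlog = 1, clock_sd = 0.3)
  state <- list(ages = dt$ages, rate = 0.003)
  state$ages[ctx$calib_nodes] <- 20
  lp_at_mean <- prior_logdensity(state, ctx)
  state2 <- state
  state2$ages[ctx$calib_nodes] <- 23
  # moving one calibrated node off its mean changes the density by the
  # normal log-density difference
  expect_equal(lp_at_mean - prior_logdensity(state2, ctx),
               dnorm(20, 20, 1.5, log = TRUE) -
                 dnorm(23, 20, 1.5, log = TRUE))
  # calibration at its mean contributes -log(sd * sqrt(2*pi))
  ctx0 <- ctx
  ctx0$calib_nodes <- integer(0)
  ctx0$calib_means <- numeric(0)
  ctx0$calib_sds <- numeric(0)
  expect_equal(lp_at_mean - prior_logdensity(state, ctx0),
               -log(1.5 * sqrt(2 * pi)))
  # child older than parent: -Inf
  bad <- state
  bad$ages[ctx$calib_nodes] <- root_age(host) + 1
  expect_identical(prior_logdensity(bad, ctx), -Inf)
})

test_that("the sampler is deterministic under a fixed seed", {
  host <- toy_host()
  carr <- list(L = c("A", "B", "C", "D"))
  sim <- simulate_dating_alignment(host, carr, root_age = 80,
                                   rate = 0.0027, n_sites = 120, seed = 4)
  cals <- host_calibrations(host, carr, sd = 1.5)
  cfg <- mcmc_config(generations = 2000, sample_every = 10, seed = 9)
  t1 <- mcmc_run(sim$alignment, sim$dating_tree, cals, clock_model(),
                 gtr_model(alpha = 1), cfg)
  t2 <- mcmc_run(sim$alignment, sim$dating_tree, cals, clock_model(),
                 gtr_model(alpha = 1), cfg)
  expect_identical(t1$samples, t2$samples)
})

test_that("the relaxed clock samples branch multipliers from their prior", {
  host <- toy_host()
  dt <- build_dating_tree(host, list(L = host$taxa))
  cals <- host_calibrations(host, list(L = host$taxa), sd = 0.5)
  trc <- mcmc_run(NULL, dt, cals, clock_model("ucln", sd = 0.3),
                  jc_model(),
                  mcmc_config(generations = 15000, sample_every = 10,
                              seed = 2, estimate_model = FALSE))
  expect_true(all(c("age", "root", "rate", "mult") %in%
                    names(trc$acceptance)))
  expect_gt(trc$acceptance["mult"], 0)
})

test_that("trace summaries: HPD, ESS and degenerate traces", {
  set.seed(83)
  x <- rnorm(10000)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.08)
  expect_lt(abs(h[2] - 1.96), 0.08)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.95)
  expect_gt(ess(x), 0.9 * length(x))
  # constant trace
  expect_equal(hpd_interval(rep(3, 100)), c(3, 3))
  s <- summarize_trace(matrix(3, 100, 1, dimnames = list(NULL, "p")),
                       burnin = 0)
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$hpd_upper - s$hpd_lower, 0)
  # positively autocorrelated trace has ESS far below n; a perfectly
  # anticorrelated trace is antithetic, so the positive-sequence estimator
  # caps it at n rather than penalizing it
  set.seed(84)
  ar <- as.numeric(arima.sim(list(ar = 0.95), 1000))
  expect_lt(ess(ar), 200)
  alt <- rep(c(0, 1), 500)
  expect_lte(ess(alt), 1000)
  expect_error(summarize_trace(matrix(1, 1, 1)), "2")
})

test_that("minimum ages come from the carrier MRCA", {
  host <- mammal_host()
  calls <- data.frame(
    taxon = host$taxa, locus = "L", method = "hits",
    state = ifelse(host$taxa %in% default_carrier_taxa(), "present",
                   "absent"),
    stringsAsFactors = FALSE)
  pm <- build_presence_matrix(calls)
  ma <- min_age_from_presence(host, pm, "L")
  expect_equal(ma$age, 102)
  # two sister carriers only
  calls2 <- calls
  calls2$state <- ifelse(calls2$taxon %in% c("human", "macaque"),
                         "present", "absent")
  expect_equal(min_age_from_presence(host,
                                     build_presence_matrix(calls2),
                                     "L")$age, 29)
  # ambiguous taxa are excluded, fewer than two carriers is an error
  calls3 <- calls
  calls3$state <- c("present", rep("ambiguous", 11))
  expect_error(min_age_from_presence(host, build_presence_matrix(calls3),
                                     "L"), "fewer than two")
})

test_that("simulated datasets return the true insertion node", {
  host <- mammal_host()
  anc <- simulate_ancestral_locus(sim_config(clock_rate = 0),
                                  polb_template(50L), seed = 21)
  sim <- evolve_locus(host, anc, branch_above(host, default_carrier_taxa()),
                      seed = 22)
  calls <- data.frame(taxon = names(sim$truth$present), locus = "L",
                      method = "truth",
                      state = ifelse(sim$truth$present, "present",
                                     "absent"),
                      stringsAsFactors = FALSE)
  ma <- min_age_from_presence(host, build_presence_matrix(calls), "L")
  expect_equal(ma$age, sim$truth$carrier_mrca_age)
  expect_equal(ma$node, as.integer(sim$truth$insertion_branch))
})
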